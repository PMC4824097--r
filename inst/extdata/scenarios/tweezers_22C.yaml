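name: tweezers_22C
# Single-molecule translocation at 22 C on the 7.7 kb substrate carrying a
# ten-Chi locus from 4588 bp: 48 wild-type and 44 latch-mutant traces at
# 60 Hz, analyzed at 3 Hz with the 0.33 s pause censor.
seed: 220
substrates:
  tweezers:
    length_bp: 7700
    chi_first_bp: 4588
    n_chi: 10
    chi_spacing_bp: 30
assays:
  - type: traces
    variant: wildtype
    substrate: tweezers
    n_traces: 48
    seed: 2201
  - type: traces
    variant: E129A
    substrate: tweezers
    n_traces: 44
    seed: 2202
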