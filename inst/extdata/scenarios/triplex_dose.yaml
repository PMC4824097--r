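name: triplex_dose
# Stopped-flow triplex displacement at 37 C on substrates carrying zero to
# three Chi sequences between the entry point and the reporter.
seed: 440
assays:
  - type: triplex
    variant: wildtype_37C
    substrate: triplex_0chi
    n_molecules: 5000
    seed: 4401
  - type: triplex
    variant: wildtype_37C
    substrate: triplex_1chi
    n_molecules: 5000
    seed: 4402
  - type: triplex
    variant: wildtype_37C
    substrate: triplex_2chi
    n_molecules: 5000
    seed: 4403
  - type: triplex
    variant: wildtype_37C
    substrate: triplex_3chi
    n_molecules: 5000
    seed: 4404
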