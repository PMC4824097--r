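name: yield_folds
# Chi-fragment yields on a single-Chi substrate for the variant panel;
# pairwise fold changes recover the latch enhancement and the Chi-binding
# mutant defects.
seed: 550
substrates:
  single_chi:
    length_bp: 5000
    chi_positions: [2500]
assays:
  - type: yield
    variant: wildtype_37C
    substrate: single_chi
    n_molecules: 4000
    seed: 5501
  - type: yield
    variant: F68A
    substrate: single_chi
    n_molecules: 4000
    seed: 5502
  - type: yield
    variant: F210A
    substrate: single_chi
    n_molecules: 4000
    seed: 5503
  - type: yield
    variant: F68A_E129A
    substrate: single_chi
    n_molecules: 4000
    seed: 5504
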