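name: chase
# Exonuclease-chase dissociation series: 500 molecules, 5% multiplicative
# densitometry noise, 8 timepoints spanning two half-lives of each variant.
seed: 330
assays:
  - type: chase
    variant: wildtype
    n_molecules: 500
    noise_cv: 0.05
    seed: 3301
  - type: chase
    variant: E129A
    n_molecules: 500
    noise_cv: 0.05
    seed: 3302
  - type: chase
    variant: F68A
    n_molecules: 500
    noise_cv: 0.05
    seed: 3303
  - type: chase
    variant: F68A_E129A
    n_molecules: 500
    noise_cv: 0.05
    seed: 3304
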