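name: distance_series
# Chi-free substrates with the triplex reporter at increasing distances from
# the entry point: the latch mutant's spontaneous isomerization to the slow
# state drains the first-phase amplitude with distance; the wild type does
# not.
seed: 660
substrates:
  chifree_1000: {length_bp: 2500, triplex_pos: 1000}
  chifree_2000: {length_bp: 3500, triplex_pos: 2000}
  chifree_3000: {length_bp: 4500, triplex_pos: 3000}
  chifree_4000: {length_bp: 5500, triplex_pos: 4000}
assays:
  - type: triplex
    variant: E129A_37C
    substrate: chifree_1000
    n_molecules: 2000
    seed: 6601
  - type: triplex
    variant: E129A_37C
    substrate: chifree_2000
    n_molecules: 2000
    seed: 6602
  - type: triplex
    variant: E129A_37C
    substrate: chifree_3000
    n_molecules: 2000
    seed: 6603
  - type: triplex
    variant: E129A_37C
    substrate: chifree_4000
    n_molecules: 2000
    seed: 6604
  - type: triplex
    variant: wildtype_37C
    substrate: chifree_1000
    n_molecules: 2000
    seed: 6605
  - type: triplex
    variant: wildtype_37C
    substrate: chifree_4000
    n_molecules: 2000
    seed: 6606
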