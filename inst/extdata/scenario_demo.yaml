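# Small synthetic scenario: 3 sites x 5 temperature levels x 4 individuals.
mode: synthetic
seed: 7
alpha: 0.05
params:
  n_per_cell: 4
  sigma_ln: 0.15
  b0: 0.75
  e0: 0.40
  e_mass_slope: -0.12
sites:
  - site: Acquatina
    t_max_c: 27.4
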