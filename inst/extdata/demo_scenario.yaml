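# Demo scenario: three homomeric receptor isoforms in separate wells
# (EC50 medians 10.1 / 49 / 186 uM), a drug-shifted well, and a phenotype
# classification block trained on pure populations with true medians
# 190 vs 32 uM and applied to their 1:1 mixture.
seed: 1
mode: trace
populations:
  alpha1:
    ec50_median: 10.1
    ec50_log_sd: 0.15
    slope_range: [0.5, 1.9]
    dF_range: [25, 90]
    fraction_responders: 0.85
    n_cells: 150
  alpha2:
    ec50_median: 49
    ec50_log_sd: 0.15
    slope_range: [0.5, 4.7]
    dF_range: [25, 90]
    fraction_responders: 0.85
    n_cells: 150
  alpha3:
    ec50_median: 186
    ec50_log_sd: 0.15
    slope_range: [0.5, 3.4]
    dF_range: [25, 90]
    fraction_responders: 0.85
    n_cells: 150
  alpha2_lindane:            # homomer under 10 uM lindane: EC50 shifted up
    ec50_median: 190
    ec50_log_sd: 0.15
    slope_range: [0.5, 4.7]
    dF_range: [25, 90]
    fraction_responders: 0.85
    n_cells: 200
  alpha2beta_lindane:        # heteromer is lindane-insensitive
    ec50_median: 32
    ec50_log_sd: 0.15
    slope_range: [0.5, 4.7]
    dF_range: [25, 90]
    fraction_responders: 0.85
    n_cells: 200
wells:
  - well: A1
    populations: [alpha1]
  - well: A2
    populations: [alpha2]
  - well: A3
    populations: [alpha3]
  - well: B1
    populations: [alpha2_lindane]
  - well: B2
    populations: [alpha2beta_lindane]
  - well: B3
    populations: [alpha2_lindane, alpha2beta_lindane]
    fractions: [0.5, 0.5]
    n_cells: 300
annotations:
  - {well: A1, population: alpha1, drug: none, drug_conc: 0}
  - {well: A2, population: alpha2, drug: none, drug_conc: 0}
  - {well: A3, population: alpha3, drug: none, drug_conc: 0}
  - {well: B1, population: alpha2_lindane, drug: lindane, drug_conc: 10}
  - {well: B2, population: alpha2beta_lindane, drug: lindane, drug_conc: 10}
  - {well: B3, population: mixed, drug: lindane, drug_conc: 10}
classify:
  train_wells: [B1, B2]
  test_wells: [B3]
  folds: 10
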