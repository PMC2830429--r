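# Example run configuration for the eacsim command-line interface.
seed: 1
output_dir: eacsim-out
years: [1986]
max_age: 79

demography:
  # life_table: path/to/life_table.csv   # default: built-in Gompertz-Makeham
  cancer_mortality:
    undetected: 0.35
    detected: 0.35

# Explicit transition parameters, used by `simulate` and `make-synthetic`.
params:
  p_normal_gerd: [0.04, 0.004, 0.002, 0.002, 0.002, 0.002]
  p_normal_be: [0.0035, 0.0012, 0.001, 0.001, 0.001, 0.001]
  p_gerd_be: [0.002, 0.002, 0.002, 0.002, 0.002, 0.002]
  r_lsbe_ca: 0.006
  secular_slope: 0.05
  mean_sojourn_years: 4.5

targets:
  file: builtin           # the built-in representative-year targets, or a CSV path
  calibration_years: [1973, 2000]
  validation_years: [2001, 2005]

calibration:
  n_iterations: 10000
  order: forward
  final_fraction: 0.01

intervention:
  five_year_reduction: 0.5
  start_year: 1960
  start_age: 40

synthetic:
  noise_cv: 0
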