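# Shared fixtures, all built in code.

# flat mortality makes closed-form checks easy
flat_life_table <- function(q = 0.01, ages = 20:100) {
  tibble::tibble(age = ages, q = q)
}

flat_demography <- function(q = 0.01, cancer_q = 0.35) {
  eac_demography(life_table = flat_life_table(q),
                 cancer_mortality = c(undetected = cancer_q,
                                      detected = cancer_q))
}

# a plausible full-scale parameter set
example_params <- function(secular_slope = 0.05) {
  transition_params(
    p_normal_gerd = c(0.04, 0.004, 0.002, 0.002, 0.002, 0.002),
    p_normal_be = c(0.0035, 0.0012, 0.001, 0.001, 0.001, 0.001),
    p_gerd_be = 0.002,
    r_lsbe_ca = 0.006,
    secular_slope = secular_slope,
    mean_sojourn_years = 4.5
  )
}

# ground truth for the three-age-group recovery experiments (ages 20-49)
recovery_truth <- function() {
  transition_params(
    p_normal_gerd = c(0.035, 0.004, 0.002, 0, 0, 0),
    p_normal_be = c(0.003, 0.0012, 0.001, 0, 0, 0),
    p_gerd_be = c(0.002, 0.0025, 0.003, 0, 0, 0),
    r_lsbe_ca = 0.008,
    secular_slope = 0.05,
    mean_sojourn_years = 5
  )
}

recovery_years <- function() 1973:1982

recovery_targets <- function(noise_cv = 0, seed = 1L) {
  generate_synthetic_targets(
    recovery_truth(), calibration_years = recovery_years(),
    demography = eac_demography(), noise_cv = noise_cv, seed = seed,
    max_age = 49L
  )
}
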