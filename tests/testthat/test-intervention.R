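test_that("five-year to annual hazard conversion matches its closed form", {
  expect_equal(annual_reduction_from_five_year(0.5), 0.12945,
               tolerance = 1e-4)
  expect_equal(annual_reduction_from_five_year(0.5), 1 - 0.5^(1 / 5),
               tolerance = 1e-12)
  expect_equal(annual_reduction_from_five_year(0), 0)
  expect_equal(annual_reduction_from_five_year(0.7), 1 - 0.3^0.2,
               tolerance = 1e-12)
  expect_equal(annual_reduction_from_five_year(0.7), 0.21400,
               tolerance = 1e-4)

  # inverse property across the whole grid
  R5 <- seq(0, 0.95, by = 0.05)
  r <- annual_reduction_from_five_year(R5)
  expect_equal((1 - r)^5, 1 - R5, tolerance = 1e-12)

  expect_error(annual_reduction_from_five_year(1), "\\[0, 1\\)")
  expect_error(annual_reduction_from_five_year(-0.1), "\\[0, 1\\)")
})

test_that("eligibility gates the hazard reduction by age and calendar year", {
  p <- transition_params(0, 0, 0, r_lsbe_ca = 0.01)
  iv <- intervention_spec(0.5, start_year = 1960, start_age = 40)
  m_active <- build_transition_matrix(p, 45, 1970, 0, 0, intervention = iv)
  m_young <- build_transition_matrix(p, 35, 1970, 0, 0, intervention = iv)
  m_early <- build_transition_matrix(p, 45, 1955, 0, 0, intervention = iv)
  expect_equal(m_active["BE_LSBE", "UNDETECTED_CA"],
               0.01 * (1 - iv$annual_reduction), tolerance = 1e-12)
  expect_equal(m_young["BE_LSBE", "UNDETECTED_CA"], 0.01)
  expect_equal(m_early["BE_LSBE", "UNDETECTED_CA"], 0.01)
  # both segments are reduced by the same multiplier
  expect_equal(m_active["BE_SSBE", "UNDETECTED_CA"] /
                 m_active["BE_LSBE", "UNDETECTED_CA"], 0.5,
               tolerance = 1e-12)
})

test_that("report-table accounting reproduces the published tallies", {
  periods <- tibble::tibble(
    start = c(1975L, 1981L, 1986L, 1991L, 1996L, 2001L),
    end = c(1980L, 1985L, 1990L, 1995L, 2000L, 2005L)
  )
  original <- c(2310, 4987, 8668, 13045, 17997, 24071)
  prevented <- c(235, 528, 904, 1315, 1748, 2290)
  rep <- build_report_table(periods, original, prevented)

  # cumulative columns are exact running sums ...
  expect_identical(rep$cumulative_original, cumsum(original))
  expect_identical(rep$cumulative_prevented, cumsum(prevented))
  # ... and agree with the published cumulative rows, whose later cells
  # carry a one-unit rounding discrepancy from independently rounded means
  expect_true(all(abs(rep$cumulative_original -
                        c(2310, 7297, 15964, 29009, 47006, 71077)) <= 1))
  expect_equal(rep$cumulative_prevented[2], 763)
  expect_equal(rep$cumulative_prevented[6], 7020)
  expect_equal(round(rep$percent_reduction[1], 1), 10.2)
  expect_true(all(rep$prevented_cases <= rep$original_cases))

  bad <- periods[c(2, 1, 3:6), ]
  expect_error(build_report_table(bad, original, prevented), "ordered")
})

test_that("counterfactual runs prevent cases monotonically in the effect size", {
  p <- example_params()
  ens <- tibble::as_tibble(as.list(params_to_vector(p)))
  periods <- tibble::tibble(start = c(1975L, 1980L), end = c(1979L, 1984L))
  dem <- eac_demography()

  # no effect, no prevention
  rep0 <- run_counterfactual(ens, intervention_spec(0), dem, periods)
  expect_equal(rep0$prevented_cases, c(0, 0), tolerance = 1e-12)

  rep <- run_counterfactual(ens, intervention_spec(0.5), dem, periods)
  expect_true(all(rep$prevented_cases > 0))
  # a single parameter set collapses the range onto the point estimate
  expect_equal(rep$prevented_lo, rep$prevented_cases)
  expect_equal(rep$prevented_hi, rep$prevented_cases)
  # dilution: the percent reduction stays below the annual hazard reduction
  expect_true(all(rep$percent_reduction <
                    100 * annual_reduction_from_five_year(0.5)))

  # counterfactual incidence never exceeds baseline, pointwise
  iv <- intervention_spec(0.5)
  base <- simulate_population(p, 1975:1984, dem)
  trt <- simulate_population(p, 1975:1984, dem, intervention = iv)
  expect_true(all(trt$eac_incidence <= base$eac_incidence + 1e-12))

  sweep <- sensitivity_sweep(ens, c(0.3, 0.5, 0.7), dem, periods)
  expect_equal(nrow(sweep), 6L)
  by_period <- split(sweep$prevented_cases, sweep$period)
  for (v in by_period) expect_true(all(diff(v) > 0))

  # a singleton sweep is just run_counterfactual
  single <- sensitivity_sweep(ens, 0.5, dem, periods)
  expect_equal(single$prevented_cases, rep$prevented_cases)
  expect_equal(nrow(sensitivity_sweep(ens, numeric(0))), 0L)
})

test_that("multi-member ensembles report ranges around the mean", {
  v <- params_to_vector(example_params())
  v2 <- v
  v2[["r_lsbe_ca"]] <- v[["r_lsbe_ca"]] * 1.5
  ens <- dplyr::bind_rows(tibble::as_tibble(as.list(v)),
                          tibble::as_tibble(as.list(v2)))
  periods <- tibble::tibble(start = 1980L, end = 1984L)
  rep <- run_counterfactual(ens, intervention_spec(0.5), eac_demography(),
                            periods)
  expect_lte(rep$prevented_lo, rep$prevented_cases)
  expect_gte(rep$prevented_hi, rep$prevented_cases)
  expect_lt(rep$prevented_lo, rep$prevented_hi)
})
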