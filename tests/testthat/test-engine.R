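test_that("transition matrix reproduces closed-form entries", {
  # no events at all -> identity on every state mass can reach (detection
  # out of undetected cancer is structurally positive because the mean
  # sojourn time is bounded; with zero feeder transitions that state is
  # never entered)
  p0 <- transition_params(0, 0, 0, r_lsbe_ca = 0)
  M0 <- build_transition_matrix(p0, 30, 1980, all_cause_q = 0, cancer_q = 0)
  reach <- c(1:4, 6:7)
  expect_equal(unname(M0[reach, ]), diag(7)[reach, ], tolerance = 1e-15)
  coh0 <- simulate_cohort(p0, 1950, flat_life_table(0), 0, 2010)
  expect_equal(coh0$occupancy[nrow(coh0$occupancy), ],
               setNames(c(1, 0, 0, 0, 0, 0, 0), health_states()))

  p <- example_params()
  M <- build_transition_matrix(p, 55, 1993, all_cause_q = 0.01,
                               cancer_q = 0.35)
  expect_equal(rowSums(M), setNames(rep(1, 7), health_states()),
               tolerance = 1e-12)
  # detection from a 4.5-year mean sojourn: 1 - exp(-1/4.5)
  expect_equal(M["UNDETECTED_CA", "DETECTED_CA"],
               (1 - 0.35) * (1 - exp(-1 / 4.5)), tolerance = 1e-12)
  expect_equal(1 - exp(-1 / 4.5), 0.19926, tolerance = 1e-4)

  # secular trend arithmetic: r = 0.01, slope 0.05, year 1993 -> x2 for LSBE
  ps <- transition_params(0, 0, 0, r_lsbe_ca = 0.01, secular_slope = 0.05)
  Ms <- build_transition_matrix(ps, 60, 1993, all_cause_q = 0, cancer_q = 0)
  expect_equal(Ms["BE_LSBE", "UNDETECTED_CA"], 0.02, tolerance = 1e-12)
  expect_equal(Ms["BE_SSBE", "UNDETECTED_CA"], 0.01, tolerance = 1e-12)

  # negative multiplier clamps at zero
  pneg <- transition_params(0, 0, 0, r_lsbe_ca = 0.01, secular_slope = 0.05)
  Mn <- build_transition_matrix(pneg, 60, 1930, all_cause_q = 0, cancer_q = 0)
  expect_equal(Mn["BE_LSBE", "UNDETECTED_CA"], 0)

  # incident BE splits 1:3 long:short
  pn <- transition_params(0, 0.04, 0, r_lsbe_ca = 0)
  Mb <- build_transition_matrix(pn, 30, 1980, all_cause_q = 0, cancer_q = 0)
  expect_equal(Mb["NORMAL", "BE_LSBE"] / Mb["NORMAL", "BE_SSBE"], 1 / 3,
               tolerance = 1e-12)

  expect_error(build_transition_matrix(p, 30, 1980, all_cause_q = 1.5,
                                       cancer_q = 0.35), "\\[0, 1\\]")
})

test_that("states never regress: mass only moves forward", {
  p <- example_params()
  M <- build_transition_matrix(p, 45, 1990, all_cause_q = 0.01,
                               cancer_q = c(0.3, 0.4))
  for (i in 2:6) {
    expect_true(all(M[i, 1:(i - 1)] == 0),
                label = paste("no backward flow from state", i))
  }
  expect_equal(M["DEATH", ], setNames(c(0, 0, 0, 0, 0, 0, 1),
                                      health_states()))
})

test_that("cohort trajectories conserve mass and match the matrix-power oracle", {
  p <- example_params(secular_slope = 0)  # constant rates
  lt <- flat_life_table(0.01)
  # make age-group rates constant so the annual matrix is constant
  pc <- transition_params(0.01, 0.002, 0.003, r_lsbe_ca = 0.006,
                          secular_slope = 0, mean_sojourn_years = 6)
  coh <- simulate_cohort(pc, 1930, lt, c(0.35, 0.35), 2010)

  expect_equal(rowSums(coh$occupancy), rep(1, nrow(coh$occupancy)),
               tolerance = 1e-10)
  expect_true(all(diff(coh$occupancy[, "DEATH"]) >= 0))
  expect_true(all(coh$new_detections >= 0))
  expect_lte(sum(coh$new_detections), 1)

  # matrix-power oracle over 60 cycles
  M <- build_transition_matrix(pc, 25, 1980, all_cause_q = 0.01,
                               cancer_q = 0.35)
  v <- c(1, 0, 0, 0, 0, 0, 0)
  for (t in 1:60) {
    v <- as.numeric(v %*% M)
    expect_lt(max(abs(coh$occupancy[t + 1, ] - v)), 1e-10)
  }
})

test_that("pure mortality gives geometric decay of the normal state", {
  p0 <- transition_params(0, 0, 0, r_lsbe_ca = 0)
  coh <- simulate_cohort(p0, 1950, flat_life_table(0.1), 0, 2000)
  expect_equal(coh$occupancy[, "NORMAL"], 0.9^(0:30), tolerance = 1e-12)

  # zero everything -> stays put forever
  coh0 <- simulate_cohort(p0, 1950, flat_life_table(0), 0, 2000)
  expect_equal(coh0$occupancy[, "NORMAL"], rep(1, 31))
})

test_that("cohort entry and life-table support are enforced", {
  p <- example_params()
  expect_error(simulate_cohort(p, 2000, flat_life_table(), 0.35, 2005),
               "birth_year")
  expect_error(simulate_cohort(p, 1950, flat_life_table(ages = 20:60),
                               0.35, 2040), "life table")
})

test_that("population cross-sections aggregate cohorts consistently", {
  p <- example_params(secular_slope = 0)
  dem <- flat_demography()
  pop <- simulate_population(p, 1980:1985, dem)
  expect_s3_class(pop, "eac_population")
  expect_equal(nrow(pop), 6 * 6)
  expect_true(all(pop$gerd_prev >= 0 & pop$gerd_prev <= 100))
  expect_true(all(pop$be_prev >= 0 & pop$be_prev <= 100))
  expect_true(all(pop$eac_incidence >= 0))

  # age-constant parameters + stationary demography + zero slope:
  # identical cross-sections every calendar year
  pc <- transition_params(0.01, 0.002, 0.003, r_lsbe_ca = 0.006,
                          secular_slope = 0)
  popc <- simulate_population(pc, 1980:1990, dem)
  one_year <- dplyr::filter(popc, year == 1980)
  for (y in 1981:1990) {
    expect_equal(dplyr::filter(popc, year == y)$eac_incidence,
                 one_year$eac_incidence, tolerance = 1e-12)
    expect_equal(dplyr::filter(popc, year == y)$be_prev,
                 one_year$be_prev, tolerance = 1e-12)
  }
})

test_that("population output matches single-cohort aggregation in a one-group world", {
  # only the 20-29 group: population restricted to max_age 29
  p <- example_params(secular_slope = 0)
  dem <- flat_demography(q = 0.02)
  pop <- simulate_population(p, 1990, dem, max_age = 29L)
  expect_equal(unique(pop$age_group), "20-29")

  # rebuild the same cross-section from ten stacked cohorts
  occ <- sapply(0:9, function(a) {
    coh <- simulate_cohort(p, 1990 - 20 - a, flat_life_table(0.02),
                           c(0.35, 0.35), 1990)
    coh$occupancy[nrow(coh$occupancy), ]
  })
  alive <- sum(1 - occ["DEATH", ])
  be <- sum(occ["BE_SSBE", ] + occ["BE_LSBE", ])
  gerd <- sum(occ["GERD", ])
  expect_equal(pop$be_prev, 100 * be / alive, tolerance = 1e-10)
  expect_equal(pop$gerd_prev, 100 * gerd / alive, tolerance = 1e-10)
})

test_that("a positive secular slope makes age-adjusted incidence rise", {
  p <- example_params(secular_slope = 0.05)
  dem <- flat_demography()
  pop <- simulate_population(p, 1975:1995, dem)
  adj <- age_adjusted_incidence(pop)
  expect_true(all(diff(adj$age_adjusted_incidence) > 0))

  # and the flat-slope model stays flat
  adj0 <- age_adjusted_incidence(
    simulate_population(example_params(secular_slope = 0), 1975:1995, dem)
  )
  expect_equal(diff(range(adj0$age_adjusted_incidence)), 0, tolerance = 1e-9)
})

test_that("requesting years before the populated window errors", {
  p <- example_params()
  lt <- flat_life_table()
  dem <- eac_demography(life_table = flat_life_table(ages = 20:60))
  expect_error(simulate_population(p, 1990, dem), "life table")
})

test_that("the undetected-cancer mortality switch applies all-cause mortality", {
  p <- example_params()
  dem_sw <- eac_demography(cancer_mortality = c(undetected = NA,
                                                detected = 0.35))
  pop_sw <- simulate_population(p, 1986, dem_sw)
  pop_def <- simulate_population(p, 1986, eac_demography())
  # background mortality is far below 0.35/yr, so more undetected cancers
  # survive to clinical detection
  expect_true(all(pop_sw$eac_incidence > pop_def$eac_incidence))

  M <- build_transition_matrix(p, 50, 1980, 0.02, c(NA, 0.35))
  expect_equal(M["UNDETECTED_CA", "DEATH"], 0.02)
  expect_equal(M["DETECTED_CA", "DEATH"], 0.35)
})
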