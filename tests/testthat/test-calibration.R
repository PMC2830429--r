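test_that("three-phase calibration mechanics hold at tiny scale", {
  tg <- recovery_targets(noise_cv = 0.1, seed = 3)
  cfg <- sa_config(n_iterations = 300, seed = 5)
  cal <- three_phase_calibrate(tg, config = cfg)

  # ensemble: 1% of the final phase, ranked ascending on the combined score
  expect_equal(nrow(cal$ensemble), round(0.01 * 300))
  expect_true(!is.unsorted(cal$ensemble$gof_total))
  expect_equal(cal$ensemble$gof_total,
               cal$ensemble$gof_GERD_PREV + cal$ensemble$gof_BE_PREV +
                 cal$ensemble$gof_EAC_INCIDENCE)
  expect_equal(cal$endpoints, c("GERD_PREV", "BE_PREV", "EAC_INCIDENCE"))

  # a larger final fraction keeps proportionally more sets
  cal5 <- three_phase_calibrate(tg, config = cfg, final_fraction = 0.05)
  expect_equal(nrow(cal5$ensemble), round(0.05 * 300))

  # phase bounds nest monotonically
  for (k in 2:3) {
    b_prev <- cal$phases[[k - 1]]$bounds
    b_k <- cal$phases[[k]]$bounds
    expect_true(all(b_k$lower >= b_prev$lower - 1e-12))
    expect_true(all(b_k$upper <= b_prev$upper + 1e-12))
  }

  # reverse order flips the endpoint sequence
  calr <- three_phase_calibrate(tg, config = cfg, order = "reverse")
  expect_equal(calr$endpoints, c("EAC_INCIDENCE", "BE_PREV", "GERD_PREV"))

  # full determinism under a fixed seed
  cal2 <- three_phase_calibrate(tg, config = cfg)
  expect_identical(cal$ensemble$gof_total, cal2$ensemble$gof_total)
  expect_identical(best_params(cal), best_params(cal2))
})

test_that("calibration refuses target sets missing an endpoint", {
  tg <- recovery_targets()
  partial <- eac_targets(
    dplyr::filter(tibble::as_tibble(tg), endpoint != "BE_PREV"),
    calibration_years = target_years(tg)
  )
  expect_error(three_phase_calibrate(partial), "BE_PREV")
})

test_that("the generating truth scores zero and anchors the objective", {
  tg <- recovery_targets(noise_cv = 0)
  obj <- eacsim:::make_gof_objective(tg, eac_demography(), NULL,
                                     recovery_years(), 49L)
  truth_v <- params_to_vector(recovery_truth())
  free <- default_bounds(n_groups = 3)$param
  expect_equal(sum(obj(truth_v[free])), 0, tolerance = 1e-12)
  # any perturbation scores worse
  pert <- truth_v[free]
  pert[["r_lsbe_ca"]] <- pert[["r_lsbe_ca"]] * 2
  expect_gt(sum(obj(pert)), 0)
})

test_that("hold-out validation computes adjusted scores and the 150% criterion", {
  tg <- generate_synthetic_targets(
    recovery_truth(), calibration_years = 1973:1982,
    validation_years = 1983:1984, noise_cv = 0.1, seed = 31, max_age = 49L
  )
  # two-member ensemble: the truth and a perturbed copy
  v <- params_to_vector(recovery_truth())
  ens <- dplyr::bind_rows(
    tibble::as_tibble(as.list(v)),
    tibble::as_tibble(as.list(v * c(rep(1, 18), 1.3, 1, 1)))
  )
  rep <- validate_calibration(ens, tg)

  expect_equal(nrow(rep$members), 2L)
  expect_equal(rep$n_calibration_years, 10L)
  expect_equal(rep$n_validation_years, 2L)
  # adjusted = raw GOF / number of years, averaged over members
  expect_equal(rep$adjusted_gof_calibration,
               mean(rep$members$gof_calibration / 10))
  expect_equal(rep$adjusted_gof_validation,
               mean(rep$members$gof_validation / 2))
  expect_equal(rep$ratio,
               rep$adjusted_gof_validation / rep$adjusted_gof_calibration)
  expect_identical(rep$passed,
                   rep$adjusted_gof_validation <
                     1.5 * rep$adjusted_gof_calibration)

  # refusal without validation targets
  expect_error(validate_calibration(ens, recovery_targets()),
               "no validation years")
  expect_error(validate_calibration(ens[0, ], tg), "empty ensemble")
})

test_that("tidy and glance summarise a calibration", {
  cal <- three_phase_calibrate(recovery_targets(noise_cv = 0.1, seed = 3),
                               config = sa_config(n_iterations = 200,
                                                  seed = 5))
  td <- tidy(cal)
  expect_true(all(c("parameter", "best", "min", "median", "max") %in%
                    names(td)))
  expect_true(all(td$min <= td$best & td$best <= td$max))
  gl <- glance(cal)
  expect_equal(gl$ensemble_size, nrow(cal$ensemble))
  expect_equal(gl$gof_total, cal$ensemble$gof_total[1])
})
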