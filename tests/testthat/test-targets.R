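test_that("representative-year fixture carries the published target values", {
  tg <- representative_year_targets()
  expect_s3_class(tg, "eac_targets")
  expect_equal(nrow(tg), 18L)
  expect_equal(target_years(tg), 1986L)

  get <- function(e, g) {
    sub <- tg[tg$endpoint == e, ]
    sub$value[match(g, sub$age_group)]
  }
  expect_identical(get("EAC_INCIDENCE", age_groups()),
                   c(0.0, 0.3, 0.6, 3.3, 7.4, 9.3))
  expect_identical(get("BE_PREV", age_groups()),
                   c(1.7, 2.5, 3.3, 4.1, 5.0, 5.8))
  expect_identical(get("GERD_PREV", age_groups()),
                   c(17.6, 18.0, 18.4, 18.8, 19.1, 19.5))
  expect_equal(get("EAC_INCIDENCE", "50-59"), 3.3)
  expect_equal(get("BE_PREV", "20-29"), 1.7)

  # prevalence rows are time-constant, incidence rows dated
  expect_true(all(is.na(tg$year[tg$endpoint != "EAC_INCIDENCE"])))
  expect_true(all(tg$year[tg$endpoint == "EAC_INCIDENCE"] == 1986L))
})

test_that("target-set constructor enforces its contracts", {
  base <- tibble::tibble(endpoint = "BE_PREV", year = NA_integer_,
                         age_group = "20-29", value = 2, role = "CALIBRATION")
  expect_error(eac_targets(dplyr::mutate(base, endpoint = "X"), 1986),
               "unknown endpoint")
  expect_error(eac_targets(dplyr::mutate(base, age_group = "80+"), 1986),
               "age group")
  expect_error(eac_targets(dplyr::mutate(base, value = -1), 1986), ">= 0")
  expect_error(
    eac_targets(dplyr::mutate(base, endpoint = "EAC_INCIDENCE"), 1986),
    "explicit years"
  )
  expect_error(eac_targets(base, 1990:2000, 1995:2005), "disjoint")
})

test_that("synthetic targets reproduce the generating model exactly at zero noise", {
  truth <- recovery_truth()
  tg <- recovery_targets(noise_cv = 0)
  pop <- simulate_population(truth, recovery_years(), eac_demography(),
                             max_age = 49L)
  expect_equal(sort(unique(tg$age_group)), age_groups()[1:3])

  joined <- dplyr::left_join(
    tibble::as_tibble(tg), population_long(pop),
    by = c("endpoint", "year", "age_group")
  )
  expect_equal(joined$value.x, joined$value.y, tolerance = 1e-12)
  # hence the truth scores a GOF of zero
  expect_equal(gof_total(chi_square_gof(pop, tg)), 0, tolerance = 1e-12)
})

test_that("synthetic noise is seeded, reproducible and monotone in the trend", {
  a <- recovery_targets(noise_cv = 0.1, seed = 42)
  b <- recovery_targets(noise_cv = 0.1, seed = 42)
  expect_identical(a$value, b$value)
  c2 <- recovery_targets(noise_cv = 0.1, seed = 43)
  expect_false(identical(a$value, c2$value))
  expect_error(recovery_targets(noise_cv = -1), "noise_cv")

  # positive secular slope in the truth -> incidence targets rise per group
  inc <- dplyr::filter(tibble::as_tibble(recovery_targets(noise_cv = 0)),
                       endpoint == "EAC_INCIDENCE")
  for (g in unique(inc$age_group)) {
    v <- inc$value[inc$age_group == g][order(inc$year[inc$age_group == g])]
    expect_true(all(diff(v) > 0), label = paste("rising incidence in", g))
  }
})

test_that("incidence CSV reader validates shape and values", {
  path <- withr::local_tempfile(fileext = ".csv")
  grid <- tidyr::expand_grid(year = 1973:2000, age_group = age_groups())
  grid$rate_per_100k <- seq_len(nrow(grid)) / 10
  readr::write_csv(grid, path)
  got <- load_incidence_csv(path)
  expect_equal(nrow(got), 168L)
  expect_true(all(got$endpoint == "EAC_INCIDENCE"))

  bad <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(dplyr::mutate(grid, rate_per_100k =
                                   replace(rate_per_100k, 3, -1)), bad)
  expect_error(load_incidence_csv(bad), "row\\(s\\) 3")

  badlab <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(dplyr::mutate(grid, age_group =
                                   replace(age_group, 5, "20-30")), badlab)
  expect_error(load_incidence_csv(badlab), "age group")
})

test_that("target CSV io is an exact round-trip", {
  tg <- representative_year_targets()
  path <- withr::local_tempfile(fileext = ".csv")
  write_targets_csv(tg, path)
  back <- load_targets_csv(path, calibration_years = 1986L,
                           validation_years = integer(0))
  expect_equal(tibble::as_tibble(back), tibble::as_tibble(tg))
  expect_equal(target_years(back), target_years(tg))
})
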