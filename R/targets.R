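# Calibration / validation targets and the synthetic-target generator.

EAC_ENDPOINTS <- c("GERD_PREV", "BE_PREV", "EAC_INCIDENCE")
EAC_ROLES <- c("CALIBRATION", "VALIDATION")

#' Construct a target set
#'
#' A target set is a tibble of endpoint values (`GERD_PREV` and `BE_PREV` in
#' percent, `EAC_INCIDENCE` per 100,000) indexed by calendar year and
#' ten-year age group, with a `role` marking each target as a calibration or
#' hold-out validation target. Prevalence targets may carry `year = NA`,
#' meaning "constant over calendar time": they expand to every calibration
#' year when scored. Incidence targets must carry explicit years.
#'
#' @param targets Tibble with columns `endpoint`, `year` (integer or `NA`),
#'   `age_group`, `value`, `role`.
#' @param calibration_years Integer vector of calibration years.
#' @param validation_years Integer vector of hold-out years (disjoint from
#'   the calibration years; may be empty).
#' @return Tibble of class `eac_targets` carrying the year ranges as
#'   attributes.
#' @export
eac_targets <- function(targets, calibration_years,
                        validation_years = integer(0)) {
  targets <- tibble::as_tibble(targets)
  need <- c("endpoint", "year", "age_group", "value", "role")
  if (!all(need %in% names(targets))) {
    stop("targets need columns ", paste(need, collapse = ", "), call. = FALSE)
  }
  if (!all(targets$endpoint %in% EAC_ENDPOINTS)) {
    stop("unknown endpoint(s): ",
         paste(setdiff(targets$endpoint, EAC_ENDPOINTS), collapse = ", "),
         call. = FALSE)
  }
  if (!all(targets$role %in% EAC_ROLES)) {
    stop("role must be CALIBRATION or VALIDATION", call. = FALSE)
  }
  bad_group <- setdiff(targets$age_group, EAC_AGE_GROUPS)
  if (length(bad_group)) {
    stop("unknown age group label(s): ", paste(bad_group, collapse = ", "),
         call. = FALSE)
  }
  if (any(targets$value < 0)) stop("target values must be >= 0", call. = FALSE)
  if (any(is.na(targets$year) & targets$endpoint == "EAC_INCIDENCE")) {
    stop("incidence targets must carry explicit years", call. = FALSE)
  }
  calibration_years <- sort(unique(as.integer(calibration_years)))
  validation_years <- sort(unique(as.integer(validation_years)))
  if (length(intersect(calibration_years, validation_years))) {
    stop("calibration and validation years must be disjoint", call. = FALSE)
  }
  structure(targets,
            calibration_years = calibration_years,
            validation_years = validation_years,
            class = c("eac_targets", class(targets)))
}

#' @export
print.eac_targets <- function(x, ...) {
  cy <- attr(x, "calibration_years")
  vy <- attr(x, "validation_years")
  cat("<eac_targets> ", nrow(x), " targets; calibration years ",
      min(cy), "-", max(cy),
      if (length(vy)) paste0("; validation years ", min(vy), "-", max(vy)),
      "\n", sep = "")
  NextMethod()
}

#' Years attached to a target set
#'
#' @param targets An [eac_targets()] object.
#' @param role `"CALIBRATION"` or `"VALIDATION"`.
#' @return Integer vector of years.
#' @export
target_years <- function(targets, role = "CALIBRATION") {
  role <- match.arg(role, EAC_ROLES)
  if (role == "CALIBRATION") attr(targets, "calibration_years")
  else attr(targets, "validation_years")
}

# Expand time-constant (year = NA) prevalence targets to one row per year of
# the role's year range; incidence targets pass through unchanged.
expand_targets <- function(targets, role = "CALIBRATION") {
  role <- match.arg(role, EAC_ROLES)
  yrs <- target_years(targets, role)
  sub <- dplyr::filter(targets, .data$role == !!role)
  const <- dplyr::filter(sub, is.na(.data$year))
  dated <- dplyr::filter(sub, !is.na(.data$year))
  if (nrow(const)) {
    const <- tidyr::crossing(dplyr::select(const, -"year"), year = yrs)
  }
  dplyr::bind_rows(dated, const) |>
    dplyr::select("endpoint", "year", "age_group", "value", "role")
}

#' The representative-year (1986) calibration targets
#'
#' The in-package calibration fixture: age-specific EAC incidence (per
#' 100,000), Barrett's-esophagus prevalence and GERD-symptom prevalence
#' (percent) for the six ten-year age groups in 1986, the midpoint of the
#' 1973-2000 calibration window. The prevalence rows are marked
#' time-constant (`year = NA`); the incidence row is anchored to 1986, and
#' the fixture's calibration window is that single representative year.
#'
#' @return An [eac_targets()] object with 18 calibration targets.
#' @examples
#' representative_year_targets()
#' @export
representative_year_targets <- function() {
  tb <- tibble::tibble(
    age_group = EAC_AGE_GROUPS,
    EAC_INCIDENCE = c(0.0, 0.3, 0.6, 3.3, 7.4, 9.3),
    BE_PREV = c(1.7, 2.5, 3.3, 4.1, 5.0, 5.8),
    GERD_PREV = c(17.6, 18.0, 18.4, 18.8, 19.1, 19.5)
  ) |>
    tidyr::pivot_longer(-"age_group", names_to = "endpoint",
                        values_to = "value") |>
    dplyr::mutate(
      year = ifelse(.data$endpoint == "EAC_INCIDENCE", 1986L, NA_integer_),
      role = "CALIBRATION"
    ) |>
    dplyr::select("endpoint", "year", "age_group", "value", "role")
  eac_targets(tb, calibration_years = 1986L)
}

#' Generate synthetic SEER-like targets from a known ground truth
#'
#' Runs the population model under a known parameter set and emits its
#' outputs as a target set, optionally perturbed by multiplicative lognormal
#' observation noise with mean 1 and coefficient of variation `noise_cv`
#' (rates are positive and SEER-style sampling error scales roughly with the
#' rate). With `noise_cv = 0` the targets equal the model outputs exactly,
#' so the generating truth has zero goodness-of-fit by construction - the
#' basis of the parameter-recovery tests. All three endpoints are emitted
#' per year and age group with explicit years.
#'
#' @param true_params The generating [transition_params()].
#' @param calibration_years,validation_years Calendar years to emit, tagged
#'   with the corresponding role.
#' @param demography An [eac_demography()] object.
#' @param noise_cv Coefficient of variation of the lognormal observation
#'   noise (`>= 0`; 0 = noise-free).
#' @param seed Integer seed for the noise draws; the same seed reproduces
#'   the same target set.
#' @param max_age Oldest modeled age (restricts the emitted age groups).
#' @return An [eac_targets()] object.
#' @export
generate_synthetic_targets <- function(true_params, calibration_years,
                                       validation_years = integer(0),
                                       demography = eac_demography(),
                                       noise_cv = 0, seed = 1L,
                                       max_age = 79L) {
  if (!is.finite(noise_cv) || noise_cv < 0) {
    stop("noise_cv must be >= 0", call. = FALSE)
  }
  years <- c(calibration_years, validation_years)
  pop <- simulate_population(true_params, years, demography,
                             max_age = max_age)
  tb <- population_long(pop) |>
    dplyr::mutate(role = ifelse(.data$year %in% validation_years,
                                "VALIDATION", "CALIBRATION"))
  if (noise_cv > 0) {
    sdlog <- sqrt(log1p(noise_cv^2))
    tb$value <- withr_seed(seed, {
      tb$value * stats::rlnorm(nrow(tb), meanlog = -sdlog^2 / 2, sdlog = sdlog)
    })
  }
  eac_targets(dplyr::select(tb, "endpoint", "year", "age_group", "value",
                            "role"),
              calibration_years = calibration_years,
              validation_years = validation_years)
}

# evaluate `expr` under a temporary RNG state seeded with `seed`
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Read an external age-specific incidence series
#'
#' Optional path for users who hold a SEER-style extract. Expects exactly
#' the columns `year`, `age_group`, `rate_per_100k`; rows with unknown
#' age-group labels or negative rates are rejected with their row number.
#'
#' @param path CSV path.
#' @param role `"CALIBRATION"` or `"VALIDATION"` tag for the loaded targets.
#' @return Tibble of `EAC_INCIDENCE` targets (not yet an [eac_targets()]
#'   set; combine and wrap with the prevalence targets of your analysis).
#' @export
load_incidence_csv <- function(path, role = "CALIBRATION") {
  role <- match.arg(role, EAC_ROLES)
  raw <- read_strict_csv(path, c(year = "i", age_group = "c",
                                 rate_per_100k = "d"))
  bad <- which(!raw$age_group %in% EAC_AGE_GROUPS)
  if (length(bad)) {
    stop(path, ": unknown age group label in row(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  bad <- which(raw$rate_per_100k < 0 | is.na(raw$rate_per_100k))
  if (length(bad)) {
    stop(path, ": negative or missing rate in row(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  tibble::tibble(endpoint = "EAC_INCIDENCE", year = raw$year,
                 age_group = raw$age_group, value = raw$rate_per_100k,
                 role = role)
}

#' Write / read a target set as tidy CSV
#'
#' Columns `endpoint`, `year` (`"ALL"` for time-constant prevalence
#' targets), `age_group`, `value`, `role`. The two functions are exact
#' inverses given the same year ranges.
#'
#' @param targets An [eac_targets()] object.
#' @param path CSV path.
#' @param calibration_years,validation_years Year ranges to attach on read.
#' @return `write_targets_csv()` returns `path` invisibly;
#'   `load_targets_csv()` returns an [eac_targets()] object.
#' @export
write_targets_csv <- function(targets, path) {
  out <- tibble::as_tibble(targets)
  out$year <- ifelse(is.na(out$year), "ALL", as.character(out$year))
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname write_targets_csv
#' @export
load_targets_csv <- function(path, calibration_years = 1973:2000,
                             validation_years = 2001:2005) {
  raw <- read_strict_csv(path, c(endpoint = "c", year = "c", age_group = "c",
                                 value = "d", role = "c"))
  yr <- suppressWarnings(as.integer(raw$year))
  if (any(is.na(yr) & raw$year != "ALL")) {
    stop(path, ": year must be an integer or 'ALL'", call. = FALSE)
  }
  eac_targets(
    tibble::tibble(endpoint = raw$endpoint, year = yr,
                   age_group = raw$age_group, value = raw$value,
                   role = raw$role),
    calibration_years = calibration_years,
    validation_years = validation_years
  )
}
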