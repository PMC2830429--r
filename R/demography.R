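# Mortality, standard-population weights and population counts.

#' Generate a Gompertz-Makeham life table
#'
#' Synthetic adult all-cause mortality: the annual death probability at age
#' `a` is `q(a) = 1 - exp(-(A + B * exp(theta * a)))`, capped at 1. This is a
#' documented stand-in for an empirical life table; any real table can be
#' loaded with [load_life_table()] instead. The defaults (`A = 5e-4`,
#' `B = 3e-5`, `theta = 0.09`) give plausible adult white-male mortality
#' (about 0.2%/yr at 40, 2%/yr at 70).
#'
#' @param A Age-independent (Makeham) hazard component, per year; `A >= 0`.
#' @param B Gompertz scale, per year; `B > 0`.
#' @param theta Gompertz log-slope, per year of age; `theta > 0`.
#' @param ages Integer ages covered (default 20 to 100).
#' @return Tibble with columns `age`, `q` of class `eac_life_table`.
#' @export
make_gompertz_life_table <- function(A = 5e-4, B = 3e-5, theta = 0.09,
                                     ages = 20:100) {
  if (!is.finite(A) || A < 0) stop("A must be >= 0", call. = FALSE)
  if (!is.finite(B) || B <= 0) stop("B must be > 0", call. = FALSE)
  if (!is.finite(theta) || theta <= 0) stop("theta must be > 0", call. = FALSE)
  tbl <- tibble::tibble(
    age = as.integer(ages),
    q = pmin(1, 1 - exp(-(A + B * exp(theta * ages))))
  )
  structure(tbl, class = c("eac_life_table", class(tbl)))
}

# internal: life table -> plain vector with age-range attributes
lifetable_vector <- function(life_table) {
  stopifnot(all(c("age", "q") %in% names(life_table)))
  lt <- life_table[order(life_table$age), ]
  v <- lt$q
  attr(v, "min_age") <- min(lt$age)
  attr(v, "max_age") <- max(lt$age)
  v
}

validate_life_table <- function(tbl, file = "life table") {
  if (nrow(tbl) == 0L) stop(file, " is empty", call. = FALSE)
  if (anyNA(tbl$age) || anyNA(tbl$q)) {
    stop(file, " contains missing values", call. = FALSE)
  }
  if (any(tbl$q < 0 | tbl$q > 1)) {
    stop(file, " has death probabilities outside [0, 1]", call. = FALSE)
  }
  ages <- sort(tbl$age)
  if (anyDuplicated(ages) || !identical(as.integer(ages),
                                        seq(min(ages), max(ages)))) {
    stop(file, " must cover contiguous integer ages without gaps",
         call. = FALSE)
  }
  invisible(tbl)
}

#' Read a life table from CSV
#'
#' Expects exactly the columns `age` and `annual_all_cause_probability`,
#' contiguous integer ages, and probabilities in `[0, 1]`. No interpolation
#' is performed; gaps are an error.
#'
#' @param path Path to a CSV file.
#' @return Tibble `age`, `q` of class `eac_life_table`.
#' @export
load_life_table <- function(path) {
  raw <- read_strict_csv(path, c(age = "i", annual_all_cause_probability = "d"))
  tbl <- tibble::tibble(age = raw$age, q = raw$annual_all_cause_probability)
  validate_life_table(tbl, file = path)
  structure(tbl, class = c("eac_life_table", class(tbl)))
}

#' Write a life table to CSV
#'
#' Inverse of [load_life_table()]; the written file round-trips through the
#' reader bit-identically.
#'
#' @param life_table Tibble `age`, `q`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_life_table <- function(life_table, path) {
  # %.17g guarantees doubles survive the text round-trip bit-identically
  writeLines(
    c("age,annual_all_cause_probability",
      sprintf("%d,%.17g", as.integer(life_table$age), life_table$q)),
    path
  )
  invisible(path)
}

# strict CSV reader: exact column set, loud rejection of unknown columns
read_strict_csv <- function(path, cols) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  # read everything as text and convert with base R, whose strtod rounds
  # correctly (exact text round-trips for doubles)
  raw <- tryCatch(
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                    col_types = readr::cols(.default = readr::col_character())),
    error = function(e) stop("cannot parse ", path, ": ", conditionMessage(e),
                             call. = FALSE)
  )
  if (nrow(raw) == 0L && ncol(raw) == 0L) {
    stop("empty file: ", path, call. = FALSE)
  }
  extra <- setdiff(names(raw), names(cols))
  missing <- setdiff(names(cols), names(raw))
  if (length(extra) || length(missing)) {
    stop(path, ": expected exactly columns {",
         paste(names(cols), collapse = ", "), "}",
         if (length(extra)) paste0("; unknown: ", paste(extra, collapse = ", ")),
         if (length(missing)) paste0("; missing: ",
                                     paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  for (nm in names(cols)) {
    raw[[nm]] <- if (cols[[nm]] == "i") as.integer(raw[[nm]])
                 else if (cols[[nm]] == "d") as.numeric(raw[[nm]])
                 else as.character(raw[[nm]])
  }
  raw
}

#' Bundle the demographic inputs of the model
#'
#' Collects the all-cause life table, the cancer-specific annual death
#' probabilities for the undetected and detected cancer states, the
#' standard-population weights used for age adjustment, and the population
#' counts used to scale per-100,000 rates to absolute case numbers.
#'
#' Defaults are deterministic fixtures: a Gompertz-Makeham life table
#' ([make_gompertz_life_table()]), cancer mortality 0.35/yr in both cancer
#' states, equal standard weights across the six age groups, and a stationary
#' population of 1,000,000 men per single year of age. Each component can be
#' overridden with empirical data.
#'
#' @param life_table Tibble `age`, `q` (see [load_life_table()]).
#' @param cancer_mortality Named numeric `c(undetected = , detected = )`, or
#'   a single unnamed value used for both states. Setting the `undetected`
#'   entry to `NA` keeps age-dependent all-cause mortality in the
#'   undetected-cancer state (by default both cancer states carry
#'   cancer-specific mortality).
#' @param standard_weights Tibble `age_group`, `weight`; weights are
#'   normalized to sum to 1.
#' @param population_counts Tibble `age`, `count` (stationary, applied to
#'   every calendar year) giving U.S. white-male counts per single year of
#'   age.
#' @return Object of class `eac_demography`.
#' @export
eac_demography <- function(life_table = make_gompertz_life_table(),
                           cancer_mortality = c(undetected = 0.35,
                                                detected = 0.35),
                           standard_weights = NULL,
                           population_counts = NULL) {
  validate_life_table(life_table)
  if (length(cancer_mortality) == 1L && is.null(names(cancer_mortality))) {
    cancer_mortality <- c(undetected = unname(cancer_mortality),
                          detected = unname(cancer_mortality))
  }
  if (!all(c("undetected", "detected") %in% names(cancer_mortality))) {
    stop("cancer_mortality needs named entries 'undetected' and 'detected'",
         call. = FALSE)
  }
  # NA for the undetected state switches that state to age-dependent
  # all-cause mortality instead of a cancer-specific probability
  if (is.na(cancer_mortality[["detected"]])) {
    stop("detected-cancer mortality must be a probability", call. = FALSE)
  }
  chk <- cancer_mortality[!is.na(cancer_mortality)]
  if (any(chk < 0 | chk > 1)) {
    stop("cancer mortality probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (is.null(standard_weights)) {
    standard_weights <- tibble::tibble(age_group = EAC_AGE_GROUPS,
                                       weight = 1 / 6)
  }
  if (any(standard_weights$weight < 0)) {
    stop("standard weights must be nonnegative", call. = FALSE)
  }
  standard_weights$weight <-
    standard_weights$weight / sum(standard_weights$weight)
  if (is.null(population_counts)) {
    population_counts <- tibble::tibble(age = 20:79, count = 1e6)
  }
  if (any(population_counts$count < 0)) {
    stop("population counts must be nonnegative", call. = FALSE)
  }
  structure(
    list(life_table = life_table, cancer_mortality = cancer_mortality,
         standard_weights = standard_weights,
         population_counts = population_counts),
    class = "eac_demography"
  )
}

#' @export
print.eac_demography <- function(x, ...) {
  cat("<eac_demography> life table ages ",
      min(x$life_table$age), "-", max(x$life_table$age),
      "; cancer mortality U=", x$cancer_mortality[["undetected"]],
      " D=", x$cancer_mortality[["detected"]], "/yr\n", sep = "")
  invisible(x)
}

#' Age-adjust a set of age-group rates
#'
#' Weighted average of age-group rates under standard-population weights:
#' `sum(w_g * rate_g)`. Linear in the rates and bounded by their range.
#'
#' @param incidence_by_group Named numeric vector of rates (names are
#'   age-group labels), or a tibble with columns `age_group` and a single
#'   rate column.
#' @param weights Tibble `age_group`, `weight` (normalized internally).
#' @return Single numeric rate.
#' @examples
#' w <- tibble::tibble(age_group = age_groups(), weight = 1 / 6)
#' age_adjust(setNames(c(0, 0.3, 0.6, 3.3, 7.4, 9.3), age_groups()), w)
#' @export
age_adjust <- function(incidence_by_group, weights) {
  if (is.data.frame(incidence_by_group)) {
    val_col <- setdiff(names(incidence_by_group), "age_group")[1]
    incidence_by_group <- stats::setNames(incidence_by_group[[val_col]],
                                          incidence_by_group$age_group)
  }
  if (!setequal(names(incidence_by_group), weights$age_group)) {
    stop("rate and weight age groups do not match", call. = FALSE)
  }
  w <- weights$weight / sum(weights$weight)
  sum(w * incidence_by_group[weights$age_group])
}

#' Age-adjusted incidence per calendar year
#'
#' Applies [age_adjust()] to the detected-cancer incidence of each calendar
#' year of a simulated population.
#'
#' @param population An `eac_population` tibble.
#' @param weights Tibble `age_group`, `weight`; defaults to equal weights
#'   over the age groups present.
#' @return Tibble `year`, `age_adjusted_incidence`.
#' @export
age_adjusted_incidence <- function(population, weights = NULL) {
  if (is.null(weights)) {
    weights <- tibble::tibble(age_group = unique(population$age_group),
                              weight = 1)
  }
  population |>
    dplyr::group_by(.data$year) |>
    dplyr::summarise(age_adjusted_incidence = age_adjust(
      stats::setNames(.data$eac_incidence, .data$age_group),
      weights
    ), .groups = "drop")
}

#' Stationary adult age-group weights implied by a life table
#'
#' The age distribution of a stationary population (one unit-mass birth
#' cohort entering at age 20 every year) restricted to ages 20-79: the
#' weight of an age group is proportional to the survivorship
#' `l(a) = prod(1 - q)` summed over its ages. These are the documented
#' default weights for the overall (all-adult) prevalence summaries; users
#' with census data should substitute empirical weights.
#'
#' @param demography An [eac_demography()] object.
#' @return Tibble `age_group`, `weight` (sums to 1).
#' @export
adult_age_weights <- function(demography = eac_demography()) {
  lq <- lifetable_vector(demography$life_table)
  ages <- 20:79
  q <- lq[ages - attr(lq, "min_age") + 1L]
  l <- cumprod(c(1, 1 - q))[seq_along(ages)]   # survivorship from age 20
  tibble::tibble(age_group = EAC_AGE_GROUPS[age_group_index(ages)], l = l) |>
    dplyr::group_by(.data$age_group) |>
    dplyr::summarise(weight = sum(.data$l), .groups = "drop") |>
    dplyr::mutate(weight = .data$weight / sum(.data$weight))
}

#' Overall adult prevalence of an endpoint
#'
#' Weighted average of age-group prevalences across ages 20-79, by calendar
#' year. Used to compare model output against all-adult prevalence figures
#' (e.g. overall Barrett's-esophagus or GERD-symptom prevalence).
#'
#' @param population An `eac_population` tibble.
#' @param endpoint `"be"` or `"gerd"`.
#' @param weights Tibble `age_group`, `weight`; defaults to
#'   [adult_age_weights()] of the default demography.
#' @return Tibble `year`, `endpoint`, `value` (percent).
#' @export
overall_prevalence <- function(population, endpoint = c("be", "gerd"),
                               weights = NULL) {
  endpoint <- match.arg(endpoint)
  if (is.null(weights)) weights <- adult_age_weights()
  col <- if (endpoint == "be") "be_prev" else "gerd_prev"
  population |>
    dplyr::group_by(.data$year) |>
    dplyr::summarise(value = age_adjust(
      stats::setNames(.data[[col]], .data$age_group), weights
    ), .groups = "drop") |>
    dplyr::mutate(endpoint = toupper(endpoint), .after = "year")
}
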