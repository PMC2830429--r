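# Aspirin chemoprevention counterfactual.

#' Convert a 5-year cumulative risk reduction to an annual reduction
#'
#' Under a constant-hazard assumption, a proportional reduction `R5` of the
#' cumulative cancer rate at the end of a 5-year period corresponds to an
#' annual transition reduction `r = 1 - (1 - R5)^(1/5)`, so that
#' `(1 - r)^5 = 1 - R5`. The base case of a 50% five-year reduction gives an
#' annual reduction of 0.12945 (about 13%).
#'
#' @param R5 Five-year cumulative reduction, in `[0, 1)`.
#' @return Annual reduction in `[0, 1)`.
#' @examples
#' annual_reduction_from_five_year(0.5)
#' @export
annual_reduction_from_five_year <- function(R5) {
  if (any(!is.finite(R5) | R5 < 0 | R5 >= 1)) {
    stop("R5 must lie in [0, 1)", call. = FALSE)
  }
  1 - (1 - R5)^(1 / 5)
}

#' Specify a chemoprevention intervention
#'
#' Aspirin chemoprevention reduces the annual Barrett's-esophagus to
#' undetected-cancer transition (both long- and short-segment, by the same
#' multiplier) for every person-year in which the individual is at least
#' `start_age` years old and the calendar year is at least `start_year`.
#' Prevalent men already past `start_age` at `start_year` begin then; full
#' adherence and no cessation are assumed. The base case is universal
#' initiation at age 40 from 1960 (a run-in before the 1973 analysis start)
#' with a 50% five-year risk reduction.
#'
#' @param five_year_reduction Five-year cumulative reduction `R5` in
#'   `[0, 1)`.
#' @param start_year First calendar year of the program.
#' @param start_age Age at initiation.
#' @return A list of class `eac_intervention` with the derived
#'   `annual_reduction`.
#' @export
intervention_spec <- function(five_year_reduction = 0.5, start_year = 1960L,
                              start_age = 40L) {
  structure(
    list(five_year_reduction = five_year_reduction,
         start_year = as.integer(start_year),
         start_age = as.integer(start_age),
         annual_reduction =
           annual_reduction_from_five_year(five_year_reduction)),
    class = "eac_intervention"
  )
}

#' @export
print.eac_intervention <- function(x, ...) {
  cat("<eac_intervention> 5-year reduction ",
      100 * x$five_year_reduction, "% (annual ",
      format(100 * x$annual_reduction, digits = 4),
      "%), from age ", x$start_age, " and year ", x$start_year, "\n",
      sep = "")
  invisible(x)
}

# default 5-year reporting grid
default_report_periods <- function() {
  tibble::tibble(start = c(1975L, 1981L, 1986L, 1991L, 1996L, 2001L),
                 end = c(1980L, 1985L, 1990L, 1995L, 2000L, 2005L))
}

validate_periods <- function(periods) {
  stopifnot(all(c("start", "end") %in% names(periods)))
  if (any(periods$end < periods$start)) {
    stop("periods must have start <= end", call. = FALSE)
  }
  if (nrow(periods) > 1L) {
    if (is.unsorted(periods$start, strictly = TRUE) ||
        any(periods$start[-1L] <= periods$end[-nrow(periods)])) {
      stop("periods must be ordered and non-overlapping", call. = FALSE)
    }
  }
  invisible(periods)
}

# national annual case counts implied by per-100k incidence and the
# population counts (person-years per age group and year)
cases_by_year <- function(core, counts) {
  ag <- age_group_of(counts$age)
  py <- tapply(counts$count, ag, sum)[core$age_groups]
  as.numeric(core$inc %*% (py / 1e5))
}

#' Counterfactual chemoprevention run over a parameter ensemble
#'
#' Simulates every ensemble member twice - with and without the
#' intervention - over the years spanned by `periods`, converts incidence
#' into national case counts using the demography's population counts, and
#' accounts prevented cases per reporting period. Point estimates are
#' ensemble means; ranges are ensemble minima and maxima.
#'
#' @param ensemble Ensemble tibble with parameter columns (e.g.
#'   `calibration$ensemble`), or an `eac_calibration` object.
#' @param spec An [intervention_spec()].
#' @param demography An [eac_demography()].
#' @param periods Tibble `start`, `end` of ordered non-overlapping reporting
#'   periods (default: six 5-year periods 1975-2005).
#' @param base_params Values for parameters not present in the ensemble.
#' @return An `eac_counterfactual` tibble from [build_report_table()]:
#'   per-period original cases, prevented cases with ensemble range, percent
#'   reduction and cumulative tallies.
#' @export
run_counterfactual <- function(ensemble, spec,
                               demography = eac_demography(),
                               periods = default_report_periods(),
                               base_params = NULL) {
  if (inherits(ensemble, "eac_calibration")) {
    base_params <- ensemble$base_params
    ensemble <- ensemble$ensemble
  }
  if (nrow(ensemble) == 0L) stop("empty ensemble", call. = FALSE)
  validate_periods(periods)
  years <- min(periods$start):max(periods$end)
  counts <- demography$population_counts

  per_member <- lapply(ensemble_param_list(ensemble), function(x) {
    p <- params_from_vector(x, base = base_params)
    base <- cases_by_year(sim_population_core(p, years, demography), counts)
    trt <- cases_by_year(
      sim_population_core(p, years, demography, intervention = spec), counts
    )
    in_period <- function(v) {
      vapply(seq_len(nrow(periods)), function(i) {
        sum(v[years >= periods$start[i] & years <= periods$end[i]])
      }, numeric(1))
    }
    cbind(original = in_period(base), prevented = in_period(base - trt))
  })
  orig <- sapply(per_member, function(m) m[, "original"])
  prev <- sapply(per_member, function(m) m[, "prevented"])
  if (is.null(dim(orig))) {  # single period
    orig <- matrix(orig, nrow = 1L)
    prev <- matrix(prev, nrow = 1L)
  }
  build_report_table(
    periods,
    original_cases = rowMeans(orig),
    prevented_cases = rowMeans(prev),
    prevented_lo = apply(prev, 1, min),
    prevented_hi = apply(prev, 1, max)
  )
}

#' Assemble a prevented-case report table
#'
#' Pure accounting over per-period case numbers: cumulative tallies are
#' exact running sums of the per-period columns and the percent reduction is
#' `100 * prevented / original`. No simulation is performed.
#'
#' @param periods Tibble `start`, `end` (ordered, non-overlapping).
#' @param original_cases Expected cases without intervention, per period.
#' @param prevented_cases Prevented cases (point estimate), per period.
#' @param prevented_lo,prevented_hi Optional ensemble range of prevented
#'   cases.
#' @return A tibble of class `eac_counterfactual` with columns `period`,
#'   `start`, `end`, `original_cases`, `cumulative_original`,
#'   `prevented_cases` (and range columns if supplied),
#'   `percent_reduction`, `cumulative_prevented`.
#' @export
build_report_table <- function(periods, original_cases, prevented_cases,
                               prevented_lo = NULL, prevented_hi = NULL) {
  validate_periods(periods)
  stopifnot(length(original_cases) == nrow(periods),
            length(prevented_cases) == nrow(periods))
  out <- tibble::tibble(
    period = paste0(periods$start, "-", periods$end),
    start = periods$start, end = periods$end,
    original_cases = original_cases,
    cumulative_original = cumsum(original_cases),
    prevented_cases = prevented_cases,
    percent_reduction = 100 * prevented_cases / original_cases,
    cumulative_prevented = cumsum(prevented_cases)
  )
  if (!is.null(prevented_lo)) out$prevented_lo <- prevented_lo
  if (!is.null(prevented_hi)) out$prevented_hi <- prevented_hi
  structure(out, class = c("eac_counterfactual", class(out)))
}

#' Sensitivity sweep over the intervention effect size
#'
#' Runs [run_counterfactual()] once per candidate five-year reduction and
#' stacks the reports. Prevented cases are non-decreasing in the effect
#' size, pointwise per period.
#'
#' @param ensemble,demography,periods,base_params As in
#'   [run_counterfactual()].
#' @param R5_values Numeric vector of five-year reductions in `[0, 1)`
#'   (e.g. `c(0.3, 0.5, 0.7)`); an empty vector returns an empty tibble
#'   without simulating.
#' @param start_year,start_age Program parameters shared across the sweep.
#' @return Tibble: the per-R5 reports stacked with a leading
#'   `five_year_reduction` column.
#' @export
sensitivity_sweep <- function(ensemble, R5_values,
                              demography = eac_demography(),
                              periods = default_report_periods(),
                              start_year = 1960L, start_age = 40L,
                              base_params = NULL) {
  if (length(R5_values) == 0L) return(tibble::tibble())
  purrr::map_dfr(R5_values, function(R5) {
    rep <- run_counterfactual(
      ensemble, intervention_spec(R5, start_year, start_age),
      demography = demography, periods = periods, base_params = base_params
    )
    dplyr::bind_cols(tibble::tibble(five_year_reduction = R5), rep)
  })
}
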