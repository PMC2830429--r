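# broom-style tidiers for fitted objects.

#' Tidy a calibrated ensemble
#'
#' One row per free parameter with the ensemble's spread: the best set's
#' value, the ensemble minimum, median and maximum. The min-max envelope is
#' the model's expression of parameter uncertainty.
#'
#' @param x An `eac_calibration` object.
#' @param ... Unused.
#' @return Tibble `parameter`, `best`, `min`, `median`, `max`.
#' @export
tidy.eac_calibration <- function(x, ...) {
  pn <- intersect(names(x$ensemble), param_vector_names())
  purrr::map_dfr(pn, function(p) {
    v <- x$ensemble[[p]]
    tibble::tibble(parameter = p, best = v[1], min = min(v),
                   median = stats::median(v), max = max(v))
  })
}

#' Glance at a calibration
#'
#' @param x An `eac_calibration` object.
#' @param ... Unused.
#' @return One-row tibble: phase order, evaluations per phase, ensemble
#'   size, best per-endpoint and combined GOF.
#' @export
glance.eac_calibration <- function(x, ...) {
  best <- x$ensemble[1, ]
  tibble::tibble(
    order = x$order,
    n_iterations = x$config$n_iterations,
    ensemble_size = nrow(x$ensemble),
    gof_gerd = best$gof_GERD_PREV,
    gof_be = best$gof_BE_PREV,
    gof_eac = best$gof_EAC_INCIDENCE,
    gof_total = best$gof_total
  )
}

#' Tidy a validation report
#'
#' @param x An `eac_validation` object.
#' @param ... Unused.
#' @return Per-ensemble-member adjusted GOF scores.
#' @export
tidy.eac_validation <- function(x, ...) x$members

#' Glance at a validation report
#'
#' @param x An `eac_validation` object.
#' @param ... Unused.
#' @return One-row tibble with the adjusted scores, their ratio and the
#'   pass flag.
#' @export
glance.eac_validation <- function(x, ...) {
  tibble::tibble(
    adjusted_gof_calibration = x$adjusted_gof_calibration,
    adjusted_gof_validation = x$adjusted_gof_validation,
    ratio = x$ratio, passed = x$passed,
    n_calibration_years = x$n_calibration_years,
    n_validation_years = x$n_validation_years
  )
}
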