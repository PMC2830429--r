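# ggplot2 methods for the result types.

#' Plot a simulated population cross-section
#'
#' Incidence (or a prevalence endpoint) as a function of calendar year,
#' one line per age group.
#'
#' @param object An `eac_population` tibble.
#' @param endpoint One of `"eac_incidence"`, `"be_prev"`, `"gerd_prev"`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.eac_population <- function(object,
                                    endpoint = c("eac_incidence", "be_prev",
                                                 "gerd_prev"), ...) {
  endpoint <- match.arg(endpoint)
  ylab <- c(eac_incidence = "EAC incidence per 100,000",
            be_prev = "BE prevalence (%)",
            gerd_prev = "GERD symptom prevalence (%)")[[endpoint]]
  ggplot2::ggplot(object, ggplot2::aes(
    x = .data$year, y = .data[[endpoint]],
    colour = .data$age_group, group = .data$age_group
  )) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Calendar year", y = ylab, colour = "Age group") +
    ggplot2::theme_minimal()
}

#' Plot model fit against calibration targets
#'
#' Compares the best calibrated parameter set's output with the target
#' values by endpoint and age group.
#'
#' @param calibration An `eac_calibration` object.
#' @param targets The [eac_targets()] it was fitted to.
#' @param demography An [eac_demography()].
#' @return A ggplot (points: targets; lines: model).
#' @export
plot_calibration_fit <- function(calibration, targets,
                                 demography = eac_demography()) {
  pop <- simulate_population(best_params(calibration),
                             target_years(targets, "CALIBRATION"),
                             demography, max_age = calibration$max_age)
  model <- population_long(pop) |> dplyr::mutate(source = "model")
  obs <- expand_targets(targets, "CALIBRATION") |>
    dplyr::select("endpoint", "year", "age_group", "value") |>
    dplyr::mutate(source = "target")
  ggplot2::ggplot(dplyr::bind_rows(model, obs), ggplot2::aes(
    x = .data$age_group, y = .data$value, colour = .data$source,
    group = interaction(.data$source, .data$year)
  )) +
    ggplot2::geom_point(data = function(d) d[d$source == "target", ]) +
    ggplot2::geom_line(data = function(d) d[d$source == "model", ]) +
    ggplot2::facet_wrap(~endpoint, scales = "free_y") +
    ggplot2::labs(x = "Age group", y = "Value", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a counterfactual report
#'
#' Prevented cases per reporting period with the ensemble range.
#'
#' @param object An `eac_counterfactual` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.eac_counterfactual <- function(object, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(
    x = .data$period, y = .data$prevented_cases
  )) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "Period", y = "Prevented EAC cases") +
    ggplot2::theme_minimal()
  if ("prevented_lo" %in% names(object)) {
    p <- p + ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$prevented_lo, ymax = .data$prevented_hi),
      width = 0.2
    )
  }
  p
}
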