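# Chi-squared goodness-of-fit scoring against target sets.

#' Chi-squared goodness of fit of model output against targets
#'
#' Pearson-style discrepancy between model output and targets, per endpoint:
#' `score_e = w_e * sum_i (O_i - M_i)^2 / max(O_i, eps)` over the targets
#' `i` of endpoint `e`, where `O` is the target value, `M` the model value
#' and `eps` a denominator floor (in the endpoint's own units) that keeps
#' the statistic defined at zero-valued targets such as the youngest age
#' group's incidence. Time-constant prevalence targets are expanded to one
#' entry per year of the role's year range before scoring, so each year
#' contributes to the score. An exact model-target match scores 0.
#'
#' @param model An `eac_population` tibble covering every scored
#'   (endpoint, year, age group) cell; an uncovered target is an error,
#'   never silently skipped.
#' @param targets An [eac_targets()] object.
#' @param endpoints Subset of endpoints to score (default: all present).
#' @param weights Named numeric endpoint weights (default 1 each).
#' @param role Score against `"CALIBRATION"` (default) or `"VALIDATION"`
#'   targets.
#' @param eps Denominator floor (default 0.5).
#' @return A tibble of class `eac_gof` with columns `endpoint`,
#'   `n_targets`, `weight`, `score`, and the total in
#'   `attr(, "total")` (also via [gof_total()]).
#' @examples
#' p <- transition_params(0.04, 0.002, 0.004, r_lsbe_ca = 0.008)
#' pop <- simulate_population(p, 1986, eac_demography())
#' chi_square_gof(pop, representative_year_targets())
#' @export
chi_square_gof <- function(model, targets, endpoints = NULL, weights = NULL,
                           role = "CALIBRATION", eps = 0.5) {
  exp_t <- expand_targets(targets, role)
  if (is.null(endpoints)) endpoints <- unique(exp_t$endpoint)
  exp_t <- dplyr::filter(exp_t, .data$endpoint %in% endpoints)
  if (nrow(exp_t) == 0L) stop("no targets to score", call. = FALSE)
  w <- endpoint_weights(weights, endpoints)

  joined <- dplyr::left_join(
    exp_t, population_long(model),
    by = c("endpoint", "year", "age_group"), suffix = c("_obs", "_model")
  )
  if (anyNA(joined$value_model)) {
    miss <- dplyr::filter(joined, is.na(.data$value_model))
    stop("model output does not cover ", nrow(miss), " target cell(s), e.g. ",
         miss$endpoint[1], " ", miss$year[1], " ", miss$age_group[1],
         call. = FALSE)
  }
  out <- joined |>
    dplyr::group_by(.data$endpoint) |>
    dplyr::summarise(
      n_targets = dplyr::n(),
      score = sum((.data$value_obs - .data$value_model)^2 /
                    pmax(.data$value_obs, eps)),
      .groups = "drop"
    ) |>
    dplyr::mutate(weight = w[.data$endpoint],
                  score = .data$weight * .data$score) |>
    dplyr::select("endpoint", "n_targets", "weight", "score")
  structure(out, total = sum(out$score),
            class = c("eac_gof", class(out)))
}

#' Total goodness-of-fit score
#'
#' @param gof An `eac_gof` tibble from [chi_square_gof()].
#' @return The summed (weighted) score across endpoints.
#' @export
gof_total <- function(gof) attr(gof, "total")

endpoint_weights <- function(weights, endpoints) {
  w <- stats::setNames(rep(1, length(endpoints)), endpoints)
  if (!is.null(weights)) {
    unknown <- setdiff(names(weights), EAC_ENDPOINTS)
    if (length(unknown)) {
      stop("unknown endpoint weight(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    w[intersect(names(weights), endpoints)] <-
      weights[intersect(names(weights), endpoints)]
  }
  w
}

# ---- fast compiled scorer used inside the calibration loop ------------------

# Pre-resolves expanded targets to (matrix, row, col) indices against the
# core engine's output layout so each SA evaluation only does vector
# arithmetic. Same formula as chi_square_gof(); a unit test asserts equality.
compile_gof <- function(targets, role, years, age_groups, weights = NULL,
                        eps = 0.5) {
  exp_t <- expand_targets(targets, role)
  endpoints <- unique(exp_t$endpoint)
  w <- endpoint_weights(weights, endpoints)
  iy <- match(exp_t$year, years)
  ig <- match(exp_t$age_group, age_groups)
  if (anyNA(iy) || anyNA(ig)) {
    stop("simulation window does not cover all targets", call. = FALSE)
  }
  mat_of <- c(GERD_PREV = 1L, BE_PREV = 2L, EAC_INCIDENCE = 3L)
  list(
    endpoints = endpoints,
    mat = mat_of[exp_t$endpoint],
    idx = cbind(iy, ig),
    O = exp_t$value,
    denom = pmax(exp_t$value, eps),
    e_fac = factor(exp_t$endpoint, levels = endpoints),
    w = w
  )
}

score_compiled <- function(sc, core) {
  M <- numeric(length(sc$O))
  for (k in 1:3) {
    sel <- sc$mat == k
    if (any(sel)) {
      mat <- switch(k, core$gerd, core$be, core$inc)
      M[sel] <- mat[sc$idx[sel, , drop = FALSE]]
    }
  }
  contrib <- (sc$O - M)^2 / sc$denom
  by_e <- vapply(split(contrib, sc$e_fac), sum, numeric(1))
  stats::setNames(sc$w[sc$endpoints] * by_e[sc$endpoints],
                  paste0("gof_", sc$endpoints))
}
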