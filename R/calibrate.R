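# Three-phase sequential calibration and hold-out validation.

FORWARD_ORDER <- c("GERD_PREV", "BE_PREV", "EAC_INCIDENCE")

#' Default search bounds for the free parameters
#'
#' Order-of-magnitude envelopes around the target magnitudes: GERD-symptom
#' prevalence near 18% by the mid-20s implies a Normal-to-GERD probability
#' of roughly 4% per year in the youngest group, so the allowable range is
#' capped at 0.10; Barrett's prevalence of 2-6% accumulated over six adult
#' decades implies feeder transitions of order 0.1% per year, capped at ten
#' times that (0.01); incidence of order 10 per 100,000 arising from a ~5%
#' BE pool implies progression rates of order 1% per year, capped at 0.05.
#' The mean sojourn time is bounded by its literature range of 4 to 9
#' years.
#'
#' In representative-year mode (targets anchored to a single calendar year)
#' the secular slope is frozen at 0, because a single-year incidence target
#' only constrains the product of base rate and that year's multiplier.
#'
#' @param n_groups Number of leading age groups with free transition
#'   probabilities (6 for the full model; smaller model worlds free only the
#'   groups they populate).
#' @param representative_year If `TRUE`, freeze `secular_slope` at 0.
#' @return Tibble `param`, `lower`, `upper`.
#' @export
default_bounds <- function(n_groups = 6L, representative_year = FALSE) {
  stopifnot(n_groups >= 1, n_groups <= 6)
  g <- seq_len(n_groups)
  tibble::tibble(
    param = c(paste0("p_normal_gerd_", g), paste0("p_normal_be_", g),
              paste0("p_gerd_be_", g),
              "r_lsbe_ca", "secular_slope", "mean_sojourn_years"),
    lower = c(rep(0, 3 * n_groups), 0, 0, 4),
    upper = c(rep(0.10, n_groups), rep(0.01, 2 * n_groups),
              0.05, if (representative_year) 0 else 0.15, 9)
  )
}

# deterministic per-stage child seeds from one global seed (kept < 2^31)
derive_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) * 100003 + 97 * stage) %% 2147483629 + 1)
}

# infer the oldest modeled age from the target age groups
targets_max_age <- function(targets) {
  gi <- max(match(unique(targets$age_group), EAC_AGE_GROUPS))
  19L + 10L * gi
}

# objective factory: named free-parameter vector -> per-endpoint GOF vector
make_gof_objective <- function(targets, demography, base_params, years,
                               max_age, weights = NULL, eps = 0.5,
                               role = "CALIBRATION") {
  groups <- EAC_AGE_GROUPS[seq_len(age_group_index(max_age))]
  sc <- compile_gof(targets, role, years, groups, weights = weights,
                    eps = eps)
  function(x) {
    p <- params_from_vector(x, base = base_params)
    core <- sim_population_core(p, years, demography, max_age = max_age)
    score_compiled(sc, core)
  }
}

#' Three-phase sequential calibration
#'
#' Fits the model to the three calibration endpoints sequentially. Each
#' phase runs a full simulated-annealing search ([sa_search()]) scored on
#' the chi-squared goodness of fit of the endpoints introduced so far
#' (phase 1: the first endpoint alone; phase 2: the first two; phase 3: all
#' three): accumulation keeps later phases from undoing earlier fits, and
#' makes the last phase optimize exactly the combined score the final
#' ensemble is ranked on. After each of the first two phases the parameter
#' bounds are narrowed to the min-max envelope of the 10% best-scoring
#' evaluations ([narrow_bounds()]). The first two phases run with the
#' configured number of annealing restarts, favouring breadth so the
#' narrowed envelopes represent every solution family; the final phase runs
#' with `final_restarts` (default 2), favouring descent depth. In the
#' `"forward"` order the endpoints enter as GERD-symptom prevalence, then
#' Barrett's-esophagus prevalence, then EAC incidence; `"reverse"`
#' introduces them in the opposite order. Because each evaluation simulates the whole population,
#' all three endpoint scores are logged at every evaluation; after the third
#' phase its evaluations are ranked on the combined three-endpoint score and
#' the best `final_fraction` retained as the calibrated ensemble (1% of 1e5
#' evaluations = 1,000 sets at paper scale). The ensemble's parameter spread
#' expresses parameter uncertainty.
#'
#' @param targets An [eac_targets()] object containing calibration targets
#'   for all three endpoints.
#' @param demography An [eac_demography()].
#' @param bounds Starting bounds tibble (`param`, `lower`, `upper`);
#'   default [default_bounds()].
#' @param config An [sa_config()]; each phase derives its own child seed
#'   from `config$seed`.
#' @param order `"forward"` or `"reverse"`.
#' @param final_fraction Fraction of third-phase evaluations retained as the
#'   ensemble (default 0.01).
#' @param narrow_fraction Fraction kept when narrowing bounds between phases
#'   (default 0.10).
#' @param final_restarts Annealing restarts used in the third phase
#'   (default 2).
#' @param base_params Values for parameters not present in `bounds`.
#' @param endpoint_weights Optional named endpoint weights for the GOF.
#' @param eps GOF denominator floor (see [chi_square_gof()]).
#' @return A list of class `eac_calibration`: the phase endpoint sequence,
#'   per-phase bounds and evaluation logs, the final `ensemble` tibble
#'   (parameters, per-endpoint scores, `gof_total`, sorted ascending), and
#'   the configuration used. [best_params()] extracts the best set.
#' @export
three_phase_calibrate <- function(targets, demography = eac_demography(),
                                  bounds = NULL, config = sa_config(),
                                  order = c("forward", "reverse"),
                                  final_fraction = 0.01,
                                  narrow_fraction = 0.10,
                                  final_restarts = 2L,
                                  base_params = NULL,
                                  endpoint_weights = NULL, eps = 0.5) {
  order <- match.arg(order)
  cal <- dplyr::filter(targets, .data$role == "CALIBRATION")
  missing_e <- setdiff(EAC_ENDPOINTS, unique(cal$endpoint))
  if (length(missing_e)) {
    stop("calibration targets missing endpoint(s): ",
         paste(missing_e, collapse = ", "), call. = FALSE)
  }
  max_age <- targets_max_age(cal)
  if (is.null(bounds)) {
    bounds <- default_bounds(
      n_groups = age_group_index(max_age),
      representative_year = length(target_years(targets)) == 1L
    )
  }
  validate_bounds(bounds)
  years <- target_years(targets, "CALIBRATION")
  objective <- make_gof_objective(targets, demography, base_params, years,
                                  max_age, weights = endpoint_weights,
                                  eps = eps)
  endpoints <- if (order == "forward") FORWARD_ORDER else rev(FORWARD_ORDER)

  phases <- vector("list", 3L)
  b <- bounds
  for (k in 1:3) {
    cfg <- config
    cfg$seed <- derive_seed(config$seed, k)
    if (k == 3L) {
      cfg$restarts <- min(as.integer(final_restarts), cfg$n_iterations)
      cfg$steps_per_temperature <-
        max(1, ceiling(cfg$n_iterations / cfg$restarts / 100))
    }
    evals <- sa_search(objective, b, cfg,
                       score_components = paste0("gof_", endpoints[1:k]))
    phases[[k]] <- list(endpoint = endpoints[k], bounds = b,
                        evaluations = evals)
    if (k < 3L) b <- narrow_bounds(evals, keep_fraction = narrow_fraction)
  }

  final <- phases[[3L]]$evaluations
  gof_cols <- paste0("gof_", EAC_ENDPOINTS)
  combined <- rowSums(as.matrix(final[, gof_cols]))
  n_keep <- max(1L, round(final_fraction * nrow(final)))
  ord <- order(combined, final$iteration)[seq_len(n_keep)]
  ensemble <- final[ord, c("iteration", bounds$param, gof_cols)]
  ensemble$gof_total <- combined[ord]

  structure(
    list(order = order, endpoints = endpoints, phases = phases,
         ensemble = ensemble, bounds = bounds, final_bounds = b,
         config = config, final_fraction = final_fraction,
         base_params = base_params, max_age = max_age,
         calibration_years = years, endpoint_weights = endpoint_weights,
         eps = eps),
    class = "eac_calibration"
  )
}

#' @export
print.eac_calibration <- function(x, ...) {
  cat("<eac_calibration> order:", x$order,
      "| evaluations/phase:", x$config$n_iterations,
      "| ensemble size:", nrow(x$ensemble), "\n")
  cat("  best combined GOF:", format(x$ensemble$gof_total[1], digits = 5),
      "\n")
  invisible(x)
}

#' Extract a parameter set from a calibrated ensemble
#'
#' @param calibration An `eac_calibration` object.
#' @param rank Ensemble rank (1 = lowest combined GOF).
#' @return An [transition_params()] object.
#' @export
best_params <- function(calibration, rank = 1L) {
  row <- calibration$ensemble[rank, ]
  x <- unlist(row[, intersect(names(row), param_vector_names())])
  params_from_vector(x, base = calibration$base_params)
}

# parameter sets (named vectors) of every ensemble member
ensemble_param_list <- function(ensemble) {
  pn <- intersect(names(ensemble), param_vector_names())
  lapply(seq_len(nrow(ensemble)), function(i) unlist(ensemble[i, pn]))
}

#' Hold-out validation of a calibrated ensemble
#'
#' Re-simulates every ensemble member over the calibration and validation
#' year ranges and compares adjusted goodness-of-fit scores: each member's
#' combined GOF over a period is divided by the number of years in that
#' period, and the adjusted scores are averaged over the ensemble. The model
#' validates when the mean adjusted validation score is strictly less than
#' 150% of the mean adjusted calibration score.
#'
#' @param calibration An `eac_calibration` object (or an ensemble tibble
#'   with parameter columns).
#' @param targets An [eac_targets()] object with a nonempty validation year
#'   range and `VALIDATION`-role targets.
#' @param demography An [eac_demography()].
#' @param base_params,endpoint_weights,eps As in [three_phase_calibrate()];
#'   taken from `calibration` when available.
#' @return A list of class `eac_validation`: `adjusted_gof_calibration`,
#'   `adjusted_gof_validation`, `ratio`, `passed`, the year counts, and a
#'   per-member tibble.
#' @export
validate_calibration <- function(calibration, targets,
                                 demography = eac_demography(),
                                 base_params = NULL,
                                 endpoint_weights = NULL, eps = 0.5) {
  if (inherits(calibration, "eac_calibration")) {
    ensemble <- calibration$ensemble
    base_params <- calibration$base_params
    endpoint_weights <- calibration$endpoint_weights
    eps <- calibration$eps
  } else {
    ensemble <- calibration
  }
  if (nrow(ensemble) == 0L) stop("empty ensemble", call. = FALSE)
  cal_years <- target_years(targets, "CALIBRATION")
  val_years <- target_years(targets, "VALIDATION")
  if (length(val_years) == 0L) {
    stop("target set has no validation years; cannot validate", call. = FALSE)
  }
  if (!any(targets$role == "VALIDATION")) {
    stop("target set has no VALIDATION-role targets", call. = FALSE)
  }
  max_age <- targets_max_age(targets)
  groups <- EAC_AGE_GROUPS[seq_len(age_group_index(max_age))]
  years <- sort(unique(c(cal_years, val_years)))
  sc_cal <- compile_gof(targets, "CALIBRATION", years, groups,
                        weights = endpoint_weights, eps = eps)
  sc_val <- compile_gof(targets, "VALIDATION", years, groups,
                        weights = endpoint_weights, eps = eps)

  members <- purrr::map_dfr(ensemble_param_list(ensemble), function(x) {
    p <- params_from_vector(x, base = base_params)
    core <- sim_population_core(p, years, demography, max_age = max_age)
    tibble::tibble(
      gof_calibration = sum(score_compiled(sc_cal, core)),
      gof_validation = sum(score_compiled(sc_val, core))
    )
  })
  members$adjusted_calibration <- members$gof_calibration / length(cal_years)
  members$adjusted_validation <- members$gof_validation / length(val_years)

  adj_cal <- mean(members$adjusted_calibration)
  adj_val <- mean(members$adjusted_validation)
  structure(
    list(adjusted_gof_calibration = adj_cal,
         adjusted_gof_validation = adj_val,
         ratio = adj_val / adj_cal,
         passed = adj_val < 1.5 * adj_cal,
         n_calibration_years = length(cal_years),
         n_validation_years = length(val_years),
         members = members),
    class = "eac_validation"
  )
}

#' @export
print.eac_validation <- function(x, ...) {
  cat("<eac_validation> adjusted GOF: calibration",
      format(x$adjusted_gof_calibration, digits = 4),
      "| validation", format(x$adjusted_gof_validation, digits = 4),
      "| ratio", format(x$ratio, digits = 3),
      "->", if (x$passed) "PASSED" else "FAILED",
      "(criterion: validation < 150% of calibration)\n")
  invisible(x)
}

#' Persist a calibrated ensemble
#'
#' Writes the ensemble as CSV (one row per parameter set with its
#' per-endpoint and total GOF scores) and a JSON metadata sidecar (search
#' configuration, seed, phase-bound history).
#'
#' @param calibration An `eac_calibration` object.
#' @param csv_path,json_path Output paths (the JSON sidecar is skipped when
#'   `json_path` is `NULL`).
#' @return `csv_path`, invisibly.
#' @export
write_ensemble <- function(calibration, csv_path, json_path = NULL) {
  readr::write_csv(calibration$ensemble, csv_path)
  if (!is.null(json_path)) {
    meta <- list(
      order = calibration$order,
      n_iterations = calibration$config$n_iterations,
      seed = calibration$config$seed,
      final_fraction = calibration$final_fraction,
      calibration_years = calibration$calibration_years,
      phase_bounds = lapply(calibration$phases, function(ph) {
        list(endpoint = ph$endpoint,
             bounds = as.list(stats::setNames(
               purrr::map2(ph$bounds$lower, ph$bounds$upper, c),
               ph$bounds$param
             )))
      })
    )
    jsonlite::write_json(meta, json_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(csv_path)
}
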