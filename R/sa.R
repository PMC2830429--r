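# Simulated-annealing search and parameter-bound narrowing.

#' Simulated-annealing configuration
#'
#' Controls the stochastic parameter search. The paper-scale run uses 1e5
#' evaluations per calibration phase; tests and examples use far fewer. The
#' schedule defaults (chosen for robustness on the parameter-recovery
#' experiments, all overridable): the run is split into `restarts`
#' independent annealing segments, each starting from a fresh bound-uniform
#' draw - multi-start keeps the best-fraction envelope representative of
#' every solution family the search finds, rather than of a single chain's
#' cold tail, which matters because the between-phase bound narrowing uses
#' that envelope. Within a segment: initial temperature `"AUTO"` - the
#' median absolute score difference among 50 random bound-uniform parameter
#' pairs; geometric cooling by `cooling_factor` every
#' `steps_per_temperature` evaluations, where the default `"SCALED"` spans
#' 100 cooling steps per segment regardless of run length; a temperature
#' floor of `floor_frac` times (1 + the best score found so far), so a
#' cooled chain keeps sampling the near-optimal basin instead of freezing
#' at a point - the retained best fraction then expresses the spread of
#' comparable fits rather than one chain endpoint;
#' single-parameter uniform proposals of half-width `proposal_width` times
#' the bound width at full temperature - shrinking with the square root of
#' the relative temperature down to a 5% floor as the segment cools, so
#' late proposals refine rather than wander - reflected at the bounds,
#' mixed with probability `jump_prob` with a full-range uniform redraw of
#' the chosen parameter and with probability `vector_prob` with a joint
#' small step in every free parameter at once. Coordinate redraws keep
#' unconstrained parameters decorrelated; joint steps let the chain move
#' along diagonal compensation ridges that single-coordinate moves cannot
#' follow at low temperature.
#' The redraw component matters for the bound-narrowing step: a parameter
#' the current endpoint does not constrain accepts redraws freely, so the
#' best-fraction envelope stays wide for it, while a constrained parameter
#' rejects them and narrows.
#'
#' @param n_iterations Number of objective evaluations recorded (>= 1).
#' @param initial_temperature `"AUTO"` or a nonnegative number; 0 gives
#'   strict stochastic hill-descent.
#' @param cooling_factor Geometric cooling multiplier in (0, 1).
#' @param steps_per_temperature Evaluations between cooling steps, or
#'   `"SCALED"` for 100 cooling steps per annealing segment.
#' @param restarts Number of independent annealing segments the evaluation
#'   budget is split into (default 5).
#' @param jump_prob Probability that a proposal redraws the chosen
#'   parameter uniformly within its bounds instead of stepping locally
#'   (default 0.2).
#' @param vector_prob Probability of a joint small step in all free
#'   parameters (quarter of the single-parameter width in each coordinate;
#'   default 0.2).
#' @param adapt_width If `TRUE` (default), the local-step half-width
#'   shrinks with the square root of the relative temperature down to a 5%
#'   floor, refining late proposals; `FALSE` keeps it fixed at
#'   `proposal_width`, which suits searches whose later phases must still
#'   traverse wide bounds.
#' @param floor_frac Temperature floor as a fraction of (1 + best score so
#'   far); 0 disables the floor (default 0.05). A vector is cycled across
#'   the annealing segments (a floor ladder): segments with wider floors
#'   sample broader shells of the near-optimal basin, narrower floors
#'   refine, and the retained best fraction draws from all of them.
#' @param proposal_width Proposal half-width as a fraction of the bound
#'   width, in (0, 1].
#' @param seed Integer seed; identical seed, config and bounds reproduce
#'   the evaluation sequence exactly.
#' @return A list of class `sa_config`.
#' @export
sa_config <- function(n_iterations = 1e5, initial_temperature = "AUTO",
                      cooling_factor = 0.90,
                      steps_per_temperature = "SCALED",
                      proposal_width = 0.1, restarts = 5L, jump_prob = 0.2,
                      vector_prob = 0.2, adapt_width = TRUE,
                      floor_frac = 0.05, seed = 1L) {
  stopifnot(n_iterations >= 1, restarts >= 1,
            jump_prob >= 0, jump_prob <= 1, vector_prob >= 0,
            jump_prob + vector_prob <= 1, length(floor_frac) >= 1,
            all(floor_frac >= 0))
  if (!identical(initial_temperature, "AUTO")) {
    stopifnot(is.numeric(initial_temperature), initial_temperature >= 0)
  }
  restarts <- min(as.integer(restarts), as.integer(n_iterations))
  if (identical(steps_per_temperature, "SCALED")) {
    steps_per_temperature <- max(1, ceiling(n_iterations / restarts / 100))
  }
  stopifnot(cooling_factor > 0, cooling_factor < 1,
            steps_per_temperature >= 1,
            proposal_width > 0, proposal_width <= 1)
  structure(
    list(n_iterations = as.integer(n_iterations),
         initial_temperature = initial_temperature,
         cooling_factor = cooling_factor,
         steps_per_temperature = as.integer(steps_per_temperature),
         proposal_width = proposal_width, restarts = restarts,
         jump_prob = jump_prob, vector_prob = vector_prob,
         adapt_width = isTRUE(adapt_width), floor_frac = floor_frac,
         seed = as.integer(seed)),
    class = "sa_config"
  )
}

validate_bounds <- function(bounds) {
  stopifnot(all(c("param", "lower", "upper") %in% names(bounds)))
  if (any(bounds$lower > bounds$upper)) {
    stop("bounds must satisfy lower <= upper", call. = FALSE)
  }
  invisible(bounds)
}

# uniform draw within bounds (frozen parameters stay at their bound)
draw_uniform <- function(bounds) {
  stats::setNames(
    bounds$lower + stats::runif(nrow(bounds)) * (bounds$upper - bounds$lower),
    bounds$param
  )
}

#' Simulated-annealing minimization over bounded parameters
#'
#' Minimizes `objective` over the box given by `bounds`, recording every
#' evaluation. `objective` takes a named parameter vector and returns either
#' a single finite score or a named vector of score components (the search
#' then minimizes the sum of `score_components`, or of all components); the
#' components are recorded alongside, which lets a calibration phase search
#' one endpoint's score while logging all endpoints from the same model run.
#' A non-finite score aborts with the offending parameter vector. Zero-width
#' bounds freeze a parameter at its value.
#'
#' @param objective Function of a named parameter vector.
#' @param bounds Tibble with columns `param`, `lower`, `upper`.
#' @param config An [sa_config()].
#' @param score_components Optional character vector naming which objective
#'   components form the minimized score.
#' @return A tibble of class `eac_sa_evals` with one row per evaluation:
#'   `iteration`, one column per parameter, the objective components,
#'   `score` (the minimized scalar) and `accepted` (whether the evaluation
#'   became the chain's current point), plus attributes `param_names` and
#'   `best` (row index of the best evaluation, earliest on ties).
#' @examples
#' b <- tibble::tibble(param = "x", lower = 0, upper = 1)
#' evals <- sa_search(function(p) (p[["x"]] - 0.3)^2, b,
#'                    sa_config(n_iterations = 500, seed = 7))
#' evals[attr(evals, "best"), ]
#' @export
sa_search <- function(objective, bounds, config = sa_config(),
                      score_components = NULL) {
  validate_bounds(bounds)
  n <- config$n_iterations
  npar <- nrow(bounds)
  width <- bounds$upper - bounds$lower
  free <- which(width > 0)

  eval_obj <- function(x) {
    v <- objective(x)
    if (any(!is.finite(v))) {
      stop("objective returned a non-finite value at parameters: ",
           paste(sprintf("%s=%.6g", names(x), x), collapse = ", "),
           call. = FALSE)
    }
    v
  }
  scalar_of <- function(v) {
    if (is.null(score_components)) sum(v) else sum(v[score_components])
  }

  withr_seed(config$seed, {
    x <- draw_uniform(bounds)
    v <- eval_obj(x)
    ncomp <- length(v)
    comp_names <- if (is.null(names(v)) && ncomp == 1L) "score" else names(v)

    P <- matrix(NA_real_, n, npar, dimnames = list(NULL, bounds$param))
    comp <- matrix(NA_real_, n, ncomp, dimnames = list(NULL, comp_names))
    score <- numeric(n)
    accepted <- logical(n)
    P[1L, ] <- x
    comp[1L, ] <- v
    score[1L] <- scalar_of(v)
    accepted[1L] <- TRUE

    temp0 <- config$initial_temperature
    if (identical(temp0, "AUTO")) {
      temp0 <- if (n == 1L || !length(free)) 0 else {
        diffs <- replicate(50, abs(scalar_of(eval_obj(draw_uniform(bounds))) -
                                     scalar_of(eval_obj(draw_uniform(bounds)))))
        stats::median(diffs)
      }
    }

    # segment starts: fresh uniform draw and a reheated temperature;
    # the temperature floor cycles through the configured ladder
    seg_len <- ceiling(n / config$restarts)
    seg_start <- 1L
    seg_num <- 1L
    floor_of <- function(k) {
      config$floor_frac[(k - 1L) %% length(config$floor_frac) + 1L]
    }

    cur <- x
    cur_s <- score[1L]
    best_s <- cur_s
    if (n > 1L && length(free)) {
      for (i in 2:n) {
        if (i - seg_start >= seg_len) {     # restart a new annealing segment
          seg_start <- i
          seg_num <- seg_num + 1L
          cur <- draw_uniform(bounds)
          v <- eval_obj(cur)
          cur_s <- scalar_of(v)
          P[i, ] <- cur
          comp[i, ] <- v
          score[i] <- cur_s
          accepted[i] <- TRUE
          best_s <- min(best_s, cur_s)
          next
        }
        temp <- temp0 * config$cooling_factor^
          ((i - seg_start) %/% config$steps_per_temperature)
        # the floor never applies to an explicitly zero temperature
        # (temperature 0 must stay strict stochastic hill-descent)
        if (temp0 > 0) {
          temp <- max(temp, floor_of(seg_num) * (1 + best_s))
        }
        wfrac <- if (config$adapt_width && temp0 > 0) {
          config$proposal_width * max(sqrt(temp / temp0), 0.05)
        } else {
          config$proposal_width
        }
        reflect <- function(xj, j) {
          while (xj < bounds$lower[j] || xj > bounds$upper[j]) {
            if (xj < bounds$lower[j]) xj <- 2 * bounds$lower[j] - xj
            if (xj > bounds$upper[j]) xj <- 2 * bounds$upper[j] - xj
          }
          xj
        }
        prop <- cur
        u <- stats::runif(1)
        if (u < config$jump_prob) {
          # full-range redraw of one parameter
          j <- free[[sample.int(length(free), 1L)]]
          prop[[j]] <- bounds$lower[j] + stats::runif(1) * width[j]
        } else if (u < config$jump_prob + config$vector_prob) {
          # joint small step in every free parameter (ridge moves)
          steps <- stats::runif(length(free), -1, 1) * 0.25 * wfrac *
            width[free]
          for (k2 in seq_along(free)) {
            j <- free[k2]
            prop[[j]] <- reflect(prop[[j]] + steps[k2], j)
          }
        } else {
          # local step in one parameter
          j <- free[[sample.int(length(free), 1L)]]
          prop[[j]] <- reflect(prop[[j]] +
                                 stats::runif(1, -1, 1) * wfrac * width[j], j)
        }
        v <- eval_obj(prop)
        s <- scalar_of(v)
        P[i, ] <- prop
        comp[i, ] <- v
        score[i] <- s
        d <- s - cur_s
        if (d <= 0 || (temp > 0 && stats::runif(1) < exp(-d / temp))) {
          cur <- prop
          cur_s <- s
          accepted[i] <- TRUE
        }
        best_s <- min(best_s, s)
      }
    } else if (n > 1L) {
      # all parameters frozen: repeated evaluation of the same point
      for (i in 2:n) {
        P[i, ] <- x
        comp[i, ] <- comp[1L, ]
        score[i] <- score[1L]
        accepted[i] <- TRUE
      }
    }

    out <- tibble::as_tibble(as.data.frame(P))
    if (!(ncomp == 1L && comp_names == "score")) {
      out <- dplyr::bind_cols(out, tibble::as_tibble(as.data.frame(comp)))
    }
    out$score <- score
    out$accepted <- accepted
    out <- dplyr::bind_cols(tibble::tibble(iteration = seq_len(n)), out)
    structure(out, param_names = bounds$param,
              best = which.min(score)[1],
              class = c("eac_sa_evals", class(out)))
  })
}

#' Narrow parameter bounds to the envelope of the best evaluations
#'
#' Keeps the `keep_fraction` of evaluations with the lowest scores (ties
#' broken by evaluation order, earlier wins) and returns, per parameter, the
#' `[min, max]` envelope of the kept sets. The new bounds are always nested
#' within the old ones; with `keep_fraction = 1` the result is the envelope
#' of all evaluations, so the operation is idempotent on its own output.
#'
#' @param evaluated An `eac_sa_evals` tibble from [sa_search()] (or any
#'   tibble with parameter columns, a `score` column and an `iteration`
#'   column).
#' @param keep_fraction Fraction in (0, 1] of evaluations to keep
#'   (default 0.10).
#' @param param_names Parameter columns; defaults to the tibble's
#'   `param_names` attribute.
#' @return Tibble `param`, `lower`, `upper`.
#' @export
narrow_bounds <- function(evaluated, keep_fraction = 0.10,
                          param_names = NULL) {
  if (nrow(evaluated) == 0L) stop("no evaluations to narrow", call. = FALSE)
  stopifnot(keep_fraction > 0, keep_fraction <= 1)
  if (is.null(param_names)) param_names <- attr(evaluated, "param_names")
  if (is.null(param_names)) {
    param_names <- intersect(names(evaluated), param_vector_names())
  }
  k <- max(1L, round(keep_fraction * nrow(evaluated)))
  ord <- order(evaluated$score, evaluated$iteration)[seq_len(k)]
  kept <- evaluated[ord, param_names, drop = FALSE]
  tibble::tibble(
    param = param_names,
    lower = unname(vapply(kept, min, numeric(1))),
    upper = unname(vapply(kept, max, numeric(1)))
  )
}
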