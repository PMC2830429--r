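# Health-state ordering and the calibrated parameter container.

# Fixed forward order; transitions may only move rightward (no regression),
# except NORMAL -> BE which skips GERD. DEATH is absorbing.
EAC_STATES <- c(
  "NORMAL", "GERD", "BE_SSBE", "BE_LSBE",
  "UNDETECTED_CA", "DETECTED_CA", "DEATH"
)

EAC_AGE_GROUPS <- c("20-29", "30-39", "40-49", "50-59", "60-69", "70-79")

#' Health states of the esophageal adenocarcinoma model
#'
#' Returns the six living health states plus the absorbing death state, in
#' their fixed progression order: normal mucosa, GERD symptoms, Barrett's
#' esophagus (short segment, then long segment), undetected cancer, detected
#' cancer, death. Probability mass only ever moves forward in this order.
#'
#' @return Character vector of state labels.
#' @export
health_states <- function() EAC_STATES

#' Ten-year age-group labels used throughout the model
#'
#' @return Character vector `"20-29"` ... `"70-79"`.
#' @export
age_groups <- function() EAC_AGE_GROUPS

# Age-group index for an integer age; ages above 79 reuse the last group's
# calibrated rates (piecewise-constant extrapolation).
age_group_index <- function(age) pmin((age - 20L) %/% 10L + 1L, 6L)

#' Age-group label for integer ages
#'
#' @param age Integer vector of ages (>= 20). Ages above 79 map to `"70-79"`.
#' @return Character vector of group labels.
#' @export
age_group_of <- function(age) {
  stopifnot(all(age >= 20))
  EAC_AGE_GROUPS[age_group_index(age)]
}

#' Transition parameters of the natural-history model
#'
#' Bundles the calibrated unknowns: annual probabilities of developing GERD
#' symptoms, of developing Barrett's esophagus (BE) directly from normal
#' mucosa, and of developing BE from the GERD state, each piecewise-constant
#' over the six ten-year age groups; the base (calendar-1973) annual
#' probability of progression from long-segment BE to undetected cancer; the
#' additive per-calendar-year slope of the linear secular multiplier on that
#' transition; and the mean sojourn time of undetected cancer before clinical
#' detection. Incident BE splits 1:3 into long- versus short-segment disease,
#' and short-segment BE progresses to cancer at half the long-segment rate;
#' both ratios are structural constants of the model.
#'
#' @param p_normal_gerd,p_normal_be,p_gerd_be Numeric vectors of annual
#'   transition probabilities, one value per ten-year age group (length 6, or
#'   length 1 recycled).
#' @param r_lsbe_ca Base annual probability of long-segment BE progressing to
#'   undetected cancer, anchored at calendar year 1973.
#' @param secular_slope Additive per-year increment of the secular multiplier
#'   `m(y) = max(0, 1 + secular_slope * (y - 1973))` applied to the BE-to-
#'   cancer transition.
#' @param mean_sojourn_years Mean years an undetected cancer remains
#'   undetected; must lie in `[4, 9]`. The annual detection probability is
#'   `1 - exp(-1 / mean_sojourn_years)`.
#' @param lsbe_fraction Fraction of incident BE that is long-segment; fixed
#'   at 0.25 (1:3 LSBE:SSBE).
#' @param ssbe_multiplier Progression-rate multiplier for short-segment BE;
#'   fixed at 0.5 (1:2 SSBE:LSBE progression).
#' @return An object of class `eac_params`.
#' @examples
#' transition_params(
#'   p_normal_gerd = 0.04, p_normal_be = 0.002, p_gerd_be = 0.004,
#'   r_lsbe_ca = 0.008, secular_slope = 0.05
#' )
#' @export
transition_params <- function(p_normal_gerd, p_normal_be, p_gerd_be,
                              r_lsbe_ca, secular_slope = 0,
                              mean_sojourn_years = 4.5,
                              lsbe_fraction = 0.25, ssbe_multiplier = 0.5) {
  expand6 <- function(x, nm) {
    if (length(x) == 1L) x <- rep(x, 6L)
    if (length(x) != 6L) {
      stop(nm, " must have length 1 or 6 (one value per age group)",
           call. = FALSE)
    }
    unname(as.numeric(x))
  }
  p <- list(
    p_normal_gerd = expand6(p_normal_gerd, "p_normal_gerd"),
    p_normal_be = expand6(p_normal_be, "p_normal_be"),
    p_gerd_be = expand6(p_gerd_be, "p_gerd_be"),
    r_lsbe_ca = as.numeric(r_lsbe_ca),
    secular_slope = as.numeric(secular_slope),
    mean_sojourn_years = as.numeric(mean_sojourn_years),
    lsbe_fraction = as.numeric(lsbe_fraction),
    ssbe_multiplier = as.numeric(ssbe_multiplier)
  )
  validate_params(p)
  structure(p, class = "eac_params")
}

validate_params <- function(p) {
  probs <- c(p$p_normal_gerd, p$p_normal_be, p$p_gerd_be, p$r_lsbe_ca)
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1)) {
    stop("transition probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (!is.finite(p$mean_sojourn_years) ||
      p$mean_sojourn_years < 4 || p$mean_sojourn_years > 9) {
    stop("mean_sojourn_years must lie in [4, 9]", call. = FALSE)
  }
  if (p$lsbe_fraction != 0.25) {
    stop("lsbe_fraction is a structural constant and must equal 0.25",
         call. = FALSE)
  }
  if (p$ssbe_multiplier != 0.5) {
    stop("ssbe_multiplier is a structural constant and must equal 0.5",
         call. = FALSE)
  }
  invisible(p)
}

#' @export
print.eac_params <- function(x, ...) {
  cat("<eac_params>\n")
  cat("  p_normal_gerd:", format(x$p_normal_gerd, digits = 4), "\n")
  cat("  p_normal_be:  ", format(x$p_normal_be, digits = 4), "\n")
  cat("  p_gerd_be:    ", format(x$p_gerd_be, digits = 4), "\n")
  cat("  r_lsbe_ca:", format(x$r_lsbe_ca, digits = 4),
      " secular_slope:", format(x$secular_slope, digits = 4),
      " sojourn:", x$mean_sojourn_years, "y\n")
  invisible(x)
}

# Flat named-vector codec used by the calibration machinery.
param_vector_names <- function() {
  c(paste0("p_normal_gerd_", 1:6), paste0("p_normal_be_", 1:6),
    paste0("p_gerd_be_", 1:6),
    "r_lsbe_ca", "secular_slope", "mean_sojourn_years")
}

#' Flatten transition parameters to a named vector
#'
#' The calibration machinery works on flat named vectors with one element per
#' free parameter (`p_normal_gerd_1` ... `mean_sojourn_years`). The two
#' structural constants (LSBE fraction, SSBE multiplier) are not included.
#'
#' @param params An `eac_params` object.
#' @return Named numeric vector of length 21.
#' @seealso [params_from_vector()]
#' @export
params_to_vector <- function(params) {
  stopifnot(inherits(params, "eac_params"))
  stats::setNames(
    c(params$p_normal_gerd, params$p_normal_be, params$p_gerd_be,
      params$r_lsbe_ca, params$secular_slope, params$mean_sojourn_years),
    param_vector_names()
  )
}

#' Rebuild transition parameters from a named vector
#'
#' Inverse of [params_to_vector()]. Elements absent from `x` fall back to
#' `base` (default: all zero probabilities, sojourn 4.5 years), so a
#' calibration may search any subset of the 21 free parameters.
#'
#' @param x Named numeric vector (subset of [params_to_vector()] names).
#' @param base `eac_params` supplying values for parameters absent from `x`.
#' @return An `eac_params` object.
#' @export
params_from_vector <- function(x, base = NULL) {
  if (is.null(base)) {
    base <- transition_params(0, 0, 0, r_lsbe_ca = 0, secular_slope = 0,
                              mean_sojourn_years = 4.5)
  }
  full <- params_to_vector(base)
  unknown <- setdiff(names(x), names(full))
  if (length(unknown)) {
    stop("unknown parameter name(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  full[names(x)] <- x
  transition_params(
    p_normal_gerd = full[paste0("p_normal_gerd_", 1:6)],
    p_normal_be = full[paste0("p_normal_be_", 1:6)],
    p_gerd_be = full[paste0("p_gerd_be_", 1:6)],
    r_lsbe_ca = full[["r_lsbe_ca"]],
    secular_slope = full[["secular_slope"]],
    mean_sojourn_years = full[["mean_sojourn_years"]]
  )
}
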