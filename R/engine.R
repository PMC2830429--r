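# Annual-cycle Markov cohort engine.
#
# Two routes share one set of rate definitions:
#  * build_transition_matrix() + simulate_cohort(): explicit 7x7 row-stochastic
#    matrices, one cohort at a time (clear, directly checkable against a
#    matrix-power oracle);
#  * sim_population_core(): a vectorized stepper that advances all overlapping
#    birth cohorts through one calendar year at a time (fast path used by
#    calibration). Tests assert the two routes agree.
#
# Competing risks within a cycle: death is applied first (probability q for the
# state), then disease transitions are distributed among survivors in
# proportion to their annual probabilities; if the probabilities of leaving a
# state sum above 1 they are rescaled proportionally so the row stays
# stochastic.

SECULAR_ANCHOR_YEAR <- 1973

secular_multiplier <- function(secular_slope, year) {
  pmax(0, 1 + secular_slope * (year - SECULAR_ANCHOR_YEAR))
}

# Aspirin (or other chemoprevention) multiplier on the BE -> undetected-cancer
# transition: (1 - annual reduction) for person-years where the intervention
# is active, 1 otherwise. Vectorized over age.
intervention_multiplier <- function(intervention, age, year) {
  if (is.null(intervention)) return(rep(1, length(age)))
  ifelse(age >= intervention$start_age & year >= intervention$start_year,
         1 - intervention$annual_reduction, 1)
}

# Per-age annual transition probabilities for one calendar year. Vectorized
# over `age`; returns the raw (uncapped) leaving probabilities per state.
rate_components <- function(params, age, year, intervention = NULL) {
  g <- age_group_index(age)
  m <- secular_multiplier(params$secular_slope, year)
  red <- intervention_multiplier(intervention, age, year)
  r_l <- pmin(1, params$r_lsbe_ca * m * red)
  r_s <- pmin(1, params$ssbe_multiplier * params$r_lsbe_ca * m * red)
  list(
    p_ng = params$p_normal_gerd[g],
    p_nb = params$p_normal_be[g],
    p_gb = pmin(1, params$p_gerd_be[g]),
    r_lsbe = r_l,
    r_ssbe = r_s,
    p_detect = 1 - exp(-1 / params$mean_sojourn_years)
  )
}

#' Build the one-year transition matrix for a given age and calendar year
#'
#' Constructs the 7x7 row-stochastic matrix over the model's health states
#' for one annual cycle. Death is resolved first (all-cause probability
#' `all_cause_q` in the pre-cancer states, cancer-specific probabilities in
#' the two cancer states); survivors then undergo disease transitions.
#' Incident Barrett's esophagus splits 1:3 into long- versus short-segment
#' disease; short-segment BE progresses at half the long-segment rate. The
#' BE-to-undetected-cancer entries carry the linear secular multiplier
#' anchored at 1973 and, when an intervention is active for this age and
#' year, the annual chemoprevention reduction. The undetected-to-detected
#' entry is `1 - exp(-1 / mean_sojourn_years)`.
#'
#' @param params An [transition_params()] object.
#' @param age Integer age (>= 20) of the cohort at the start of the cycle.
#' @param year Calendar year of the cycle.
#' @param all_cause_q Annual all-cause death probability at this age.
#' @param cancer_q Annual cancer-specific death probability; either a single
#'   value used for both cancer states or a length-2 vector
#'   `c(undetected, detected)`. An `NA` undetected entry applies
#'   `all_cause_q` to the undetected-cancer state instead (the clinically
#'   motivated alternative to the default cancer-specific mortality in
#'   both cancer states).
#' @param intervention Optional [intervention_spec()].
#' @return A 7x7 numeric matrix with rows and columns named by
#'   [health_states()]; every row sums to 1.
#' @examples
#' p <- transition_params(0.04, 0.002, 0.004, r_lsbe_ca = 0.008)
#' M <- build_transition_matrix(p, age = 55, year = 1986,
#'                              all_cause_q = 0.01, cancer_q = 0.35)
#' rowSums(M)
#' @export
build_transition_matrix <- function(params, age, year, all_cause_q, cancer_q,
                                    intervention = NULL) {
  stopifnot(inherits(params, "eac_params"), length(age) == 1L, age >= 20)
  validate_params(params)
  if (length(cancer_q) == 1L) cancer_q <- c(cancer_q, cancer_q)
  if (is.na(cancer_q[[1]])) cancer_q[[1]] <- all_cause_q
  qs <- c(all_cause_q, cancer_q)
  if (any(!is.finite(qs)) || any(qs < 0) || any(qs > 1)) {
    stop("mortality probabilities must lie in [0, 1]", call. = FALSE)
  }
  q_u <- cancer_q[[1]]
  q_d <- cancer_q[[2]]
  rc <- rate_components(params, age, year, intervention)
  f_l <- params$lsbe_fraction

  M <- matrix(0, 7, 7, dimnames = list(EAC_STATES, EAC_STATES))
  # row = state, entries: death first, then survivor transitions (rescaled to
  # keep the row stochastic if leaving probabilities exceed 1)
  fill_row <- function(state, q, dest_p) {
    s <- sum(dest_p)
    if (s > 1) dest_p <- dest_p / s
    M[state, "DEATH"] <<- M[state, "DEATH"] + q
    for (d in names(dest_p)) M[state, d] <<- M[state, d] + (1 - q) * dest_p[[d]]
    M[state, state] <<- M[state, state] + (1 - q) * (1 - min(1, s))
  }
  fill_row("NORMAL", all_cause_q, c(
    GERD = rc$p_ng, BE_LSBE = f_l * rc$p_nb, BE_SSBE = (1 - f_l) * rc$p_nb
  ))
  fill_row("GERD", all_cause_q, c(
    BE_LSBE = f_l * rc$p_gb, BE_SSBE = (1 - f_l) * rc$p_gb
  ))
  fill_row("BE_SSBE", all_cause_q, c(UNDETECTED_CA = rc$r_ssbe))
  fill_row("BE_LSBE", all_cause_q, c(UNDETECTED_CA = rc$r_lsbe))
  fill_row("UNDETECTED_CA", q_u, c(DETECTED_CA = rc$p_detect))
  fill_row("DETECTED_CA", q_d, stats::setNames(numeric(0), character(0)))
  M["DEATH", "DEATH"] <- 1
  M
}

#' Simulate a single birth cohort
#'
#' Propagates a cohort that enters the model in the normal state at age 20
#' (calendar year `birth_year + 20`) through annual cycles until the start of
#' `end_year`, applying [build_transition_matrix()] at the cohort's current
#' age and calendar year. Pre-cancer states die at the age-specific all-cause
#' probability; cancer states at the cancer-specific probabilities.
#'
#' @param params An [transition_params()] object.
#' @param birth_year Calendar year of birth; the cohort enters at
#'   `birth_year + 20`.
#' @param life_table Tibble with columns `age`, `q` (annual all-cause death
#'   probability), covering every age the cohort reaches.
#' @param cancer_mortality Length-2 numeric `c(undetected, detected)` annual
#'   cancer death probabilities (a single value is recycled).
#' @param end_year Last calendar year; the trajectory records state occupancy
#'   at the start of every year from entry through `end_year`.
#' @param intervention Optional [intervention_spec()].
#' @return An object of class `eac_cohort`: a list with `birth_year`,
#'   integer vectors `years` and `ages`, an occupancy matrix (one row per
#'   recorded year, columns [health_states()]), and per-cycle vectors
#'   `new_detections` and `deaths` (fractions of the original cohort).
#' @export
simulate_cohort <- function(params, birth_year, life_table, cancer_mortality,
                            end_year, intervention = NULL) {
  stopifnot(inherits(params, "eac_params"))
  entry_year <- birth_year + 20L
  if (entry_year > end_year) {
    stop("cohort enters after end_year (birth_year + 20 must be <= end_year)",
         call. = FALSE)
  }
  n_cycles <- end_year - entry_year
  ages <- 20L + 0:n_cycles
  lq <- lifetable_vector(life_table)
  need <- utils::head(ages, -1L)
  if (n_cycles > 0 && (min(need) < attr(lq, "min_age") ||
                       max(need) > attr(lq, "max_age"))) {
    stop("life table does not cover ages ", min(need), "-", max(need),
         call. = FALSE)
  }
  if (length(cancer_mortality) == 1L) {
    cancer_mortality <- rep(cancer_mortality, 2L)
  }

  occ <- matrix(0, n_cycles + 1L, 7L,
                dimnames = list(NULL, EAC_STATES))
  occ[1L, "NORMAL"] <- 1
  new_det <- numeric(n_cycles)
  deaths <- numeric(n_cycles)
  for (t in seq_len(n_cycles)) {
    age <- ages[t]
    year <- entry_year + t - 1L
    M <- build_transition_matrix(
      params, age, year,
      all_cause_q = lq[age - attr(lq, "min_age") + 1L],
      cancer_q = cancer_mortality, intervention = intervention
    )  # an NA undetected entry falls back to all-cause mortality
    v <- occ[t, ]
    occ[t + 1L, ] <- v %*% M
    new_det[t] <- v[["UNDETECTED_CA"]] * M["UNDETECTED_CA", "DETECTED_CA"]
    deaths[t] <- occ[t + 1L, "DEATH"] - v[["DEATH"]]
  }
  structure(
    list(birth_year = birth_year, years = entry_year + 0:n_cycles,
         ages = ages, occupancy = occ,
         new_detections = new_det, deaths = deaths),
    class = "eac_cohort"
  )
}

# ---- fast multi-cohort population engine ------------------------------------

# Advances all overlapping birth cohorts (entry at age 20, one cohort per
# calendar year, unit mass at entry) and records calendar-year cross-sections.
# Prevalences are % of the alive population at the start of the year;
# incidence is detections during the year per 100,000 alive at the start of
# the year. Cohorts are dropped once they age past `max_age`, so the life
# table only needs support on [20, max_age].
sim_population_core <- function(params, years, dem, intervention = NULL,
                                max_age = 79L) {
  years <- sort(unique(as.integer(years)))
  span <- max_age - 20L
  e_start <- min(years) - span
  e_end <- max(years)
  n_coh <- e_end - e_start + 1L

  lq <- lifetable_vector(dem$life_table)
  if (attr(lq, "min_age") > 20L || attr(lq, "max_age") < max_age) {
    stop("life table must cover ages 20-", max_age, call. = FALSE)
  }
  lq_at <- function(age) lq[age - attr(lq, "min_age") + 1L]
  # NA undetected mortality = the all-cause switch: the undetected state
  # keeps age-dependent background mortality instead of cancer mortality
  u_all_cause <- is.na(dem$cancer_mortality[["undetected"]])
  q_u <- dem$cancer_mortality[["undetected"]]
  q_d <- dem$cancer_mortality[["detected"]]

  ng <- age_group_index(max_age)
  ny <- length(years)
  gerd <- be <- inc <- matrix(NA_real_, ny, ng)

  N <- G <- S <- L <- U <- D <- X <- numeric(n_coh)
  f_l <- params$lsbe_fraction
  p_detect <- 1 - exp(-1 / params$mean_sojourn_years)
  has_iv <- !is.null(intervention)

  for (y in e_start:e_end) {
    i_hi <- y - e_start + 1L
    N[i_hi] <- 1                       # newborn cohort enters at age 20
    i_lo <- max(1L, i_hi - span)
    idx <- i_lo:i_hi
    ages <- 20L + (y - e_start) - (idx - 1L)
    g <- age_group_index(ages)
    q <- lq_at(ages)
    if (u_all_cause) q_u <- q

    yi <- match(y, years)
    record <- !is.na(yi)
    if (record) {
      alive <- 1 - X[idx]
      cross <- rowsum(cbind(gerd = G[idx], be = S[idx] + L[idx],
                            alive = alive), group = g)
      if (nrow(cross) != ng) {
        stop("requested year ", y, " has unpopulated age groups",
             call. = FALSE)
      }
      ord <- as.integer(rownames(cross))
      gerd[yi, ord] <- 100 * cross[, "gerd"] / cross[, "alive"]
      be[yi, ord] <- 100 * cross[, "be"] / cross[, "alive"]
    }

    m <- secular_multiplier(params$secular_slope, y)
    red <- if (has_iv) intervention_multiplier(intervention, ages, y) else 1
    r_l <- pmin(1, params$r_lsbe_ca * m * red)
    r_s <- pmin(1, params$ssbe_multiplier * params$r_lsbe_ca * m * red)
    p_ng <- params$p_normal_gerd[g]
    p_nb <- params$p_normal_be[g]
    p_gb <- pmin(1, params$p_gerd_be[g])

    s_tot <- p_ng + p_nb
    scl <- ifelse(s_tot > 1, 1 / s_tot, 1)
    p_ng_e <- p_ng * scl
    p_nb_e <- p_nb * scl

    sN <- N[idx] * (1 - q)
    sG <- G[idx] * (1 - q)
    sS <- S[idx] * (1 - q)
    sL <- L[idx] * (1 - q)
    sU <- U[idx] * (1 - q_u)
    sD <- D[idx] * (1 - q_d)

    toG <- sN * p_ng_e
    toBE_N <- sN * p_nb_e
    toBE_G <- sG * p_gb
    toU_S <- sS * r_s
    toU_L <- sL * r_l
    toD <- sU * p_detect

    X[idx] <- X[idx] + q * (N[idx] + G[idx] + S[idx] + L[idx]) +
      q_u * U[idx] + q_d * D[idx]
    N[idx] <- sN - toG - toBE_N
    G[idx] <- sG - toBE_G + toG
    S[idx] <- sS - toU_S + (1 - f_l) * (toBE_N + toBE_G)
    L[idx] <- sL - toU_L + f_l * (toBE_N + toBE_G)
    U[idx] <- sU - toD + toU_S + toU_L
    D[idx] <- sD + toD

    if (record) {
      det <- rowsum(toD, group = g)        # same sorted group order as `cross`
      inc[yi, as.integer(rownames(det))] <- 1e5 * det[, 1L] / cross[, "alive"]
    }
  }
  list(years = years, age_groups = EAC_AGE_GROUPS[seq_len(ng)],
       gerd = gerd, be = be, inc = inc)
}

#' Simulate the overlapping-cohort population
#'
#' Stacks one birth cohort per calendar year (each entering the normal state
#' at age 20 with unit mass) so that every age from 20 to `max_age` is
#' populated in every requested year, and reports calendar-year
#' cross-sections: GERD-symptom prevalence, Barrett's esophagus prevalence
#' (both as % of the alive population), and detected-cancer incidence per
#' 100,000 alive, by ten-year age group. Entry cohorts start
#' `max_age - 20` years before the first requested year.
#'
#' @param params An [transition_params()] object.
#' @param years Integer vector of calendar years to report.
#' @param demography An [eac_demography()] object.
#' @param intervention Optional [intervention_spec()].
#' @param max_age Oldest age retained in the population (default 79; cohorts
#'   are dropped after this age). Use a smaller value, e.g. 49, to restrict
#'   the model to the first age groups.
#' @return A tibble of class `eac_population` with columns `year`,
#'   `age_group`, `gerd_prev`, `be_prev`, `eac_incidence`.
#' @examples
#' p <- transition_params(0.04, 0.002, 0.004, r_lsbe_ca = 0.008,
#'                        secular_slope = 0.04)
#' pop <- simulate_population(p, 1986, eac_demography())
#' pop
#' @export
simulate_population <- function(params, years, demography = eac_demography(),
                                intervention = NULL, max_age = 79L) {
  stopifnot(inherits(params, "eac_params"))
  validate_params(params)
  core <- sim_population_core(params, years, demography, intervention,
                              max_age = as.integer(max_age))
  out <- tidyr::expand_grid(year = core$years, age_group = core$age_groups)
  ord <- cbind(match(out$year, core$years), match(out$age_group, core$age_groups))
  out$gerd_prev <- core$gerd[ord]
  out$be_prev <- core$be[ord]
  out$eac_incidence <- core$inc[ord]
  structure(out, class = c("eac_population", class(out)))
}

#' Pivot a population cross-section to tidy endpoint/value form
#'
#' @param population An `eac_population` tibble from [simulate_population()].
#' @return Tibble with columns `year`, `age_group`, `endpoint`
#'   (`"GERD_PREV"`, `"BE_PREV"`, `"EAC_INCIDENCE"`), `value`.
#' @export
population_long <- function(population) {
  population |>
    tidyr::pivot_longer(
      cols = c("gerd_prev", "be_prev", "eac_incidence"),
      names_to = "endpoint", values_to = "value"
    ) |>
    dplyr::mutate(endpoint = dplyr::recode(.data$endpoint,
      gerd_prev = "GERD_PREV", be_prev = "BE_PREV",
      eac_incidence = "EAC_INCIDENCE"
    ))
}
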