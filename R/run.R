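# Configuration-driven entry points binding the modules into reproducible
# runs. A thin command-line wrapper over these functions ships in
# inst/cli/eacsim.R (subcommands: simulate, calibrate, validate, aspirin,
# make-synthetic).

#' Load and validate a run configuration
#'
#' Reads a YAML run configuration (or validates a list built in code),
#' applies defaults and reports every validation failure at once. One global
#' `seed` fans out to fixed per-stage child seeds so that stages can be
#' re-run in isolation reproducibly.
#'
#' Recognized fields: `seed`, `output_dir`, `years` (report years),
#' `max_age`; `demography` (`life_table` CSV path, `cancer_mortality`
#' with `undetected`/`detected`); `params` (explicit transition parameters
#' for `simulate`/`make-synthetic`: `p_normal_gerd`, `p_normal_be`,
#' `p_gerd_be`, `r_lsbe_ca`, `secular_slope`, `mean_sojourn_years`);
#' `targets` (`file` CSV path or `"builtin"`, `calibration_years`,
#' `validation_years` as `[first, last]` ranges); `calibration`
#' (`n_iterations`, `order`, `final_fraction`); `intervention`
#' (`five_year_reduction`, `start_year`, `start_age`); `synthetic`
#' (`noise_cv`).
#'
#' @param config Path to a YAML file, or a named list.
#' @param seed Optional override of the configured global seed.
#' @return A validated configuration list of class `eac_config`.
#' @export
run_config <- function(config, seed = NULL) {
  if (is.character(config)) {
    if (!file.exists(config)) {
      stop("config file not found: ", config, call. = FALSE)
    }
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  defaults <- list(
    seed = 1L, output_dir = ".", years = 1986L, max_age = 79L,
    demography = list(), params = NULL,
    targets = list(file = "builtin",
                   calibration_years = c(1973L, 2000L),
                   validation_years = c(2001L, 2005L)),
    calibration = list(n_iterations = 1000L, order = "forward",
                       final_fraction = 0.01),
    intervention = list(five_year_reduction = 0.5, start_year = 1960L,
                        start_age = 40L),
    synthetic = list(noise_cv = 0)
  )
  cfg <- utils::modifyList(defaults, config)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)

  errors <- character(0)
  note <- function(msg) errors <<- c(errors, msg)
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1L) {
    note("seed must be a single integer")
  }
  if (!is.numeric(cfg$years) || !length(cfg$years)) {
    note("years must be a nonempty numeric vector")
  }
  if (!is.numeric(cfg$max_age) || cfg$max_age < 29 || cfg$max_age > 100) {
    note("max_age must lie in [29, 100]")
  }
  lt <- cfg$demography$life_table
  if (!is.null(lt) && !file.exists(lt)) {
    note(paste0("demography life_table file not found: ", lt))
  }
  tf <- cfg$targets$file
  if (!identical(tf, "builtin") && !is.null(tf) && !file.exists(tf)) {
    note(paste0("targets file not found: ", tf))
  }
  if (!cfg$calibration$order %in% c("forward", "reverse")) {
    note("calibration order must be 'forward' or 'reverse'")
  }
  if (cfg$calibration$n_iterations < 1) {
    note("calibration n_iterations must be >= 1")
  }
  iv <- cfg$intervention
  if (iv$five_year_reduction < 0 || iv$five_year_reduction >= 1) {
    note("intervention five_year_reduction must lie in [0, 1)")
  }
  if (cfg$synthetic$noise_cv < 0) note("synthetic noise_cv must be >= 0")
  if (length(errors)) {
    stop("invalid configuration:\n  - ", paste(errors, collapse = "\n  - "),
         call. = FALSE)
  }
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = c("eac_config", "list"))
}

config_demography <- function(cfg) {
  lt <- if (is.null(cfg$demography$life_table)) {
    make_gompertz_life_table()
  } else {
    load_life_table(cfg$demography$life_table)
  }
  cm <- cfg$demography$cancer_mortality
  if (is.null(cm)) cm <- c(undetected = 0.35, detected = 0.35)
  eac_demography(life_table = lt, cancer_mortality = unlist(cm))
}

config_params <- function(cfg) {
  p <- cfg$params
  if (is.null(p)) {
    stop("config lacks explicit `params`; required for this command",
         call. = FALSE)
  }
  transition_params(
    p_normal_gerd = p$p_normal_gerd, p_normal_be = p$p_normal_be,
    p_gerd_be = p$p_gerd_be, r_lsbe_ca = p$r_lsbe_ca,
    secular_slope = p$secular_slope %||% 0,
    mean_sojourn_years = p$mean_sojourn_years %||% 4.5
  )
}

config_targets <- function(cfg) {
  span <- function(x) if (length(x) == 2L) x[1]:x[2] else as.integer(x)
  if (identical(cfg$targets$file, "builtin") || is.null(cfg$targets$file)) {
    representative_year_targets()
  } else {
    load_targets_csv(cfg$targets$file,
                     calibration_years = span(cfg$targets$calibration_years),
                     validation_years = span(cfg$targets$validation_years))
  }
}

write_run_metadata <- function(cfg, stage, path, extra = list()) {
  meta <- c(list(stage = stage, seed = cfg$seed,
                 stage_seed = derive_seed(cfg$seed, stage_index(stage)),
                 config_hash = rlang::hash(unclass(cfg)),
                 package_version = as.character(utils::packageVersion("eacsim"))),
            extra)
  jsonlite::write_json(meta, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

stage_index <- function(stage) {
  match(stage, c("simulate", "calibrate", "validate", "aspirin",
                 "make-synthetic"))
}

out_path <- function(cfg, file) {
  if (!dir.exists(cfg$output_dir)) {
    dir.create(cfg$output_dir, recursive = TRUE)
  }
  file.path(cfg$output_dir, file)
}

#' Run the population simulation from a configuration
#'
#' Simulates the population under the configuration's explicit parameters
#' and writes `population.csv` (tidy `year`, `age_group`, `endpoint`,
#' `value`) plus a metadata JSON stamped with the seed and a configuration
#' hash. Re-running the same configuration yields byte-identical outputs.
#'
#' @param config A path, list, or [run_config()] result.
#' @param seed Optional seed override.
#' @return The `eac_population` tibble, invisibly.
#' @export
run_simulate <- function(config, seed = NULL) {
  cfg <- as_config(config, seed)
  pop <- simulate_population(config_params(cfg), cfg$years,
                             config_demography(cfg),
                             max_age = cfg$max_age)
  readr::write_csv(population_long(pop), out_path(cfg, "population.csv"))
  write_run_metadata(cfg, "simulate", out_path(cfg, "simulate_meta.json"),
                     list(n_years = length(cfg$years)))
  invisible(pop)
}

#' Run a three-phase calibration from a configuration
#'
#' @inheritParams run_simulate
#' @return The `eac_calibration` object, invisibly. Writes `ensemble.csv`
#'   and `calibrate_meta.json`.
#' @export
run_calibrate <- function(config, seed = NULL) {
  cfg <- as_config(config, seed)
  calib <- three_phase_calibrate(
    config_targets(cfg), config_demography(cfg),
    config = sa_config(n_iterations = cfg$calibration$n_iterations,
                       seed = derive_seed(cfg$seed, stage_index("calibrate"))),
    order = cfg$calibration$order,
    final_fraction = cfg$calibration$final_fraction
  )
  write_ensemble(calib, out_path(cfg, "ensemble.csv"),
                 out_path(cfg, "ensemble_meta.json"))
  write_run_metadata(cfg, "calibrate", out_path(cfg, "calibrate_meta.json"),
                     list(best_gof = calib$ensemble$gof_total[1],
                          ensemble_size = nrow(calib$ensemble)))
  invisible(calib)
}

#' Validate a calibrated ensemble from a configuration
#'
#' Refuses explicitly (writing nothing) when the target set carries no
#' validation targets.
#'
#' @inheritParams run_simulate
#' @param calibration An `eac_calibration` (e.g. from [run_calibrate()]).
#' @return The `eac_validation` object, invisibly. Writes
#'   `validation.json`.
#' @export
run_validate <- function(config, calibration, seed = NULL) {
  cfg <- as_config(config, seed)
  targets <- config_targets(cfg)
  report <- validate_calibration(calibration, targets,
                                 config_demography(cfg))
  jsonlite::write_json(
    report[c("adjusted_gof_calibration", "adjusted_gof_validation",
             "ratio", "passed", "n_calibration_years",
             "n_validation_years")],
    out_path(cfg, "validation.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE
  )
  write_run_metadata(cfg, "validate", out_path(cfg, "validate_meta.json"))
  invisible(report)
}

#' Run the aspirin counterfactual from a configuration
#'
#' @inheritParams run_validate
#' @return The `eac_counterfactual` tibble, invisibly. Writes
#'   `aspirin_report.csv` and `aspirin_meta.json` (which records the derived
#'   annual reduction).
#' @export
run_aspirin <- function(config, calibration, seed = NULL) {
  cfg <- as_config(config, seed)
  spec <- intervention_spec(cfg$intervention$five_year_reduction,
                            cfg$intervention$start_year,
                            cfg$intervention$start_age)
  message("aspirin: five-year reduction ", spec$five_year_reduction,
          " -> annual reduction ", format(spec$annual_reduction, digits = 5))
  report <- run_counterfactual(calibration, spec, config_demography(cfg))
  readr::write_csv(report, out_path(cfg, "aspirin_report.csv"))
  write_run_metadata(cfg, "aspirin", out_path(cfg, "aspirin_meta.json"),
                     list(annual_reduction = spec$annual_reduction))
  invisible(report)
}

#' Generate synthetic targets from a configuration
#'
#' @inheritParams run_simulate
#' @return The synthetic [eac_targets()], invisibly. Writes `targets.csv`.
#' @export
run_make_synthetic <- function(config, seed = NULL) {
  cfg <- as_config(config, seed)
  span <- function(x) if (length(x) == 2L) x[1]:x[2] else as.integer(x)
  tg <- generate_synthetic_targets(
    config_params(cfg),
    calibration_years = span(cfg$targets$calibration_years),
    validation_years = span(cfg$targets$validation_years),
    demography = config_demography(cfg),
    noise_cv = cfg$synthetic$noise_cv,
    seed = derive_seed(cfg$seed, stage_index("make-synthetic")),
    max_age = cfg$max_age
  )
  write_targets_csv(tg, out_path(cfg, "targets.csv"))
  write_run_metadata(cfg, "make-synthetic",
                     out_path(cfg, "make_synthetic_meta.json"))
  invisible(tg)
}

as_config <- function(config, seed = NULL) {
  if (inherits(config, "eac_config") && is.null(seed)) config
  else run_config(config, seed)
}

#' Dispatch a named pipeline stage
#'
#' Programmatic equivalent of the command-line interface: runs one of
#' `simulate`, `calibrate`, `validate`, `aspirin` or `make-synthetic`
#' against a configuration. `validate` and `aspirin` run `calibrate` first
#' when no calibration object is supplied.
#'
#' @param command Stage name.
#' @param config Path, list or [run_config()] result.
#' @param seed Optional seed override.
#' @param calibration Optional `eac_calibration` for the dependent stages.
#' @return The stage's result object, invisibly.
#' @export
eac_run <- function(command = c("simulate", "calibrate", "validate",
                                "aspirin", "make-synthetic"),
                    config, seed = NULL, calibration = NULL) {
  command <- match.arg(command)
  cfg <- as_config(config, seed)
  switch(command,
    "simulate" = run_simulate(cfg),
    "calibrate" = run_calibrate(cfg),
    "validate" = run_validate(cfg, calibration %||% run_calibrate(cfg)),
    "aspirin" = run_aspirin(cfg, calibration %||% run_calibrate(cfg)),
    "make-synthetic" = run_make_synthetic(cfg)
  )
}
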