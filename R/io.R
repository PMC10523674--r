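# Trial-dataset CSV schema, run configuration, checkpoints.

TRIAL_COLUMNS <- c("subject_id", "gender", "weight_kg", "nerve",
                   "neuropathic", "pa_mA", "pw_us", "intensity", "stype",
                   "location", "se")

#' Validate a trial dataset against the schema
#'
#' Checks column names and order, enum spellings, the se range and the
#' grid membership of every stimulus; violations are reported with row
#' numbers.
#'
#' @param trials A tibble.
#' @param grid A [stim_grid()] for parameter validation.
#' @return `trials`, invisibly.
#' @export
validate_trials <- function(trials, grid = stim_grid()) {
  if (!identical(names(trials), TRIAL_COLUMNS))
    stop("trial dataset must have exactly the columns: ",
         paste(TRIAL_COLUMNS, collapse = ", "), call. = FALSE)
  bad <- function(cond, what) {
    if (any(cond))
      stop(sprintf("invalid %s in trial rows: %s", what,
                   paste(utils::head(which(cond), 5), collapse = ", ")),
           call. = FALSE)
  }
  bad(!trials$gender %in% c("M", "F"), "gender")
  bad(!trials$nerve %in% c("peroneal", "tibial", "sural"), "nerve")
  bad(!trials$neuropathic %in% c(0, 1), "neuropathic flag")
  bad(!trials$intensity %in% INTENSITY_LEVELS, "intensity")
  bad(!trials$stype %in% TYPE_LEVELS, "stype")
  bad(!trials$location %in% LOCATION_LEVELS, "location")
  bad(trials$se < 0 | trials$se > 10 | trials$se != round(trials$se), "se")
  bad(!on_grid(trials$pa_mA, trials$pw_us, grid), "stimulation parameters")
  invisible(trials)
}

#' Read / write a trial dataset CSV
#'
#' UTF-8 comma-separated files with the exact ordered header
#' `subject_id, gender, weight_kg, nerve, neuropathic, pa_mA, pw_us,
#' intensity, stype, location, se`; round-trips are lossless.
#'
#' @param path CSV file path.
#' @param grid A [stim_grid()] used for validation.
#' @return `read_trials` returns the validated tibble; `write_trials`
#'   returns `path` invisibly.
#' @export
read_trials <- function(path, grid = stim_grid()) {
  trials <- readr::read_csv(path, show_col_types = FALSE,
                            col_types = readr::cols(
                              subject_id = readr::col_character(),
                              gender = readr::col_character(),
                              weight_kg = readr::col_double(),
                              nerve = readr::col_character(),
                              neuropathic = readr::col_integer(),
                              pa_mA = readr::col_double(),
                              pw_us = readr::col_double(),
                              intensity = readr::col_character(),
                              stype = readr::col_character(),
                              location = readr::col_character(),
                              se = readr::col_integer()))
  validate_trials(trials, grid)
  trials
}

#' @rdname read_trials
#' @param trials A validated trial tibble.
#' @export
write_trials <- function(trials, path, grid = stim_grid()) {
  validate_trials(trials, grid)
  readr::write_csv(trials, path)
  invisible(path)
}

#' Read a run configuration
#'
#' YAML configuration covering the grid, hyperparameters, reward values,
#' cohort composition, environment settings, calibration limits and
#' seeds. Unknown top-level keys are rejected. Every section is optional;
#' omitted sections fall back to the package defaults.
#'
#' @param path YAML file.
#' @return A list of class `run_config` with constructed component
#'   objects (`grid`, `hyperparams`, `cohort`, `env`, `limits`, `seed`).
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- c("grid", "hyperparams", "rewards", "cohort", "env", "limits",
             "seed")
  extra <- setdiff(names(raw), known)
  if (length(extra))
    stop("unknown config keys: ", paste(extra, collapse = ", "),
         call. = FALSE)
  # YAML maps arrive as lists; constructor arguments that are numeric
  # vectors (grids, per-nerve counts, per-gender means) need flattening
  build <- function(fn, args) {
    args <- lapply(args %||% list(),
                   function(x) if (is.list(x)) unlist(x) else x)
    do.call(fn, args)
  }
  cfg <- list(
    grid = build(stim_grid, raw$grid),
    hyperparams = build(dqn_hyperparams, raw$hyperparams),
    rewards = raw$rewards,
    cohort = build(cohort_spec, raw$cohort),
    env = build(env_config, raw$env),
    limits = build(calib_limits, raw$limits),
    seed = raw$seed %||% 1L)
  class(cfg) <- "run_config"
  cfg
}

default_run_config <- function(seed = 1L) {
  structure(list(grid = stim_grid(), hyperparams = dqn_hyperparams(),
                 rewards = NULL, cohort = cohort_spec(seed = seed),
                 env = env_config(seed = seed),
                 limits = calib_limits(), seed = seed),
            class = "run_config")
}

#' Save / load a versioned checkpoint
#'
#' Checkpoints (fitted environments, trained agents) are serialized
#' containers tagged with a format version and the object class; loading
#' refuses containers written by an unknown format.
#'
#' @param object An `env_models` or `dqn_agent` object.
#' @param path Destination file.
#' @return `path` / the restored object.
#' @export
save_checkpoint <- function(object, path) {
  saveRDS(list(format = "tenscal-checkpoint", version = 1L,
               class = class(object), object = object), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  x <- readRDS(path)
  if (!identical(x$format, "tenscal-checkpoint") ||
      !identical(x$version, 1L))
    stop("not a recognized checkpoint: ", path, call. = FALSE)
  x$object
}

#' Serialize a calibration result to JSON
#'
#' @param result A `calibration_result`.
#' @param path Destination JSON file.
#' @return `path`, invisibly.
#' @export
write_calibration_json <- function(result, path) {
  jsonlite::write_json(
    list(method = result$method,
         low_params = result$low_params, high_params = result$high_params,
         n_stims = result$n_stims,
         converged = as.list(result$converged),
         aborted = as.list(result$aborted),
         trace = result$trace),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
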