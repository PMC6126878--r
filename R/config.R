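# Configuration loading/validation, run output writers, and the manifest.

#' Default run configuration
#'
#' The fully resolved configuration used when a config file omits fields:
#' the fixed model parameter set, an intact lesion spec, the calibrated task
#' tables, and cohort settings.
#'
#' @return A nested named list (`model`, `lesion`, `tasks`, `cohort`).
#' @export
rml_defaults <- function() {
  list(
    model = list(rho = 0.2, mu = 0.1, tau = 0.6, alpha = 0.3, beta = 0.2,
                 omega = 0.15, n_boost_levels = 10L),
    lesion = list(da_gain = 1, dacc_gain = 1),
    tasks = list(
      bandit = list(n_trials = 432L, p_levels = c(0.7, 0.3),
                    m_levels = c(1.0, 1.5), stat2_p = 0.6, stat2_m = 1.25,
                    switch_period = 30L),
      effort = list(hr_magnitude = 1.3, lr_magnitude = 0.4, high_cost = 2.5,
                    low_cost = 0.2, n_trials = 150L),
      chain = list(max_order = 3L, n_trials_per_stage = 100L,
                   reward_magnitude = 1.0)),
    cohort = list(n_subjects = 12L, base_seed = 1L, window = 0.25))
}

merge_config <- function(defaults, user, path = "") {
  for (nm in names(user)) {
    here <- if (nzchar(path)) paste0(path, ".", nm) else nm
    if (!nm %in% names(defaults))
      stop("unknown configuration key: ", here, call. = FALSE)
    if (is.list(defaults[[nm]]) && !is.null(names(defaults[[nm]]))) {
      if (!is.list(user[[nm]]))
        stop("configuration key ", here, " must be a mapping", call. = FALSE)
      defaults[[nm]] <- merge_config(defaults[[nm]], user[[nm]], here)
    } else {
      defaults[[nm]] <- user[[nm]]
    }
  }
  defaults
}

#' Load and validate a run configuration
#'
#' Reads a YAML or JSON configuration file, rejects unknown keys (with the
#' path to the offending field), fills omitted fields with [rml_defaults()],
#' and validates the model-parameter constraints.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file. An empty file (or
#'   empty mapping) yields the full default configuration.
#' @return A validated configuration list with class `rml_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  user <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  cfg <- merge_config(rml_defaults(), user)
  do.call(rml_params, cfg$model)            # validates model constraints
  do.call(lesion_spec, cfg$lesion)
  if (cfg$cohort$n_subjects < 1L)
    stop("cohort.n_subjects must be >= 1", call. = FALSE)
  structure(cfg, class = "rml_config")
}

#' Write a configuration to file
#'
#' @param config Configuration list (as from [load_config()] or
#'   [rml_defaults()]).
#' @param path Destination `.yaml`/`.yml` or `.json` path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  config <- unclass(config)
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  else yaml::write_yaml(config, path)
  invisible(path)
}

#' Model parameters and lesion spec from a configuration
#'
#' @param config An `rml_config` (or compatible list).
#' @return `list(params, lesion)`.
#' @export
config_objects <- function(config) {
  list(params = do.call(rml_params, config$model),
       lesion = do.call(lesion_spec, config$lesion))
}

#' Write cohort outputs to a directory
#'
#' Writes one trial-log CSV per stored log, the cohort summary as JSON, an
#' echo of the configuration, and a manifest listing the subject seeds and
#' an MD5 checksum per file. Floats are serialized with full precision so a
#' rerun with the same configuration and seed reproduces identical
#' checksums.
#'
#' @param cohort An `rml_cohort`.
#' @param out_dir Output directory (created if missing).
#' @param config Optional configuration list to echo.
#' @return The manifest (invisibly), also written as `manifest.json`.
#' @export
write_outputs <- function(cohort, out_dir, config = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create ", out_dir, call. = FALSE)
  old <- options(digits = 17); on.exit(options(old))
  files <- character(0)
  log_names <- names(cohort$logs)
  if (is.null(log_names)) log_names <- sprintf("subject%02d",
                                               seq_along(cohort$logs))
  for (k in seq_along(cohort$logs)) {
    f <- file.path(out_dir, paste0("trials_", log_names[k], ".csv"))
    utils::write.csv(format(cohort$logs[[k]], digits = 17, trim = TRUE,
                            scientific = FALSE),
                     f, row.names = FALSE, quote = FALSE)
    files <- c(files, f)
  }
  f_sum <- file.path(out_dir, "summary.json")
  jsonlite::write_json(list(schema_version = 1L, kind = cohort$kind,
                            summary = cohort$summary, seeds = cohort$seeds),
                       f_sum, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  files <- c(files, f_sum)
  if (!is.null(config)) {
    f_cfg <- file.path(out_dir, "config.yaml")
    write_config(config, f_cfg)
    files <- c(files, f_cfg)
  }
  manifest <- list(kind = cohort$kind, seeds = cohort$seeds,
                   files = data.frame(
                     file = basename(files),
                     md5 = unname(tools::md5sum(files)),
                     stringsAsFactors = FALSE))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
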