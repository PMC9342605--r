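#' Default experiment configuration
#'
#' The configuration that reproduces the two-group study: 10 subjects per
#' group, 1,000 training epochs, 100 test stimuli, control `Vmax` 1.2 and
#' imbalance `Vmax` 1.8, integrator step 1 ms.
#'
#' @return nested named list of defaults.
#' @export
default_config <- function() {
  list(
    base_seed = 1L,
    n_per_group = 10L,
    epochs = 1000L,
    n_test = 100L,
    dt = 1e-3,
    train_duration = 0.8,
    test_duration = 1.8,
    threshold = 0.9,
    sweep_sd = seq(0, 1, by = 0.1),
    gain_amplitudes = seq(0.1, 1, by = 0.1),
    control = list(Vmax = 1.2),
    imbalance = list(Vmax = 1.8),
    network = list(),
    learning = list(),
    out_dir = "results"
  )
}

#' Load and validate an experiment configuration
#'
#' Reads a YAML configuration file, fills every missing field with the
#' defaults of [default_config()] and validates the result.  Unknown
#' top-level keys are rejected so that typos fail loudly.  An empty file
#' yields the full default (paper-protocol) configuration.
#'
#' @param path path to a YAML file, or `NULL` for pure defaults.
#' @return validated configuration list of class `"run_config"`.
#' @examples
#' cfg <- load_config(NULL)
#' cfg$n_per_group
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    user <- yaml::read_yaml(path)
    if (is.null(user)) user <- list()
    bad <- setdiff(names(user), names(cfg))
    if (length(bad))
      stop("unknown config key(s): ", paste(bad, collapse = ", "))
    cfg <- modifyList(cfg, user)
  }
  validate_config(cfg)
  class(cfg) <- "run_config"
  cfg
}

validate_config <- function(cfg) {
  if (cfg$n_per_group < 1) stop("n_per_group must be >= 1")
  if (cfg$epochs < 4 || cfg$epochs %% 4 != 0)
    stop("epochs must be a positive multiple of 4")
  if (cfg$dt <= 0 || cfg$dt > 1e-3) stop("dt must lie in (0, 0.001]")
  if (cfg$threshold <= 0 || cfg$threshold >= 1)
    stop("threshold must lie in (0, 1)")
  for (g in c("control", "imbalance")) {
    v <- cfg[[g]]$Vmax
    if (!is.null(v) && v <= 0) stop(g, " Vmax must be > 0")
  }
  # constructor-level validation of overrides
  do.call(network_params, cfg$network)
  do.call(learning_params, cfg$learning)
  invisible(cfg)
}

#' Build the model parameter objects from a configuration
#'
#' @param cfg a [load_config()] configuration.
#' @return list with `net`, `lp`, and per-group `da` parameter objects.
#' @export
config_params <- function(cfg) {
  list(net = do.call(network_params, cfg$network),
       lp = do.call(learning_params, cfg$learning),
       da = list(control = do.call(da_params,
                   c(list(group = "control"), cfg$control)),
                 imbalance = do.call(da_params,
                   c(list(group = "imbalance"), cfg$imbalance))))
}

#' Write experiment results to disk
#'
#' Serialises an experiment: one CSV of per-trial test logs and one of
#' per-epoch training history per subject, a JSON group summary, the
#' configuration snapshot and a seed manifest sufficient for an exact
#' rerun.
#'
#' @param experiment result of [run_experiment()].
#' @param out_dir output directory (created if missing).
#' @param cfg optional configuration to snapshot alongside the results.
#' @return (invisibly) the manifest list.
#' @export
write_results <- function(experiment, out_dir, cfg = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  subj_files <- character(0)
  for (s in experiment$subjects) {
    id <- sprintf("%s_%02d", s$spec$group, s$spec$subject_id)
    train_df <- data.frame(epoch = seq_along(s$train$history),
                           target = s$train$target,
                           chosen = s$train$chosen,
                           rt = s$train$rt,
                           code = s$train$history)
    test_df <- data.frame(trial = seq_along(s$test$target),
                          target = s$test$target,
                          chosen = s$test$chosen,
                          rt = s$test$rt,
                          success = s$test$success)
    f1 <- file.path(out_dir, paste0("train_", id, ".csv"))
    f2 <- file.path(out_dir, paste0("test_", id, ".csv"))
    write.csv(train_df, f1, row.names = FALSE)
    write.csv(test_df, f2, row.names = FALSE)
    subj_files <- c(subj_files, f1, f2)
  }
  jsonlite::write_json(experiment$summary,
                       file.path(out_dir, "summary.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  manifest <- list(
    package_version = as.character(utils::packageVersion("tonicphasic")),
    seeds = lapply(experiment$subjects, function(s)
      list(group = s$spec$group, subject_id = s$spec$subject_id,
           noise_seed = s$spec$noise_seed)),
    files = basename(subj_files))
  if (!is.null(cfg))
    yaml::write_yaml(unclass(cfg), file.path(out_dir, "config.yaml"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
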