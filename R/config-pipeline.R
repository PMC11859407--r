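#' Load and validate a pipeline run configuration
#'
#' Reads a YAML file and fills in defaults for every stage of the pipeline.
#' Recognized top-level keys: `seed`, `out_dir`, `log_level`, `synth`
#' (arguments of [generate_dataset()]), `preprocess` (`band`, `order`,
#' `notch_hz`, `notch_q`, `envelope_hz`, `window`, `stride`, `input_repr`),
#' `classifier` (arguments of [classifier_config()]), `controller` (arguments
#' of [controller_config()]), `path` (one of the standard path kinds),
#' `simulate` (`duration`).  Unknown keys are rejected by name; stage values
#' are validated by the stage constructors before anything runs.
#'
#' @param file YAML path, or `NULL`/empty file for all defaults.
#' @return A validated list of class `run_config`.
#' @export
load_validate_config <- function(file = NULL) {
  raw <- if (is.null(file)) list() else {
    if (!file.exists(file)) rlang::abort(paste0("Config file not found: ", file))
    yaml::read_yaml(file) %||% list()
  }
  known <- c("seed", "out_dir", "log_level", "synth", "preprocess",
             "classifier", "controller", "path", "simulate")
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    rlang::abort(paste0("Unknown config key(s): ", paste(unknown, collapse = ", ")))
  }
  merge_defaults <- function(user, defaults, section) {
    user <- user %||% list()
    bad <- setdiff(names(user), names(defaults))
    if (length(bad)) {
      rlang::abort(sprintf("Unknown key(s) in `%s`: %s", section,
                           paste(bad, collapse = ", ")))
    }
    utils::modifyList(defaults, user)
  }
  cfg <- list(
    seed = raw$seed %||% 1L,
    out_dir = raw$out_dir %||% "myointent-out",
    log_level = raw$log_level %||% "info",
    synth = merge_defaults(raw$synth, list(
      n_subjects = 1, n_groups = 7, sets_per_group = 1,
      force_levels = c(5, 10, 15, 20, 25), phase_duration = 5,
      sample_rate = 2000
    ), "synth"),
    preprocess = merge_defaults(raw$preprocess, list(
      band = c(20, 450), order = 4, notch_hz = 50, notch_q = 30,
      envelope_hz = 10, window = 450, stride = 450, input_repr = "raw"
    ), "preprocess"),
    classifier = merge_defaults(raw$classifier, list(
      architecture = "mlcnn", learning_rate = 1e-3, num_filters_1 = 32,
      num_filters_2 = 64, dropout_rate = 0.5, dense_units = 128,
      batch_size = 64, l2_reg = 0, epochs = 30, patience = 5
    ), "classifier"),
    controller = merge_defaults(raw$controller, list(
      mode = "isotonic_closed_loop", target_offset = 0.030,
      smoothing_T = 0.4, kp = 0.15, ki = 0, kd = 0.5, rate = 60,
      workspace = c(0.6, 0.3), resistance_cap = 25, arrival_tol = 0.010
    ), "controller"),
    path = raw$path %||% "co_ptp",
    simulate = merge_defaults(raw$simulate, list(duration = 60), "simulate")
  )
  # validate by constructing the stage objects
  fs <- cfg$preprocess
  spec <- filter_spec(low = fs$band[1], high = fs$band[2], order = fs$order,
                      notch_hz = fs$notch_hz, notch_q = fs$notch_q,
                      envelope_hz = fs$envelope_hz)
  if (fs$band[2] >= cfg$synth$sample_rate / 2) {
    rlang::abort(sprintf(
      "Band-pass high cutoff (%g Hz) must be below the Nyquist frequency (%g Hz).",
      fs$band[2], cfg$synth$sample_rate / 2
    ))
  }
  if (!cfg$path %in% c("circle", "co_ptp", "sine1", "sine2")) {
    rlang::abort("`path` must be one of circle, co_ptp, sine1, sine2.")
  }
  cfg$filter_spec <- spec
  cfg$classifier_config <- do.call(classifier_config,
                                   c(cfg$classifier, list(seed = cfg$seed)))
  cfg$controller_config <- do.call(controller_config, cfg$controller)
  structure(cfg, class = "run_config")
}

#' Save a run configuration as YAML
#'
#' Writes the user-settable keys so that [load_validate_config()] on the
#' result is the identity.
#'
#' @param config A `run_config`.
#' @param file Output YAML path.
#' @return `file`, invisibly.
#' @export
save_config <- function(config, file) {
  keep <- c("seed", "out_dir", "log_level", "synth", "preprocess",
            "classifier", "controller", "path", "simulate")
  yaml::write_yaml(unclass(config)[keep], file)
  invisible(file)
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  save_config(config, tmp)
  unname(tools::md5sum(tmp))
}

pipeline_log <- function(config, ...) {
  if (identical(config$log_level, "quiet")) return(invisible())
  message(sprintf("[myointent %s] %s", format(Sys.time(), "%H:%M:%S"),
                  paste0(...)))
}

stage_fresh <- function(stamp_file, hash) {
  file.exists(stamp_file) && identical(readLines(stamp_file, warn = FALSE), hash)
}

#' Run the full offline pipeline
#'
#' Executes synth -> preprocess -> cross-validation -> closed-loop simulation
#' -> metrics in order, writing every artifact (plus the stamped config and a
#' machine-readable status file) under `config$out_dir`.  Stages whose output
#' already carries the current config hash are reused; a stage failure halts
#' the run with partial artifacts retained.
#'
#' @param config A `run_config` from [load_validate_config()].
#' @return Invisibly, a list with the cross-validation table, the trajectory
#'   and the metrics report.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config)
  save_config(config, file.path(config$out_dir, "config.yaml"))
  status <- list(config_hash = hash, seed = config$seed, stages = list())
  status_file <- file.path(config$out_dir, "status.json")
  write_status <- function() {
    jsonlite::write_json(status, status_file, auto_unbox = TRUE, digits = NA)
  }
  on.exit(write_status())

  run_stage <- function(name, outputs, compute) {
    stamp <- file.path(config$out_dir, paste0(name, ".stamp"))
    if (stage_fresh(stamp, hash) && all(file.exists(outputs))) {
      pipeline_log(config, "stage ", name, ": cached")
      status$stages[[name]] <<- "cached"
      return(invisible(NULL))
    }
    pipeline_log(config, "stage ", name, ": running")
    compute()
    writeLines(hash, stamp)
    status$stages[[name]] <<- "done"
    invisible(NULL)
  }

  sy <- config$synth
  dataset <- NULL
  windows_file <- file.path(config$out_dir, "windows.csv")

  run_stage("synth", file.path(config$out_dir, "dataset_index.csv"), function() {
    dataset <<- do.call(generate_dataset, c(sy, list(seed = config$seed)))
    idx <- dplyr::select(dataset$recordings, -"recording")
    utils::write.csv(idx, file.path(config$out_dir, "dataset_index.csv"),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(dataset$mvc),
                     file.path(config$out_dir, "mvc.csv"), row.names = FALSE)
  })
  if (is.null(dataset)) {
    dataset <- do.call(generate_dataset, c(sy, list(seed = config$seed)))
  }

  pp <- config$preprocess
  windows <- NULL
  run_stage("preprocess", character(0), function() {
    windows <<- preprocess_dataset(
      dataset, spec = config$filter_spec, input_repr = pp$input_repr,
      window = pp$window, stride = pp$stride
    )
    counts <- dplyr::count(windows, .data$group, .data$label)
    utils::write.csv(counts, file.path(config$out_dir, "window_counts.csv"),
                     row.names = FALSE)
  })
  if (is.null(windows)) {
    windows <- preprocess_dataset(
      dataset, spec = config$filter_spec, input_repr = pp$input_repr,
      window = pp$window, stride = pp$stride
    )
  }

  cv <- NULL
  cv_file <- file.path(config$out_dir, "crossval.csv")
  run_stage("crossval", cv_file, function() {
    cv <<- crossval_groups(windows, config$classifier_config,
                           seed = config$seed)
    utils::write.csv(
      dplyr::select(cv, -"confusion", -"model"), cv_file, row.names = FALSE
    )
    best <- cv$model[[which.max(cv$external_accuracy)]]
    save_model(best, file.path(config$out_dir, "model"))
  })

  traj <- NULL
  traj_file <- file.path(config$out_dir, "trajectory.csv")
  path <- path_spec(config$path)
  run_stage("simulate", traj_file, function() {
    patient <- simulated_patient(path, config$controller_config)
    traj <<- simulate_session(patient, config$controller_config,
                              duration = config$simulate$duration,
                              path = path, seed = config$seed)
    write_trajectory_csv(traj, traj_file)
  })
  if (is.null(traj)) traj <- read_trajectory_csv(traj_file)

  metrics_file <- file.path(config$out_dir, "metrics.json")
  report <- evaluate_trajectory(traj, path)
  write_metrics(report, metrics_file)
  status$stages[["metrics"]] <- "done"

  invisible(list(crossval = cv, trajectory = traj, metrics = report))
}
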