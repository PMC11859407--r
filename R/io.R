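#' Write / read a recording as CSV
#'
#' The on-disk dialect is one `time` column (seconds), one column per channel
#' (mV) and one `label` column, with a header row, UTF-8, '.' decimal.
#' Sample rate and metadata travel in a YAML sidecar (`<file>.meta.yaml`).
#'
#' @param recording An `emg_recording`.
#' @param file Output CSV path.
#' @return `file`, invisibly.
#' @export
write_recording_csv <- function(recording, file) {
  stopifnot(inherits(recording, "emg_recording"))
  df <- data.frame(
    time = (seq_len(nrow(recording$samples)) - 1) / recording$sample_rate,
    recording$samples, check.names = FALSE
  )
  df$label <- recording$labels
  utils::write.csv(df, file, row.names = FALSE, fileEncoding = "UTF-8")
  meta <- c(list(sample_rate = recording$sample_rate,
                 channels = as.list(recording$channels)),
            recording$meta)
  yaml::write_yaml(meta, paste0(file, ".meta.yaml"))
  invisible(file)
}

#' @rdname write_recording_csv
#' @return For the reader, the `emg_recording`.
#' @export
read_recording_csv <- function(file) {
  df <- utils::read.csv(file, check.names = FALSE, fileEncoding = "UTF-8")
  meta_file <- paste0(file, ".meta.yaml")
  meta <- if (file.exists(meta_file)) yaml::read_yaml(meta_file) else list()
  channels <- unlist(meta$channels) %||%
    setdiff(names(df), c("time", "label"))
  sample_rate <- meta$sample_rate %||%
    round(1 / stats::median(diff(df$time)))
  extra <- meta[setdiff(names(meta), c("sample_rate", "channels"))]
  new_emg_recording(
    as.matrix(df[, channels, drop = FALSE]), sample_rate, channels,
    as.integer(df$label), extra
  )
}

#' Write / read a trajectory record as CSV
#'
#' Columns: `t`, `x`, `y`, `speed`, `Fvx`, `Fvy`, `Fmx`, `Fmy`, `intent`.
#'
#' @param traj A `trajectory_record` tibble.
#' @param file CSV path.
#' @return `file` (writer) / the `trajectory_record` tibble (reader).
#' @export
write_trajectory_csv <- function(traj, file) {
  utils::write.csv(as.data.frame(traj), file, row.names = FALSE,
                   fileEncoding = "UTF-8")
  invisible(file)
}

#' @rdname write_trajectory_csv
#' @export
read_trajectory_csv <- function(file) {
  out <- tibble::as_tibble(utils::read.csv(file, fileEncoding = "UTF-8"))
  out$intent <- as.integer(out$intent)
  class(out) <- c("trajectory_record", class(out))
  out
}

#' Save / load a trained model checkpoint
#'
#' A checkpoint is a directory holding the weights as flat CSV (one row per
#' parameter value, with its parameter name), the configuration as YAML and
#' the training history as CSV -- all plain text.
#'
#' @param model A trained `intent_model`.
#' @param dir Checkpoint directory (created if needed).
#' @return `dir` (writer) / the restored `intent_model` (loader).
#' @export
save_model <- function(model, dir) {
  stopifnot(inherits(model, "intent_model"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- do.call(rbind, lapply(names(model$params), function(nm) {
    data.frame(param = nm, index = seq_along(model$params[[nm]]),
               value = as.vector(model$params[[nm]]))
  }))
  utils::write.csv(w, file.path(dir, "weights.csv"), row.names = FALSE)
  shapes <- lapply(model$params, function(p) as.list(if (is.matrix(p)) dim(p) else length(p)))
  cfg <- unclass(model$config)
  yaml::write_yaml(
    list(config = cfg, input_shape = as.list(model$input_shape),
         shapes = shapes, trained = model$trained),
    file.path(dir, "config.yaml")
  )
  if (!is.null(model$history)) {
    utils::write.csv(as.data.frame(model$history),
                     file.path(dir, "history.csv"), row.names = FALSE)
  }
  invisible(dir)
}

#' @rdname save_model
#' @export
load_model <- function(dir) {
  meta <- yaml::read_yaml(file.path(dir, "config.yaml"))
  cfg <- do.call(classifier_config, meta$config)
  model <- build_model(cfg, unlist(meta$input_shape))
  w <- utils::read.csv(file.path(dir, "weights.csv"))
  for (nm in names(model$params)) {
    vals <- w$value[w$param == nm]
    shape <- unlist(meta$shapes[[nm]])
    model$params[[nm]] <- if (length(shape) == 2) {
      matrix(vals, shape[1], shape[2])
    } else {
      vals
    }
  }
  hist_file <- file.path(dir, "history.csv")
  if (file.exists(hist_file)) {
    model$history <- tibble::as_tibble(utils::read.csv(hist_file))
  }
  model$trained <- isTRUE(meta$trained)
  model
}

#' Write a metrics report as JSON or a CSV row
#'
#' @param report A `metrics_report` tibble.
#' @param file Output path; `.json` or `.csv` by extension.
#' @return `file`, invisibly.
#' @export
write_metrics <- function(report, file) {
  if (grepl("\\.json$", file)) {
    jsonlite::write_json(as.list(as.data.frame(report)[1, ]), file,
                         auto_unbox = TRUE, digits = NA)
  } else {
    utils::write.csv(as.data.frame(report), file, row.names = FALSE)
  }
  invisible(file)
}
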