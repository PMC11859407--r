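#' Filter specification for the sEMG conditioning chain
#'
#' The chain is: 4th-order Butterworth band-pass (20--450 Hz), 50 Hz band-stop
#' notch, full-wave rectification, low-pass linear envelope.  All filters are
#' applied zero-phase (forward-backward) by default; a causal variant is used
#' for the simulated real-time loop.
#'
#' @param low,high Band-pass corner frequencies in Hz (`0 < low < high`).
#' @param order Band-pass Butterworth order.
#' @param notch_hz Notch center frequency in Hz.
#' @param notch_q Notch quality factor (bandwidth = `notch_hz / notch_q`).
#' @param envelope_hz Envelope low-pass cutoff in Hz.
#' @param envelope_order Envelope Butterworth order.
#' @return A list of class `filter_spec`.
#' @export
filter_spec <- function(low = 20, high = 450, order = 4, notch_hz = 50,
                        notch_q = 30, envelope_hz = 10, envelope_order = 2) {
  stopifnot(low > 0, high > low, order >= 1, notch_hz > 0, notch_q > 0,
            envelope_hz > 0, envelope_order >= 1)
  structure(
    list(low = low, high = high, order = order, notch_hz = notch_hz,
         notch_q = notch_q, envelope_hz = envelope_hz,
         envelope_order = envelope_order),
    class = "filter_spec"
  )
}

apply_filter <- function(flt, x, zero_phase = TRUE) {
  if (zero_phase) signal::filtfilt(flt, x) else
    as.numeric(signal::filter(flt, x))
}

#' Band-pass and notch filtering of a recording
#'
#' Applies the Butterworth band-pass (default 4th order, 20--450 Hz) followed
#' by a band-stop notch at the power-line frequency, per channel.  Labels and
#' metadata are preserved.
#'
#' @param recording An `emg_recording`.
#' @param spec A [filter_spec()].
#' @param zero_phase Use zero-phase (forward-backward) filtering.
#' @return The filtered `emg_recording`.
#' @export
bandpass_notch <- function(recording, spec = filter_spec(), zero_phase = TRUE) {
  stopifnot(inherits(recording, "emg_recording"), inherits(spec, "filter_spec"))
  fs <- recording$sample_rate
  nyq <- fs / 2
  if (spec$high >= nyq) {
    rlang::abort(sprintf(
      "Band-pass high cutoff (%g Hz) must be below the Nyquist frequency (%g Hz).",
      spec$high, nyq
    ))
  }
  bp <- signal::butter(spec$order, c(spec$low, spec$high) / nyq, type = "pass")
  bw <- spec$notch_hz / spec$notch_q
  notch <- signal::butter(2, c(spec$notch_hz - bw / 2, spec$notch_hz + bw / 2) / nyq,
                          type = "stop")
  out <- recording
  out$samples <- apply(recording$samples, 2, function(x) {
    apply_filter(notch, apply_filter(bp, x, zero_phase), zero_phase)
  })
  colnames(out$samples) <- recording$channels
  out
}

envelope_channel <- function(rectified, sample_rate, spec, zero_phase = TRUE) {
  lp <- signal::butter(spec$envelope_order, spec$envelope_hz / (sample_rate / 2),
                       type = "low")
  apply_filter(lp, rectified, zero_phase)
}

#' Rectification and linear-envelope extraction
#'
#' Full-wave rectifies each channel and then low-pass filters it (default
#' 2nd-order zero-phase Butterworth at 10 Hz) to obtain the linear envelope.
#' The output is clamped at zero: zero-phase low-pass filtering of a
#' non-negative signal can undershoot slightly.
#'
#' @inheritParams bandpass_notch
#' @return The `emg_recording` holding the non-negative envelope.
#' @export
rectify_envelope <- function(recording, spec = filter_spec(), zero_phase = TRUE) {
  stopifnot(inherits(recording, "emg_recording"), inherits(spec, "filter_spec"))
  out <- recording
  out$samples <- apply(recording$samples, 2, function(x) {
    pmax(envelope_channel(abs(x), recording$sample_rate, spec, zero_phase), 0)
  })
  colnames(out$samples) <- recording$channels
  out
}

#' MVC normalization
#'
#' Divides each channel by its maximum-voluntary-contraction reference so the
#' amplitudes become dimensionless fractions of MVC, comparable across
#' individuals.
#'
#' @param recording An `emg_recording`.
#' @param mvc An [mvc_reference()] tibble (columns `muscle`, `mvc`) or a named
#'   numeric vector with one positive entry per channel.
#' @return The normalized `emg_recording`.
#' @export
normalize_mvc <- function(recording, mvc) {
  stopifnot(inherits(recording, "emg_recording"))
  if (inherits(mvc, "data.frame")) {
    ref <- stats::setNames(mvc$mvc, mvc$muscle)
  } else {
    ref <- mvc
  }
  missing <- setdiff(recording$channels, names(ref))
  if (length(missing)) {
    rlang::abort(paste0("MVC reference missing for channel(s): ",
                        paste(missing, collapse = ", ")))
  }
  ref <- ref[recording$channels]
  if (any(!is.finite(ref)) || any(ref <= 0)) {
    rlang::abort("All MVC reference entries must be positive and finite.")
  }
  out <- recording
  out$samples <- sweep(recording$samples, 2, ref, "/")
  out
}

#' Segment a recording into fixed-length labeled windows
#'
#' Cuts each channel into `window`-sample segments (default 450) advanced by
#' `stride`.  Windows that straddle a label transition carry ambiguous
#' supervision and are discarded; every returned window has exactly one intent
#' label.  Subject and group ids from the recording metadata are propagated.
#'
#' @param recording An `emg_recording`.
#' @param window Window length in samples.
#' @param stride Hop between window starts in samples (default `window`,
#'   i.e. non-overlapping).
#' @return A tibble of class `labeled_windows` with columns `window_id`,
#'   `label`, `subject`, `group`, `start` (first sample index) and the
#'   list-column `samples` (window x channel matrices).
#' @export
segment_windows <- function(recording, window = 450, stride = window) {
  stopifnot(inherits(recording, "emg_recording"), stride >= 1, window >= 1)
  n <- nrow(recording$samples)
  if (window > n) {
    rlang::warn("Window length exceeds recording length; returning no windows.")
    starts <- integer(0)
  } else {
    starts <- seq(1, n - window + 1, by = stride)
  }
  keep <- vapply(starts, function(s) {
    lab <- recording$labels[s:(s + window - 1)]
    lab[1] == lab[window] && all(lab == lab[1])
  }, logical(1))
  starts <- starts[keep]
  subject <- recording$meta$subject %||% NA_integer_
  group <- recording$meta$group %||% NA_integer_
  out <- tibble::tibble(
    window_id = seq_along(starts),
    label = vapply(starts, function(s) recording$labels[s], integer(1)),
    subject = subject, group = group, start = starts,
    samples = lapply(starts, function(s) {
      recording$samples[s:(s + window - 1), , drop = FALSE]
    })
  )
  class(out) <- c("labeled_windows", class(out))
  out
}

#' Full conditioning chain for one recording
#'
#' Convenience wrapper reproducing the standard stage order raw ->
#' band-passed/notched -> (optional rectified envelope) -> MVC-normalized ->
#' windows.
#'
#' @inheritParams segment_windows
#' @param mvc MVC reference passed to [normalize_mvc()], or `NULL` to skip.
#' @param spec A [filter_spec()].
#' @param input_repr `"raw"` feeds the band-passed, notch-filtered signal to
#'   the windows; `"envelope"` feeds the rectified linear envelope.
#' @return A `labeled_windows` tibble.
#' @export
preprocess_recording <- function(recording, mvc = NULL, spec = filter_spec(),
                                 input_repr = c("raw", "envelope"),
                                 window = 450, stride = window) {
  input_repr <- match.arg(input_repr)
  rec <- bandpass_notch(recording, spec)
  if (input_repr == "envelope") rec <- rectify_envelope(rec, spec)
  if (!is.null(mvc)) rec <- normalize_mvc(rec, mvc)
  segment_windows(rec, window = window, stride = stride)
}

#' Preprocess every recording of a dataset into one window table
#'
#' @param dataset A `semg_dataset` from [generate_dataset()].
#' @inheritParams preprocess_recording
#' @param normalize Use the dataset's per-subject MVC references.
#' @return A `labeled_windows` tibble pooled over recordings.
#' @export
preprocess_dataset <- function(dataset, spec = filter_spec(),
                               input_repr = c("raw", "envelope"),
                               window = 450, stride = window,
                               normalize = TRUE) {
  stopifnot(inherits(dataset, "semg_dataset"))
  input_repr <- match.arg(input_repr)
  out <- purrr::map_dfr(seq_len(nrow(dataset$recordings)), function(i) {
    rec <- dataset$recordings$recording[[i]]
    mvc <- NULL
    if (normalize) {
      mvc <- dplyr::filter(dataset$mvc, .data$subject == rec$meta$subject)
    }
    w <- preprocess_recording(rec, mvc = mvc, spec = spec,
                              input_repr = input_repr,
                              window = window, stride = stride)
    w$recording_id <- i
    w
  })
  class(out) <- c("labeled_windows", class(out))
  out
}

#' Balance a window table across intent classes
#'
#' The acquisition protocol has nine rest phases but only one phase per
#' directional class, so rest windows outnumber each active class roughly
#' 9:1.  This helper subsamples every class (in practice: rest) down to the
#' median count of the active classes, within each group so group-wise
#' cross-validation stays balanced.
#'
#' @param windows A `labeled_windows` tibble.
#' @param seed Integer seed for the subsampling.
#' @return The balanced `labeled_windows` tibble.
#' @export
balance_windows <- function(windows, seed = 1L) {
  check_windows(windows)
  active <- dplyr::count(windows[windows$label != 0, ], .data$group, .data$label)
  target <- stats::median(active$n)
  out <- withr::with_seed(seed, {
    windows |>
      dplyr::group_by(.data$group, .data$label) |>
      dplyr::slice_sample(n = target) |>
      dplyr::ungroup()
  })
  class(out) <- c("labeled_windows", class(out))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
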