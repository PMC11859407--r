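#' @importFrom stats rnorm runif sd
NULL

# The eleven shoulder/elbow muscles instrumented in the acquisition setup the
# generator emulates.
MUSCLES <- c(
  "latissimus_dorsi", "supraspinatus", "infraspinatus", "triceps_brachii",
  "biceps_brachii", "anterior_deltoid", "posterior_deltoid",
  "pectoralis_major", "brachialis", "brachioradialis", "middle_deltoid"
)

#' Isometric-contraction protocol timeline
#'
#' Builds the timeline of one acquisition sequence: alternating 5-s rest and
#' 5-s directional contraction phases, starting and ending with rest, with the
#' eight directional codes each appearing exactly once (17 phases, 85 s total
#' at the defaults).
#'
#' @param force_level Target contraction force in newtons (> 0).
#' @param phase_duration Duration of each phase in seconds.
#' @param sample_rate Sampling rate in Hz.
#' @param order `"sequential"` runs codes 1..8 in order; `"random"` shuffles
#'   them (seeded).
#' @param seed Integer seed (used only when `order = "random"`).
#' @return An object of class `semg_protocol`: a list with `phases` (tibble of
#'   `code`, `start`, `end` in seconds), `labels` (per-sample intent codes),
#'   `sample_rate`, `phase_duration` and `force_level`.
#' @examples
#' p <- semg_protocol(force_level = 15)
#' nrow(p$phases)     # 17
#' length(p$labels)   # 170000
#' @export
semg_protocol <- function(force_level, phase_duration = 5, sample_rate = 2000,
                          order = c("sequential", "random"), seed = 1L) {
  order <- match.arg(order)
  if (!is.numeric(force_level) || length(force_level) != 1 || force_level <= 0) {
    rlang::abort("`force_level` must be a single positive force in newtons.")
  }
  stopifnot(phase_duration > 0, sample_rate > 0)
  active <- 1:8
  if (order == "random") {
    active <- withr::with_seed(seed, sample(active))
  }
  codes <- integer(17)
  codes[seq(2, 16, by = 2)] <- active            # 8 active phases
  codes[seq(1, 17, by = 2)] <- 0L                # 9 rest phases
  n_per_phase <- as.integer(round(phase_duration * sample_rate))
  labels <- rep(as.integer(codes), each = n_per_phase)
  phases <- tibble::tibble(
    code = as.integer(codes),
    start = (seq_along(codes) - 1) * phase_duration,
    end = seq_along(codes) * phase_duration
  )
  structure(
    list(
      phases = phases, labels = labels, sample_rate = sample_rate,
      phase_duration = phase_duration, force_level = force_level
    ),
    class = "semg_protocol"
  )
}

#' @export
print.semg_protocol <- function(x, ...) {
  cat(sprintf(
    "<semg_protocol> %d phases x %g s = %g s at %g Hz, force %g N\n",
    nrow(x$phases), x$phase_duration,
    nrow(x$phases) * x$phase_duration, x$sample_rate, x$force_level
  ))
  invisible(x)
}

#' Directional tuning of the recorded muscles
#'
#' Each channel is modelled as a cosine-tuned force generator: its activation
#' drive during a directional phase is `max(0, d . p) * gain * (F / 25)^exponent`
#' where `d` is the phase direction, `p` the muscle's preferred direction and
#' `F` the protocol force level (25 N is the maximum resistance of the
#' acquisition rig).  Activation follows the drive through a first-order lag
#' with separate rise and fall time constants.
#'
#' Default preferred directions spread the eleven muscles evenly around the
#' circle with a small offset so no muscle is exactly aligned with an intent
#' direction.
#'
#' @param muscles Character vector of channel names.
#' @param preferred_angle Preferred direction per muscle, radians.
#' @param gain Dimensionless gain per muscle (>= 0); sets the full-activation
#'   carrier amplitude in mV.
#' @param tau_rise,tau_fall Activation/deactivation time constants in seconds.
#' @param force_exponent Exponent of the force scaling (1 = linear).
#' @return A tibble of class `muscle_tuning` with one row per channel.
#' @export
muscle_tuning <- function(muscles = MUSCLES,
                          preferred_angle = (pi / 2) - (seq_along(muscles) - 1) *
                            2 * pi / length(muscles) - 0.2,
                          gain = rep(1, length(muscles)),
                          tau_rise = 0.03, tau_fall = 0.06,
                          force_exponent = 1) {
  stopifnot(
    length(preferred_angle) == length(muscles),
    length(gain) == length(muscles), all(gain >= 0),
    tau_rise > 0, tau_fall > 0
  )
  out <- tibble::tibble(
    muscle = muscles,
    preferred_angle = preferred_angle,
    px = cos(preferred_angle), py = sin(preferred_angle),
    gain = gain,
    tau_rise = tau_rise, tau_fall = tau_fall,
    force_exponent = force_exponent
  )
  class(out) <- c("muscle_tuning", class(out))
  out
}

#' Artifact/noise specification for the generator
#'
#' Controls the three artifact sources injected on top of the activation-
#' modulated carrier: broadband sensor noise, 50 Hz power-line interference
#' and low-frequency baseline wander.
#'
#' @param broadband_sd Standard deviation of additive white noise (mV).
#' @param line_amplitude Amplitude of the 50 Hz sinusoidal interference (mV).
#' @param wander_amplitude RMS amplitude of the baseline wander (mV).
#' @param wander_cutoff Low-pass cutoff shaping the wander (Hz).
#' @return A list of class `noise_spec`.
#' @export
noise_spec <- function(broadband_sd = 0.02, line_amplitude = 0.05,
                       wander_amplitude = 0.02, wander_cutoff = 1) {
  stopifnot(
    broadband_sd >= 0, line_amplitude >= 0,
    wander_amplitude >= 0, wander_cutoff > 0
  )
  structure(
    list(
      broadband_sd = broadband_sd, line_amplitude = line_amplitude,
      wander_amplitude = wander_amplitude, wander_cutoff = wander_cutoff
    ),
    class = "noise_spec"
  )
}

# Exact first-order lag response to a piecewise-constant drive.  Within each
# phase the target is constant so a(t) relaxes exponentially toward it with
# the rise constant when activating and the fall constant when deactivating.
activation_lag <- function(targets_per_phase, n_per_phase, dt, tau_rise, tau_fall) {
  a0 <- 0
  out <- vector("list", length(targets_per_phase))
  tt <- seq_len(n_per_phase) * dt
  for (i in seq_along(targets_per_phase)) {
    target <- targets_per_phase[i]
    tau <- if (target > a0) tau_rise else tau_fall
    seg <- target + (a0 - target) * exp(-tt / tau)
    out[[i]] <- seg
    a0 <- seg[n_per_phase]
  }
  unlist(out, use.names = FALSE)
}

# Band-limited (20-450 Hz) unit-variance carrier noise.
emg_carrier <- function(n, sample_rate, band = c(20, 450)) {
  x <- rnorm(n)
  bf <- signal::butter(4, band / (sample_rate / 2), type = "pass")
  y <- signal::filtfilt(bf, x)
  y / sd(y)
}

#' Synthesize one labeled sEMG recording
#'
#' Produces a time x channel matrix of synthetic sEMG for a protocol timeline:
#' per channel, a first-order-lagged directional activation drive amplitude-
#' modulates a band-limited (20--450 Hz) zero-mean carrier, then line
#' interference, baseline wander and broadband noise are added.  Identical
#' seeds give bit-identical output.
#'
#' @param protocol A [semg_protocol()].
#' @param tuning A [muscle_tuning()] with one row per channel.
#' @param noise A [noise_spec()].
#' @param seed Integer seed.
#' @param meta Optional named list of metadata (subject, group, set, ...).
#' @return An object of class `emg_recording`: list with `samples` (numeric
#'   matrix, mV), `sample_rate`, `channels`, `labels` and `meta`.
#' @examples
#' rec <- synthesize_recording(semg_protocol(15, phase_duration = 0.25),
#'                             muscle_tuning(), noise_spec(), seed = 7)
#' dim(rec$samples)
#' @export
synthesize_recording <- function(protocol, tuning = muscle_tuning(),
                                 noise = noise_spec(), seed = 1L,
                                 meta = list()) {
  stopifnot(inherits(protocol, "semg_protocol"), inherits(tuning, "muscle_tuning"),
            inherits(noise, "noise_spec"))
  fs <- protocol$sample_rate
  n_per_phase <- as.integer(round(protocol$phase_duration * fs))
  n <- length(protocol$labels)
  n_ch <- nrow(tuning)
  dirs <- intent_directions()

  samples <- withr::with_seed(seed, {
    m <- matrix(0, nrow = n, ncol = n_ch, dimnames = list(NULL, tuning$muscle))
    t_sec <- (seq_len(n) - 1) / fs
    force_frac <- protocol$force_level / 25
    for (ch in seq_len(n_ch)) {
      tu <- tuning[ch, ]
      # drive per phase: half-rectified cosine tuning scaled by force fraction
      phase_codes <- protocol$phases$code
      drive <- vapply(phase_codes, function(code) {
        if (code == 0) return(0)
        d <- dirs[dirs$code == code, ]
        max(0, d$dx * tu$px + d$dy * tu$py) * tu$gain *
          force_frac^tu$force_exponent
      }, numeric(1))
      act <- activation_lag(drive, n_per_phase, 1 / fs, tu$tau_rise, tu$tau_fall)
      sig <- if (tu$gain > 0) act * emg_carrier(n, fs) else {
        # keep the RNG stream aligned across gain settings
        emg_carrier(n, fs)
        numeric(n)
      }
      if (noise$line_amplitude > 0) {
        sig <- sig + noise$line_amplitude * sin(2 * pi * 50 * t_sec + runif(1, 0, 2 * pi))
      } else {
        runif(1)
      }
      if (noise$wander_amplitude > 0) {
        wf <- signal::butter(2, noise$wander_cutoff / (fs / 2), type = "low")
        w <- signal::filtfilt(wf, rnorm(n))
        sig <- sig + noise$wander_amplitude * w / sd(w)
      } else {
        rnorm(n)
      }
      if (noise$broadband_sd > 0) {
        sig <- sig + noise$broadband_sd * rnorm(n)
      } else {
        rnorm(n)
      }
      m[, ch] <- sig
    }
    m
  })

  new_emg_recording(samples, fs, tuning$muscle, protocol$labels,
                    c(meta, list(force_level = protocol$force_level, seed = seed)))
}

new_emg_recording <- function(samples, sample_rate, channels, labels, meta = list()) {
  stopifnot(
    is.matrix(samples), nrow(samples) == length(labels),
    ncol(samples) == length(channels), all(is.finite(samples)),
    all(labels %in% 0:8)
  )
  structure(
    list(
      samples = samples, sample_rate = sample_rate,
      channels = channels, labels = as.integer(labels), meta = meta
    ),
    class = "emg_recording"
  )
}

#' @export
print.emg_recording <- function(x, ...) {
  cat(sprintf(
    "<emg_recording> %d samples x %d channels at %g Hz (%.1f s)\n",
    nrow(x$samples), ncol(x$samples), x$sample_rate,
    nrow(x$samples) / x$sample_rate
  ))
  if (length(x$meta)) {
    cat("  meta:", paste(names(x$meta), unlist(lapply(x$meta, format)),
                         sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Per-channel MVC reference from maximal synthetic trials
#'
#' Emulates the maximum-voluntary-contraction calibration: for each channel a
#' maximal trial (full gain, preferred direction, maximal force) is held for
#' `hold` seconds and repeated `repetitions` times; the reference is the peak
#' of the rectified-and-enveloped signal across repetitions.
#'
#' @param tuning A [muscle_tuning()].
#' @param noise A [noise_spec()] (defaults to noise-free calibration).
#' @param hold Hold duration per repetition in seconds (protocol: 3 to 5 s).
#' @param repetitions Number of repetitions per muscle.
#' @param sample_rate Sampling rate in Hz.
#' @param seed Integer seed.
#' @return A tibble of class `mvc_reference` with columns `muscle` and `mvc`
#'   (mV, all > 0).
#' @export
mvc_reference <- function(tuning = muscle_tuning(), noise = noise_spec(0, 0, 0),
                          hold = 4, repetitions = 5, sample_rate = 2000,
                          seed = 1L) {
  stopifnot(inherits(tuning, "muscle_tuning"), hold >= 3, hold <= 5,
            repetitions >= 1)
  if (any(tuning$gain <= 0)) {
    rlang::abort("MVC calibration requires strictly positive gains on all channels.")
  }
  n <- as.integer(hold * sample_rate)
  spec <- filter_spec()
  mvc <- withr::with_seed(seed, {
    vapply(seq_len(nrow(tuning)), function(ch) {
      tu <- tuning[ch, ]
      peak <- 0
      for (r in seq_len(repetitions)) {
        act <- tu$gain * (1 - exp(-(seq_len(n) / sample_rate) / tu$tau_rise))
        sig <- act * emg_carrier(n, sample_rate)
        if (noise$broadband_sd > 0) sig <- sig + noise$broadband_sd * rnorm(n)
        env <- envelope_channel(abs(sig), sample_rate, spec)
        peak <- max(peak, env)
      }
      peak
    }, numeric(1))
  })
  out <- tibble::tibble(muscle = tuning$muscle, mvc = mvc)
  class(out) <- c("mvc_reference", class(out))
  out
}

#' Generate a multi-subject, multi-session synthetic dataset
#'
#' Emulates the acquisition campaign: each subject contributes
#' `n_groups x sets_per_group x length(force_levels)` recordings, with the
#' group id standing in for the experiment date so group-wise cross-validation
#' is well defined.  Subjects get individually jittered muscle tuning and each
#' group a mild session-to-session gain drift.
#'
#' @param n_subjects,n_groups,sets_per_group Positive counts.
#' @param force_levels Numeric vector of force levels in newtons (non-empty).
#' @param seed Integer seed; all per-recording seeds derive from it.
#' @param tuning Base [muscle_tuning()] shared by subjects before jitter.
#' @param noise A [noise_spec()].
#' @param phase_duration Phase duration in seconds (5 s is the standard
#'   protocol; shorter values give small fixtures).
#' @param sample_rate Sampling rate in Hz.
#' @param subject_jitter_sd Angular jitter (radians) of per-subject preferred
#'   directions.
#' @param group_gain_sd Log-normal sd of per-group gain drift.
#' @param order Contraction order passed to [semg_protocol()].
#' @return A list of class `semg_dataset`: `recordings` (tibble with columns
#'   `subject`, `group`, `set`, `force_level`, `seed` and list-column
#'   `recording`) and `mvc` (tibble `subject`, `muscle`, `mvc`).
#' @export
generate_dataset <- function(n_subjects = 7, n_groups = 7, sets_per_group = 3,
                             force_levels = c(5, 10, 15, 20, 25), seed = 1L,
                             tuning = muscle_tuning(), noise = noise_spec(),
                             phase_duration = 5, sample_rate = 2000,
                             subject_jitter_sd = 0.05, group_gain_sd = 0.03,
                             order = "sequential") {
  stopifnot(n_subjects >= 1, n_groups >= 1, sets_per_group >= 1)
  if (length(force_levels) == 0) {
    rlang::abort("`force_levels` must contain at least one force level.")
  }
  grid <- tidyr::expand_grid(
    subject = seq_len(n_subjects), group = seq_len(n_groups),
    set = seq_len(sets_per_group), force_level = force_levels
  )
  seeds <- withr::with_seed(seed, {
    list(
      recording = sample.int(.Machine$integer.max - 1, nrow(grid)),
      subject_angle = matrix(rnorm(n_subjects * nrow(tuning), 0, subject_jitter_sd),
                             nrow = n_subjects),
      group_gain = matrix(exp(rnorm(n_subjects * n_groups, 0, group_gain_sd)),
                          nrow = n_subjects),
      mvc = sample.int(.Machine$integer.max - 1, n_subjects)
    )
  })

  subject_tuning <- lapply(seq_len(n_subjects), function(s) {
    tu <- tuning
    ang <- tu$preferred_angle + seeds$subject_angle[s, ]
    muscle_tuning(
      muscles = tu$muscle, preferred_angle = ang, gain = tu$gain,
      tau_rise = tu$tau_rise[1], tau_fall = tu$tau_fall[1],
      force_exponent = tu$force_exponent[1]
    )
  })

  recs <- purrr::pmap(
    list(grid$subject, grid$group, grid$set, grid$force_level,
         seq_len(nrow(grid))),
    function(s, g, st, f, i) {
      tu <- subject_tuning[[s]]
      tu$gain <- tu$gain * seeds$group_gain[s, g]
      proto <- semg_protocol(f, phase_duration = phase_duration,
                             sample_rate = sample_rate, order = order,
                             seed = seeds$recording[i])
      synthesize_recording(
        proto, tu, noise, seed = seeds$recording[i],
        meta = list(subject = s, group = g, set = st)
      )
    }
  )

  mvc <- purrr::map_dfr(seq_len(n_subjects), function(s) {
    m <- mvc_reference(subject_tuning[[s]], noise = noise_spec(0, 0, 0),
                       sample_rate = sample_rate, seed = seeds$mvc[s])
    dplyr::mutate(tibble::as_tibble(m), subject = s, .before = 1)
  })

  recordings <- dplyr::mutate(grid, seed = seeds$recording,
                              recording = recs)
  structure(list(recordings = recordings, mvc = mvc), class = "semg_dataset")
}

#' @export
print.semg_dataset <- function(x, ...) {
  cat(sprintf(
    "<semg_dataset> %d recordings, %d subject(s), %d group(s)\n",
    nrow(x$recordings), dplyr::n_distinct(x$recordings$subject),
    dplyr::n_distinct(x$recordings$group)
  ))
  invisible(x)
}
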