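# Small fixtures built in code; everything is seeded.

# Short-protocol recording for fast tests (0.25 s phases -> 4.25 s, 8500
# samples at 2000 Hz).
tiny_recording <- function(force = 15, seed = 7, noise = noise_spec(),
                           phase_duration = 0.25, tuning = muscle_tuning(),
                           meta = list(subject = 1L, group = 1L)) {
  synthesize_recording(
    semg_protocol(force, phase_duration = phase_duration),
    tuning, noise, seed = seed, meta = meta
  )
}

# A recording holding one pure sinusoid on a single channel.
sine_recording <- function(freq, amp = 1, duration = 4, sample_rate = 2000) {
  t <- seq(0, duration - 1 / sample_rate, by = 1 / sample_rate)
  samples <- matrix(amp * sin(2 * pi * freq * t), ncol = 1,
                    dimnames = list(NULL, "ch1"))
  myointent:::new_emg_recording(samples, sample_rate, "ch1",
                                rep(0L, length(t)))
}

rms <- function(x) sqrt(mean(x^2))

# Middle section of a signal, away from filter edge transients.
mid <- function(x, frac = 0.25) {
  n <- length(x)
  x[floor(n * frac):ceiling(n * (1 - frac))]
}

# Toy linearly separable windows: class codes `codes`, channel means encode
# the class.  Returns a labeled_windows tibble with window length L.
toy_windows <- function(n_per_class = 30, codes = c(0L, 3L), L = 64, C = 2,
                        noise_sd = 0.05, groups = 1L, seed = 1) {
  withr::with_seed(seed, {
    rows <- list()
    id <- 0L
    for (g in groups) {
      for (code in codes) {
        for (i in seq_len(n_per_class)) {
          id <- id + 1L
          m <- matrix(rnorm(L * C, 0, noise_sd), L, C)
          # class signature: which channel carries the offset and how large
          idx <- match(code, codes)
          ch <- 1 + (idx - 1) %% C
          m[, ch] <- m[, ch] + 1 + (idx - 1) %/% C
          rows[[id]] <- tibble::tibble(
            window_id = id, label = code, subject = 1L, group = g,
            start = 1L, samples = list(m)
          )
        }
      }
    }
    out <- dplyr::bind_rows(rows)
    class(out) <- c("labeled_windows", class(out))
    out
  })
}

# Central finite-difference Jacobian of forward kinematics (independent
# oracle for the geometric Jacobian).
fd_jacobian <- function(model, q, h = 1e-6) {
  J <- matrix(0, 6, 6)
  R0 <- forward_kinematics(model, q)$rotation
  for (i in 1:6) {
    qp <- q; qm <- q
    qp[i] <- q[i] + h; qm[i] <- q[i] - h
    fp <- forward_kinematics(model, qp)
    fm <- forward_kinematics(model, qm)
    J[1:3, i] <- (fp$position - fm$position) / (2 * h)
    S <- ((fp$rotation - fm$rotation) / (2 * h)) %*% t(R0)
    J[4:6, i] <- c(S[3, 2], S[1, 3], S[2, 1])
  }
  J
}

# Planar two-link arm (unit links, all z-axes vertical) embedded as the
# first two joints of a 6R chain; the remaining joints are degenerate.
planar_2r_model <- function() {
  arm_model(data.frame(
    a = c(1, 1, 0, 0, 0, 0), d = 0, alpha = 0, theta_offset = 0
  ))
}
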