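test_that("band-pass/notch chain attenuates out-of-band tones and passes the band", {
  spec <- filter_spec()
  in5 <- sine_recording(5)
  in50 <- sine_recording(50)
  in100 <- sine_recording(100)
  r5 <- rms(mid(bandpass_notch(in5, spec)$samples[, 1]))
  r50 <- rms(mid(bandpass_notch(in50, spec)$samples[, 1]))
  r100 <- rms(mid(bandpass_notch(in100, spec)$samples[, 1]))
  r_in <- rms(mid(in100$samples[, 1]))
  expect_lt(r5 / r_in, 0.10)
  expect_lt(r50 / r_in, 0.05)
  expect_lt(abs(r100 - r_in) / r_in, 0.20)
  # in decibels: stop-band attenuation at least 20 dB
  expect_gt(-20 * log10(r5 / r_in), 20)
  expect_gt(-20 * log10(r50 / r_in), 20)
})

test_that("cutoffs at or above Nyquist are rejected with a clear message", {
  rec <- sine_recording(100)
  expect_error(bandpass_notch(rec, filter_spec(high = 1000)), "Nyquist")
  expect_error(bandpass_notch(rec, filter_spec(high = 1200)), "Nyquist")
})

test_that("filtering is linear", {
  rec <- tiny_recording(seed = 13)
  rec3 <- rec
  rec3$samples <- 3 * rec$samples
  out1 <- bandpass_notch(rec)
  out3 <- bandpass_notch(rec3)
  expect_equal(out3$samples, 3 * out1$samples, tolerance = 1e-10)
})

test_that("labels and metadata survive the filter chain", {
  rec <- tiny_recording(seed = 3)
  out <- rectify_envelope(bandpass_notch(rec))
  expect_identical(out$labels, rec$labels)
  expect_identical(out$meta, rec$meta)
  expect_identical(colnames(out$samples), rec$channels)
})

test_that("rectified envelope is non-negative and tracks a burst plateau", {
  rec <- tiny_recording(seed = 3)
  env <- rectify_envelope(bandpass_notch(rec))
  expect_true(all(env$samples >= 0))

  # amplitude-modulated 100 Hz tone: envelope ~ mean of rectified sinusoid
  fs <- 2000
  t <- seq(0, 4 - 1 / fs, by = 1 / fs)
  A <- 0.8
  x <- A * sin(2 * pi * 100 * t)
  rec2 <- myointent:::new_emg_recording(
    matrix(x, ncol = 1, dimnames = list(NULL, "ch1")), fs, "ch1",
    rep(0L, length(t))
  )
  env2 <- rectify_envelope(rec2)$samples[, 1]
  plateau <- mean(mid(env2))
  expect_lt(abs(plateau - 2 * A / pi) / (2 * A / pi), 0.15)

  zero <- rec2
  zero$samples[] <- 0
  expect_true(all(rectify_envelope(zero)$samples == 0))
})

test_that("residual 50 Hz energy is down at least 20 dB after the chain", {
  withr::with_seed(21, {
    fs <- 2000
    t <- seq(0, 4 - 1 / fs, by = 1 / fs)
    x <- rnorm(length(t), 0, 0.05) + 1.0 * sin(2 * pi * 50 * t)
    rec <- myointent:::new_emg_recording(
      matrix(x, ncol = 1, dimnames = list(NULL, "ch1")), fs, "ch1",
      rep(0L, length(t))
    )
    out <- bandpass_notch(rec)$samples[, 1]
    p_in <- stats::spec.pgram(stats::ts(mid(x), frequency = fs), plot = FALSE)
    p_out <- stats::spec.pgram(stats::ts(mid(out), frequency = fs), plot = FALSE)
    band <- p_in$freq > 49 & p_in$freq < 51
    atten_db <- 10 * log10(sum(p_in$spec[band]) / sum(p_out$spec[band]))
    expect_gt(atten_db, 20)
  })
})

test_that("MVC normalization identities hold and invalid references fail", {
  rec <- tiny_recording(seed = 8)
  ref <- apply(abs(rec$samples), 2, max)
  mvc <- tibble::tibble(muscle = rec$channels, mvc = ref)
  norm <- normalize_mvc(rec, mvc)
  expect_lte(max(abs(norm$samples)), 1)
  # signal equal to its reference everywhere -> all ones
  ones <- rec
  ones$samples <- matrix(rep(ref, each = nrow(rec$samples)),
                         ncol = ncol(rec$samples),
                         dimnames = dimnames(rec$samples))
  expect_true(all(normalize_mvc(ones, mvc)$samples == 1))
  # halving: reference = 2x signal -> 0.5
  mvc2 <- tibble::tibble(muscle = rec$channels, mvc = 2 * ref)
  expect_equal(unname(normalize_mvc(ones, mvc2)$samples[1, 1]), 0.5)
  # round trip
  denorm <- norm
  denorm$samples <- sweep(norm$samples, 2, ref, "*")
  expect_equal(denorm$samples, rec$samples, tolerance = 1e-12)
  bad <- tibble::tibble(muscle = rec$channels, mvc = c(0, ref[-1]))
  expect_error(normalize_mvc(rec, bad), "positive")
  expect_error(normalize_mvc(rec, mvc[-1, ]), "missing")
})

test_that("windowing yields only single-label 450-row windows", {
  labels <- rep(c(0L, 3L), each = 5000)
  samples <- matrix(rnorm(10000 * 2), ncol = 2,
                    dimnames = list(NULL, c("a", "b")))
  rec <- myointent:::new_emg_recording(samples, 2000, c("a", "b"), labels,
                                       list(subject = 2L, group = 4L))
  w <- segment_windows(rec)
  expect_s3_class(w, "labeled_windows")
  expect_true(all(vapply(w$samples, nrow, integer(1)) == 450))
  expect_true(all(w$label %in% c(0L, 3L)))
  expect_true(all(w$subject == 2L))
  expect_true(all(w$group == 4L))
  # stride-450 starts: 11 fit the first 5000-sample block, one straddles the
  # transition (discarded), 10 fit the remainder of the second block
  expect_equal(nrow(w), 21)
  # per window: constant label
  for (i in seq_len(nrow(w))) {
    seg <- labels[w$start[i]:(w$start[i] + 449)]
    expect_equal(length(unique(seg)), 1)
  }
})

test_that("windowing respects the stride-450 tiling bound", {
  labels <- rep(5L, 170000)
  samples <- matrix(0, 170000, 1, dimnames = list(NULL, "a"))
  rec <- myointent:::new_emg_recording(samples, 2000, "a", labels)
  w <- segment_windows(rec)
  expect_equal(nrow(w), floor(170000 / 450))   # 377
  # non-overlapping tiles
  expect_equal(diff(w$start), rep(450L, nrow(w) - 1))

  rec900 <- myointent:::new_emg_recording(samples[1:900, , drop = FALSE],
                                          2000, "a", labels[1:900])
  expect_equal(nrow(segment_windows(rec900)), 2)
  expect_warning(w0 <- segment_windows(rec900, window = 1000), "length")
  expect_equal(nrow(w0), 0)
})

test_that("the dataset pipeline pools windows with ids and balance works", {
  ds <- generate_dataset(n_subjects = 1, n_groups = 2, sets_per_group = 1,
                         force_levels = 25, seed = 31, phase_duration = 0.5)
  w <- preprocess_dataset(ds, window = 200, stride = 200)
  expect_true(all(c("label", "subject", "group") %in% names(w)))
  expect_setequal(unique(w$group), 1:2)
  expect_true(all(vapply(w$samples, nrow, integer(1)) == 200))
  wb <- balance_windows(w, seed = 1)
  counts <- table(wb$group, wb$label)
  expect_true(max(counts) - min(counts) <= 1)
  expect_lte(nrow(wb), nrow(w))
})

test_that("envelope input representation is available end to end", {
  rec <- tiny_recording(seed = 17, phase_duration = 0.5)
  w <- preprocess_recording(rec, input_repr = "envelope", window = 200,
                            stride = 200)
  expect_true(all(vapply(w$samples, function(m) all(m >= 0), logical(1))))
})
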