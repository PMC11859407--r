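test_that("standard paths carry the expected lengths", {
  paths <- standard_paths()
  expect_equal(paths$circle$length, 2 * pi * 0.1)
  expect_equal(paths$co_ptp$length, 1.6)
  # the faster sine oscillates more, hence is longer
  expect_gt(paths$sine1$length, paths$sine2$length)
  # both sines span x in [-0.2, 0.2] with amplitude 0.1
  expect_equal(range(paths$sine1$waypoints[, 1]), c(-0.2, 0.2))
  expect_lte(max(abs(paths$sine1$waypoints[, 2])), 0.1 + 1e-12)
  # a path exceeding the workspace is rejected
  expect_error(path_spec("circle", radius = 0.2), "workspace")
})

test_that("point-to-path distance matches the dense-sampling oracle", {
  paths <- standard_paths()
  expect_equal(point_to_path_distance(c(0, 0), paths$circle), 0.1,
               tolerance = 1e-6)
  on_path <- paths$sine2$waypoints[537, ]
  expect_lt(point_to_path_distance(on_path, paths$sine2), 1e-9)

  withr::with_seed(3, {
    for (kind in names(paths)) {
      dense <- path_spec(kind, n = 100000)
      for (i in 1:5) {
        p <- c(runif(1, -0.3, 0.3), runif(1, -0.15, 0.15))
        d_fast <- point_to_path_distance(p, paths[[kind]])
        d_oracle <- min(sqrt((dense$waypoints[, 1] - p[1])^2 +
                               (dense$waypoints[, 2] - p[2])^2))
        expect_lt(abs(d_fast - d_oracle), 1e-4)
      }
    }
  })
})

test_that("smoothness closed forms hold", {
  # constant speed -> 1
  traj <- tibble::tibble(t = seq(0, 1, by = 0.1), x = seq(0, 1, by = 0.1),
                         y = 0)
  expect_equal(smoothness(traj)$lambda_s, 1)
  # logged speed sequence (1, 1, 2) -> mean/max = 2/3
  traj2 <- tibble::tibble(t = 0:2, x = c(0, 1, 3), y = 0, speed = c(1, 1, 2))
  expect_equal(smoothness(traj2, speed_source = "logged")$lambda_s, 2 / 3)
  # invariant under uniform speed rescaling
  traj3 <- traj2
  traj3$speed <- 5 * traj2$speed
  expect_equal(smoothness(traj3, speed_source = "logged")$lambda_s, 2 / 3)
  # all-zero speeds: undefined with a warning
  still <- tibble::tibble(t = 0:3, x = 0, y = 0)
  expect_warning(s0 <- smoothness(still), "undefined")
  expect_true(is.na(s0$lambda_s))
})

test_that("range deviation reproduces the printed worked case", {
  # unit-length straight standard path; samples at distances 0, 0.1, 0.2
  line <- polyline_path(cbind(c(0, 1), c(0, 0)))
  expect_equal(line$length, 1)
  traj <- tibble::tibble(t = 0:2, x = c(0.2, 0.5, 0.8), y = c(0, 0.1, 0.2))
  rd <- range_deviation(traj, line)
  expect_equal(rd$rx, 0.025)
  expect_equal(rd$lambda_d, 1 / 1.025, tolerance = 1e-9)

  # on-path trajectory: rx = 0, lambda_d = 1
  on <- tibble::tibble(t = 0:2, x = c(0.1, 0.5, 0.9), y = 0)
  expect_equal(range_deviation(on, line)$lambda_d, 1)

  # monotone: increasing any distance decreases lambda_d
  worse <- traj
  worse$y[3] <- 0.3
  expect_lt(range_deviation(worse, line)$lambda_d, rd$lambda_d)

  # rms variant uses the square root of the summed squares
  rd_rms <- range_deviation(traj, line, variant = "rms")
  expect_equal(rd_rms$rx, sqrt(0.05) / 2)
})

test_that("normalized path length is a homogeneous length ratio", {
  circle <- path_spec("circle")
  wp <- circle$waypoints[seq(1, nrow(circle$waypoints), by = 10), ]
  traj <- tibble::tibble(t = seq_len(nrow(wp)), x = wp[, 1], y = wp[, 2])
  expect_equal(normalized_path_length(traj, circle)$lambda_l, 1,
               tolerance = 1e-3)
  # chord across a half circle is shorter than the arc
  half <- polyline_path(circle$waypoints[1:5000, ],
                        length = pi * 0.1)
  chord <- tibble::tibble(t = 0:1,
                          x = c(circle$waypoints[1, 1], circle$waypoints[5000, 1]),
                          y = c(circle$waypoints[1, 2], circle$waypoints[5000, 2]))
  expect_lt(normalized_path_length(chord, half)$lambda_l, 1)
  # doubling every displacement doubles lambda_l
  traj2 <- tibble::tibble(t = traj$t, x = 2 * traj$x, y = 2 * traj$y)
  expect_equal(normalized_path_length(traj2, circle)$lambda_l,
               2 * normalized_path_length(traj, circle)$lambda_l,
               tolerance = 1e-9)
})

test_that("full evaluation composes the metrics and serializes", {
  circle <- path_spec("circle")
  wp <- circle$waypoints[seq(1, nrow(circle$waypoints), by = 10), ]
  traj <- tibble::tibble(t = seq_len(nrow(wp)) / 60, x = wp[, 1], y = wp[, 2])
  rep1 <- evaluate_trajectory(traj, circle)
  expect_equal(rep1$lambda_d, 1, tolerance = 1e-6)
  expect_equal(rep1$lambda_l, 1, tolerance = 1e-3)
  expect_gt(rep1$lambda_s, 0.99)
  # bit-reproducible
  expect_identical(as.data.frame(evaluate_trajectory(traj, circle)),
                   as.data.frame(rep1))
  # round trip through JSON and CSV
  jf <- withr::local_tempfile(fileext = ".json")
  cf <- withr::local_tempfile(fileext = ".csv")
  write_metrics(rep1, jf)
  write_metrics(rep1, cf)
  back <- jsonlite::read_json(jf)
  expect_equal(back$lambda_d, rep1$lambda_d, tolerance = 1e-12)
  csv <- utils::read.csv(cf)
  expect_equal(csv$lambda_l, rep1$lambda_l, tolerance = 1e-12)
})

test_that("metric ranges hold on randomized trajectories", {
  paths <- standard_paths()
  withr::with_seed(8, {
    for (i in 1:20) {
      n <- sample(5:60, 1)
      traj <- tibble::tibble(
        t = seq_len(n) / 60,
        x = runif(n, -0.3, 0.3), y = runif(n, -0.15, 0.15)
      )
      path <- paths[[sample(names(paths), 1)]]
      m <- evaluate_trajectory(traj, path)
      expect_gte(m$lambda_s, 0); expect_lte(m$lambda_s, 1)
      expect_gt(m$lambda_d, 0); expect_lte(m$lambda_d, 1)
      expect_gte(m$lambda_l, 0)
    }
  })
})

test_that("positional noise lowers the range-deviation score", {
  circle <- path_spec("circle")
  wp <- circle$waypoints[seq(1, nrow(circle$waypoints), by = 10), ]
  clean <- tibble::tibble(t = seq_len(nrow(wp)) / 60, x = wp[, 1], y = wp[, 2])
  noisy <- withr::with_seed(5, {
    dplyr::mutate(clean, x = .data$x + rnorm(dplyr::n(), 0, 0.02),
                  y = .data$y + rnorm(dplyr::n(), 0, 0.02))
  })
  expect_gt(evaluate_trajectory(clean, circle)$lambda_d,
            evaluate_trajectory(noisy, circle)$lambda_d)
})
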