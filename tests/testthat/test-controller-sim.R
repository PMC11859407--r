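test_that("virtual force follows the intent and mode", {
  cfg <- controller_config("isometric_mimic")
  pos <- c(0.05, -0.02)
  expect_equal(virtual_force(pos, 0, cfg)$force, c(0, 0))
  expect_null(virtual_force(pos, 0, cfg)$target)

  v3 <- virtual_force(pos, 3, cfg)
  expect_equal(v3$force, c(4, 0))
  expect_equal(v3$target, pos + c(0.030, 0))

  iso <- controller_config("isotonic_closed_loop")
  v3i <- virtual_force(pos, 3, iso)
  expect_equal(sqrt(sum(v3i$force^2)), 6.5)
  expect_equal(v3i$force / 6.5, c(1, 0))

  expect_error(virtual_force(pos, 9, cfg), "0..8")
  # target clamped at the workspace boundary
  edge <- virtual_force(c(0.29, 0), 3, cfg)
  expect_equal(edge$target[1], 0.30)
})

test_that("force smoothing is exact at the boundaries and linear between", {
  f_last <- c(4, 0); f_next <- c(0, 4)
  expect_equal(smooth_force(f_last, f_next, 0.4, 0), f_last)
  expect_equal(smooth_force(f_last, f_next, 0.4, 0.4), f_next)
  expect_equal(smooth_force(f_last, f_next, 0.4, 0.1), c(3, 1))
  # linear in t
  ts <- seq(0, 0.4, by = 0.05)
  fx <- vapply(ts, function(t) smooth_force(f_last, f_next, 0.4, t)[1],
               numeric(1))
  expect_equal(fx, 4 - 10 * ts)
  expect_error(smooth_force(f_last, f_next, 0, 0), "positive")
})

test_that("PD velocity law matches its difference equation", {
  cfg <- controller_config()
  pd <- pd_controller(cfg)
  e <- c(2, -1)
  # step error from rest: u = (Kp + Kd) e = 0.65 e
  expect_equal(pd(e), (0.15 + 0.5) * e)
  # constant error afterwards: derivative term vanishes
  expect_equal(pd(e), 0.15 * e)
  expect_equal(pd(e), 0.15 * e)
  pd0 <- pd_controller(cfg)
  expect_equal(pd0(c(0, 0)), c(0, 0))
  # Ki = 0 keeps the integrator inert over many ticks
  pd1 <- pd_controller(cfg)
  for (i in 1:50) u <- pd1(e)
  expect_equal(u, 0.15 * e)
})

test_that("simulated patient quantizes direction within 22.5 degrees", {
  # direct quantization bound of the 8-sector code book
  withr::with_seed(2, {
    for (i in 1:200) {
      th <- runif(1, -pi, pi)
      v <- c(cos(th), sin(th))
      code <- nearest_intent(v)
      d <- intent_direction(code)
      ang <- acos(pmin(1, sum(v * d)))
      expect_lte(ang, (22.5 + 1e-9) * pi / 180)
    }
  })
  expect_equal(nearest_intent(c(1, 0)), 3L)   # +x is "right"
  expect_equal(nearest_intent(c(0, 1)), 1L)
  expect_equal(nearest_intent(c(0, -1)), 5L)

  cfg <- controller_config("isotonic_closed_loop")
  path <- path_spec("co_ptp")
  pat <- simulated_patient(path, cfg)
  # first goal is target 1 at (0, 0.1): from the center the intent is 1
  out <- pat(c(0, 0))
  expect_equal(out$intent, 1L)
  expect_false(out$done)
  expect_gt(sum(out$hand_force^2), 0)
  # at the goal the patient rests for a tick
  out2 <- pat(path$targets[1, ])
  expect_equal(out2$intent, 0L)
  expect_equal(out2$hand_force, c(0, 0))
})

test_that("plant stepping integrates, stays put at rest and clamps", {
  m <- arm_model()
  q0 <- home_configuration()
  home <- forward_kinematics(m, q0)$position
  still <- step_plant(m, q0, c(0, 0), 1 / 60, home)
  expect_equal(still$q, q0)
  expect_equal(still$position, c(0, 0), tolerance = 1e-12)

  # constant +x velocity advances x by ~ k * v * dt
  v <- 0.05; dt <- 1 / 60; k <- 30
  q <- q0
  for (i in 1:k) {
    st <- step_plant(m, q, c(v, 0), dt, home)
    q <- st$q
  }
  expect_equal(st$position[1], k * v * dt, tolerance = 1e-3)
  expect_equal(st$position[2], 0, tolerance = 1e-3)

  # pushing past the +x bound saturates at the bound
  homeshift <- home
  homeshift[1] <- home[1] - 0.299   # start just inside the +x wall
  st2 <- step_plant(m, q0, c(0.5, 0), dt, homeshift)
  expect_equal(st2$position[1], 0.3)
})

test_that("sessions are deterministic, contained and responsive to intent", {
  cfg <- controller_config("isometric_mimic")
  # scripted rest: stationary
  t_rest <- simulate_session(rep(0L, 30), cfg, duration = 0.5, seed = 1)
  expect_true(all(t_rest$x == 0 & t_rest$y == 0))

  # constant +x intent: monotone x until the bound, never outside workspace
  t_x <- simulate_session(rep(3L, 600), cfg, duration = 10, seed = 1)
  expect_true(all(diff(t_x$x) >= -1e-12))
  expect_true(all(abs(t_x$x) <= 0.3 + 1e-9))
  expect_true(all(abs(t_x$y) <= 0.15 + 1e-9))
  expect_gt(max(t_x$x), 0.29)

  t_x2 <- simulate_session(rep(3L, 600), cfg, duration = 10, seed = 1)
  expect_identical(as.data.frame(t_x), as.data.frame(t_x2))
})

test_that("smoothing bounds the per-tick force change across intent switches", {
  cfg <- controller_config("isometric_mimic")
  script <- c(rep(3L, 60), rep(7L, 60))   # +x then -x: a 8 N force reversal
  tr <- simulate_session(script, cfg, duration = 2, seed = 1)
  dF <- sqrt(diff(tr$Fvx)^2 + diff(tr$Fvy)^2)
  bound <- 8 * (1 / cfg$rate) / cfg$smoothing_T
  expect_lte(max(dF), bound + 1e-9)

  # without smoothing the switch is a step larger than the smoothed bound
  tr0 <- simulate_session(script, cfg, duration = 2, seed = 1,
                          smoothing = FALSE)
  dF0 <- sqrt(diff(tr0$Fvx)^2 + diff(tr0$Fvy)^2)
  expect_gt(max(dF0), bound)
  expect_equal(max(dF0), 8, tolerance = 1e-9)
})

test_that("the closed loop reaches every CO-PTP target", {
  cfg <- controller_config("isotonic_closed_loop")
  path <- path_spec("co_ptp")
  pat <- simulated_patient(path, cfg)
  tr <- simulate_session(pat, cfg, duration = 60, path = path, seed = 2)
  for (k in 1:8) {
    d <- sqrt((tr$x - path$targets[k, 1])^2 + (tr$y - path$targets[k, 2])^2)
    expect_lte(min(d), cfg$arrival_tol)
  }
  # and the trajectory is workspace-contained
  expect_true(all(abs(tr$x) <= 0.3 + 1e-9 & abs(tr$y) <= 0.15 + 1e-9))
})
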