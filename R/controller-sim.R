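#' Controller configuration
#'
#' Parameters of the intent-to-motion control law.  In `isometric_mimic` mode
#' the virtual force magnitude is 4 N; in `isotonic_closed_loop` mode 6.5 N,
#' with the simulated patient's hand force added to the loop.  The virtual
#' force points 30 mm ahead of the end effector along the intent direction,
#' force transitions are linearly smoothed over `smoothing_T` seconds, and the
#' PD gains (Kp = 0.15 (m/s)/N, Ki = 0, Kd = 0.5) convert force error into
#' Cartesian velocity at the 60 Hz control rate.  The workspace is a
#' 0.6 m x 0.3 m horizontal rectangle centered at the origin.
#'
#' @param mode `"isometric_mimic"` or `"isotonic_closed_loop"`.
#' @param target_offset Target-point offset in meters.
#' @param virtual_force Virtual force magnitude in newtons (`NULL` picks
#'   4 N / 6.5 N by mode).
#' @param smoothing_T Force-smoothing duration in seconds.
#' @param kp,ki,kd PID gains.
#' @param rate Control/logging rate in Hz.
#' @param workspace Workspace extents `c(width, height)` in meters.
#' @param resistance_cap Maximum patient hand force in newtons.
#' @param arrival_tol Distance at which the simulated patient considers a
#'   waypoint reached, meters.
#' @param patient_stiffness Gain (N/m) mapping distance-to-waypoint to the
#'   simulated patient's hand-force magnitude before capping.
#' @return A list of class `controller_config`.
#' @export
controller_config <- function(mode = c("isometric_mimic", "isotonic_closed_loop"),
                              target_offset = 0.030, virtual_force = NULL,
                              smoothing_T = 0.4, kp = 0.15, ki = 0, kd = 0.5,
                              rate = 60, workspace = c(0.6, 0.3),
                              resistance_cap = 25, arrival_tol = 0.010,
                              patient_stiffness = 40) {
  mode <- match.arg(mode)
  if (is.null(virtual_force)) {
    virtual_force <- if (mode == "isometric_mimic") 4 else 6.5
  }
  stopifnot(target_offset > 0, virtual_force > 0, smoothing_T > 0, rate > 0,
            all(workspace > 0), resistance_cap > 0, arrival_tol > 0,
            patient_stiffness > 0)
  structure(
    list(mode = mode, target_offset = target_offset,
         virtual_force = virtual_force, smoothing_T = smoothing_T,
         kp = kp, ki = ki, kd = kd, rate = rate, workspace = workspace,
         resistance_cap = resistance_cap, arrival_tol = arrival_tol,
         patient_stiffness = patient_stiffness),
    class = "controller_config"
  )
}

clamp_workspace <- function(p, workspace) {
  half <- workspace / 2
  c(min(max(p[1], -half[1]), half[1]), min(max(p[2], -half[2]), half[2]))
}

#' Virtual force and target point for an intent
#'
#' Rest (code 0) produces no virtual force and no target.  An active intent
#' places the target 30 mm from the current position along the intent
#' direction (clamped to the workspace) and generates a virtual force of the
#' mode's magnitude along that direction.
#'
#' @param position Current end-effector position `c(x, y)` in meters.
#' @param intent Integer intent code 0--8.
#' @param config A [controller_config()].
#' @return List with `force` (`c(Fx, Fy)` in newtons) and `target`
#'   (`c(x, y)` or `NULL` at rest).
#' @export
virtual_force <- function(position, intent, config = controller_config()) {
  stopifnot(length(position) == 2)
  if (length(intent) != 1 || is.na(intent) || !intent %in% 0:8) {
    rlang::abort("`intent` must be a single code in 0..8.")
  }
  if (intent == 0) {
    return(list(force = c(0, 0), target = NULL))
  }
  d <- intent_direction(intent)
  target <- clamp_workspace(position + config$target_offset * d, config$workspace)
  list(force = config$virtual_force * d, target = target)
}

#' Linear virtual-force smoothing across an intent transition
#'
#' `F_smooth = F_last * (T_remaining / T) + F_next * (T_passed / T)` with
#' `T_remaining = T - T_passed`: exactly `F_last` at the start of the
#' transition, exactly `F_next` once `T_passed = T`, linear in between.
#'
#' @param f_last,f_next Force 2-vectors before/after the intent change (N).
#' @param T_total Smoothing duration `T` in seconds (> 0).
#' @param t_passed Elapsed time since the change, clamped to `[0, T]`.
#' @return Smoothed force 2-vector.
#' @export
smooth_force <- function(f_last, f_next, T_total, t_passed) {
  if (T_total <= 0) rlang::abort("Smoothing duration must be positive.")
  t_passed <- min(max(t_passed, 0), T_total)
  t_remaining <- T_total - t_passed
  f_last * (t_remaining / T_total) + f_next * (t_passed / T_total)
}

#' Incremental PID state on the force error
#'
#' Implements the discrete loop `u = Kp * e + Ki * sum(e) + Kd * (e - e_prev)`
#' per control tick, the derivative taken on the error.  With `ki = 0` the
#' integrator term is inert.
#'
#' @param config A [controller_config()].
#' @return A function `step(error)` returning the commanded Cartesian
#'   velocity for the current tick and updating its internal state.
#' @export
pd_controller <- function(config = controller_config()) {
  integ <- c(0, 0)
  e_prev <- c(0, 0)
  function(error) {
    integ <<- integ + error
    u <- config$kp * error + config$ki * integ + config$kd * (error - e_prev)
    e_prev <<- error
    u
  }
}

#' Simulated patient following a path
#'
#' A closed-loop test double for the human: it walks the path waypoint by
#' waypoint (for CO-PTP, target by target with the return to center), emits
#' the intent code among 1--8 whose direction best matches the direction to
#' the current waypoint (rest within the arrival tolerance; ties to the
#' lowest code), and in isotonic mode applies a hand force along the true
#' direction with magnitude `min(patient_stiffness * distance,
#' resistance_cap)`.  The angle between the true direction and the quantized
#' intent direction never exceeds 22.5 degrees.
#'
#' @param path A [path_spec()].
#' @param config A [controller_config()].
#' @param waypoint_spacing Arc-length spacing (m) of the goal points sampled
#'   along the path (CO-PTP uses its 16 leg endpoints instead).
#' @return A stateful function `step(position)` returning a list with
#'   `intent`, `hand_force` and `done` (all waypoints visited).  On the tick
#'   a goal is reached the patient rests (intent 0); it resumes toward the
#'   next goal on the following tick.
#' @export
simulated_patient <- function(path, config = controller_config(),
                              waypoint_spacing = 0.02) {
  stopifnot(inherits(path, "path_spec"))
  goals <- if (path$kind == "co_ptp") {
    out <- matrix(0, 16, 2)
    for (k in 1:8) {
      out[2 * k - 1, ] <- path$targets[k, ]
      out[2 * k, ] <- c(0, 0)
    }
    out
  } else {
    n_goals <- max(2, ceiling(path$length / waypoint_spacing))
    idx <- unique(round(seq(1, nrow(path$waypoints), length.out = n_goals)))
    path$waypoints[idx, , drop = FALSE]
  }
  i <- 1L
  function(position) {
    arrived <- FALSE
    while (i <= nrow(goals) &&
           sqrt(sum((goals[i, ] - position)^2)) <= config$arrival_tol) {
      i <<- i + 1L
      arrived <- TRUE
    }
    if (i > nrow(goals)) {
      return(list(intent = 0L, hand_force = c(0, 0), done = TRUE))
    }
    if (arrived) {
      # rest on the arrival tick, resume next tick
      return(list(intent = 0L, hand_force = c(0, 0), done = FALSE))
    }
    v <- goals[i, ] - position
    dist <- sqrt(sum(v^2))
    dir <- v / dist
    mag <- min(config$patient_stiffness * dist, config$resistance_cap)
    list(intent = nearest_intent(v),
         hand_force = if (config$mode == "isotonic_closed_loop") mag * dir
                      else c(0, 0),
         done = FALSE)
  }
}

#' Home configuration placing the tool over the workspace center
#'
#' A comfortable elbow-bent pose of the default arm, away from kinematic
#' singularities over the whole workspace.
#'
#' @return Numeric vector of 6 joint angles (radians).
#' @export
home_configuration <- function() {
  c(0, -1.1, 1.5, -1.97, -1.57, 0)
}

#' Advance the simulated plant by one control step
#'
#' Builds the 6-D twist from the commanded in-plane velocity (out-of-plane
#' and angular components zero), solves the joint velocities through the
#' LU-factorized geometric Jacobian and integrates the joints by explicit
#' Euler over `dt`.  The planar position is the base-frame x--y offset of the
#' end effector from its home position, clamped to the workspace (velocity
#' zeroed at a hit boundary axis).
#'
#' @param model An [arm_model()].
#' @param q Current joint angles (6).
#' @param v_cmd Commanded planar velocity `c(vx, vy)` in m/s.
#' @param dt Time step in seconds (> 0).
#' @param home_position Base-frame end-effector position of the home pose.
#' @param workspace Workspace extents in meters.
#' @return List with `q` (new joint angles), `qdot`, and `position` (planar,
#'   workspace coordinates).
#' @export
step_plant <- function(model, q, v_cmd, dt, home_position,
                       workspace = c(0.6, 0.3)) {
  stopifnot(dt > 0, length(v_cmd) == 2)
  J <- geometric_jacobian(model, q)
  xi <- c(v_cmd[1], v_cmd[2], 0, 0, 0, 0)
  qdot <- joint_velocities(J, xi)
  q_new <- q + qdot * dt
  pos3 <- forward_kinematics(model, q_new)$position
  planar <- pos3[1:2] - home_position[1:2]
  clamped <- clamp_workspace(planar, workspace)
  if (any(clamped != planar)) {
    # saturate at the boundary: one corrective velocity step back onto it,
    # zeroing the blocked velocity component
    v_corr <- (clamped - planar) / dt
    J2 <- geometric_jacobian(model, q_new)
    qdot2 <- joint_velocities(J2, c(v_corr, 0, 0, 0, 0))
    q_new <- q_new + qdot2 * dt
    qdot <- qdot + qdot2
  }
  list(q = q_new, qdot = qdot, position = clamped)
}

#' Simulate a control session
#'
#' Runs the full loop at the control rate: acquire intent -> virtual force
#' (plus the simulated patient's hand force in isotonic mode; the gravity-
#' compensation hook is the identity in-plane) -> linear force smoothing on
#' intent changes -> PD velocity law -> inverse-Jacobian joint velocities ->
#' explicit-Euler plant step -> log.  Deterministic for a fixed seed.
#'
#' @param intent_source Either a [simulated_patient()] step function, an
#'   integer vector of scripted intent codes (one per tick, recycled), or a
#'   function `(position, tick) -> intent code`.
#' @param config A [controller_config()].
#' @param model An [arm_model()].
#' @param duration Session length in seconds (capped; a simulated patient
#'   stops early once its path is complete).
#' @param path Optional [path_spec()] (kept in the record for evaluation).
#' @param start Planar start position, defaults to the workspace center.
#' @param seed Integer seed (the loop itself is deterministic; the seed keys
#'   any stochastic intent source).
#' @param smoothing Apply the transition smoothing (disabling it reproduces
#'   the abrupt force steps the smoother exists to remove).
#' @return A tibble of class `trajectory_record` with columns `t`, `x`, `y`,
#'   `speed`, `Fvx`, `Fvy`, `Fmx`, `Fmy`, `intent`.
#' @export
simulate_session <- function(intent_source, config = controller_config(),
                             model = arm_model(), duration = 30,
                             path = NULL, start = c(0, 0), seed = 1L,
                             smoothing = TRUE) {
  dt <- 1 / config$rate
  n_ticks <- as.integer(ceiling(duration * config$rate))
  q <- home_configuration()
  home_position <- forward_kinematics(model, q)$position
  # place the start point by shifting the home reference
  home_position[1:2] <- home_position[1:2] - start
  position <- start
  pd <- pd_controller(config)

  scripted <- NULL
  if (is.numeric(intent_source)) {
    scripted <- as.integer(rep_len(intent_source, n_ticks))
  }

  f_cmd <- c(0, 0)      # currently commanded (smoothed) virtual force
  f_last <- c(0, 0)
  f_next <- c(0, 0)
  t_passed <- config$smoothing_T   # smoother inactive
  cur_intent <- 0L

  log <- matrix(0, n_ticks, 9)
  colnames(log) <- c("t", "x", "y", "speed", "Fvx", "Fvy", "Fmx", "Fmy", "intent")
  n_logged <- 0L

  res <- withr::with_seed(seed, {
    for (k in seq_len(n_ticks)) {
      hand <- c(0, 0)
      done <- FALSE
      intent <- if (!is.null(scripted)) {
        scripted[k]
      } else if (is.function(intent_source)) {
        out <- intent_source(position)
        if (is.list(out)) {
          hand <- out$hand_force %||% c(0, 0)
          done <- isTRUE(out$done)
          out$intent
        } else {
          as.integer(out)
        }
      } else {
        rlang::abort("Unsupported `intent_source`.")
      }
      if (done) break

      vf <- virtual_force(position, intent, config)
      if (intent != cur_intent) {
        f_last <- f_cmd
        f_next <- vf$force
        t_passed <- if (smoothing) 0 else config$smoothing_T
        cur_intent <- intent
      } else {
        f_next <- vf$force
      }
      t_passed <- min(t_passed + dt, config$smoothing_T)
      f_cmd <- smooth_force(f_last, f_next, config$smoothing_T, t_passed)

      # gravity compensation hook: identity for the planar task
      f_meas <- f_cmd + hand
      if (config$mode == "isotonic_closed_loop") {
        mag <- sqrt(sum(f_meas^2))
        if (mag > config$resistance_cap + config$virtual_force) {
          f_meas <- f_meas * (config$resistance_cap + config$virtual_force) / mag
        }
      }
      u <- pd(f_meas)

      stepped <- tryCatch(
        step_plant(model, q, u, dt, home_position, config$workspace),
        myointent_singularity = function(e) {
          rlang::warn(paste0("Session aborted at a kinematic singularity (tick ",
                             k, "); partial log returned."))
          NULL
        }
      )
      if (is.null(stepped)) break
      speed <- sqrt(sum((stepped$position - position)^2)) / dt
      q <- stepped$q
      position <- stepped$position
      n_logged <- n_logged + 1L
      log[n_logged, ] <- c((k - 1) * dt, position[1], position[2], speed,
                           f_cmd[1], f_cmd[2], hand[1], hand[2], intent)
    }
    log[seq_len(n_logged), , drop = FALSE]
  })

  out <- tibble::as_tibble(as.data.frame(res))
  out$intent <- as.integer(out$intent)
  attr(out, "config") <- config
  attr(out, "path") <- if (!is.null(path)) path$kind else NA_character_
  attr(out, "seed") <- seed
  class(out) <- c("trajectory_record", class(out))
  out
}
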