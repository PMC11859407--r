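#' Standard test-path specification
#'
#' The four benchmark paths live on the 0.6 m x 0.3 m horizontal workspace
#' centered at the origin:
#' * `circle`: radius 0.1 m around the workspace center;
#' * `co_ptp`: center-out point-to-point -- out-and-back from the center to 8
#'   targets evenly spaced (clockwise from +y) on the radius-0.1 circle, total
#'   length 16 x 0.1 = 1.6 m;
#' * `sine1`: `y = 0.1 * sin(10 * pi * x - 0.525)` for `x` in `[-0.2, 0.2]`;
#' * `sine2`: `y = 0.1 * sin(5 * pi * x - 0.525)` for `x` in `[-0.2, 0.2]`.
#'
#' Paths are represented as dense waypoint polylines (default `n = 10^4`
#' points) for distance queries; the standard length `L` of the sine paths is
#' obtained by numeric arc-length integration, the circle and CO-PTP lengths
#' in closed form.
#'
#' @param kind One of `"circle"`, `"co_ptp"`, `"sine1"`, `"sine2"`.
#' @param n Number of dense waypoints.
#' @param radius Circle / CO-PTP target radius in meters.
#' @param workspace Workspace extents `c(width, height)` in meters.
#' @return An object of class `path_spec`: list with `kind`, `waypoints`
#'   (n x 2 matrix), `length` (m) and for CO-PTP also `targets` (8 x 2).
#' @export
path_spec <- function(kind = c("circle", "co_ptp", "sine1", "sine2"),
                      n = 10000, radius = 0.1, workspace = c(0.6, 0.3)) {
  kind <- match.arg(kind)
  half <- workspace / 2
  wp <- switch(kind,
    circle = {
      th <- seq(0, 2 * pi, length.out = n)
      cbind(radius * cos(th), radius * sin(th))
    },
    co_ptp = {
      targets <- t(vapply(1:8, intent_direction, numeric(2))) * radius
      pts <- list()
      per_leg <- max(2, floor(n / 16))
      for (k in 1:8) {
        s <- seq(0, 1, length.out = per_leg)
        pts[[2 * k - 1]] <- cbind(s * targets[k, 1], s * targets[k, 2])
        pts[[2 * k]] <- cbind(rev(s) * targets[k, 1], rev(s) * targets[k, 2])
      }
      do.call(rbind, pts)
    },
    sine1 = {
      x <- seq(-0.2, 0.2, length.out = n)
      cbind(x, 0.1 * sin(10 * pi * x - 0.525))
    },
    sine2 = {
      x <- seq(-0.2, 0.2, length.out = n)
      cbind(x, 0.1 * sin(5 * pi * x - 0.525))
    }
  )
  if (any(abs(wp[, 1]) > half[1] + 1e-9) || any(abs(wp[, 2]) > half[2] + 1e-9)) {
    rlang::abort("Path exceeds the workspace bounds.")
  }
  len <- switch(kind,
    circle = 2 * pi * radius,
    co_ptp = 16 * radius,
    sum(sqrt(rowSums(diff(wp)^2)))
  )
  out <- list(kind = kind, waypoints = wp, length = len, radius = radius,
              workspace = workspace)
  if (kind == "co_ptp") {
    out$targets <- t(vapply(1:8, intent_direction, numeric(2))) * radius
  }
  structure(out, class = "path_spec")
}

#' @export
print.path_spec <- function(x, ...) {
  cat(sprintf("<path_spec> %s: L = %.5f m, %d waypoints\n",
              x$kind, x$length, nrow(x$waypoints)))
  invisible(x)
}

#' Custom standard path from a waypoint polyline
#'
#' Wraps an arbitrary waypoint matrix as a path for the trajectory metrics,
#' e.g. a bespoke training shape; the standard length is the polyline length
#' unless given explicitly.
#'
#' @param waypoints n x 2 numeric matrix (meters).
#' @param length Standard length `L` in meters (default: polyline length).
#' @param kind Label stored on the path.
#' @return A [path_spec()] object.
#' @export
polyline_path <- function(waypoints, length = NULL, kind = "custom") {
  waypoints <- as.matrix(waypoints)
  stopifnot(ncol(waypoints) == 2, nrow(waypoints) >= 2)
  len <- length %||% sum(sqrt(rowSums(diff(waypoints)^2)))
  if (len <= 0) rlang::abort("Standard path length must be positive.")
  structure(
    list(kind = kind, waypoints = waypoints, length = len, radius = NA_real_,
         workspace = NULL),
    class = "path_spec"
  )
}

#' The four standard test paths
#'
#' @inheritParams path_spec
#' @return Named list of [path_spec()] objects (`circle`, `co_ptp`, `sine1`,
#'   `sine2`).
#' @export
standard_paths <- function(workspace = c(0.6, 0.3), n = 10000) {
  kinds <- c("circle", "co_ptp", "sine1", "sine2")
  stats::setNames(
    lapply(kinds, path_spec, n = n, workspace = workspace), kinds
  )
}

#' Distance from a point to a path
#'
#' Minimum Euclidean distance from `point` to the path polyline, using exact
#' point-to-segment projection on every segment (not just nearest vertex).
#'
#' @param point Numeric length-2 vector.
#' @param path A [path_spec()].
#' @return Distance in meters.
#' @export
point_to_path_distance <- function(point, path) {
  stopifnot(length(point) == 2, inherits(path, "path_spec"))
  min(points_to_path_distances(matrix(point, 1), path))
}

# Vectorized over query points: for each point the min distance over all
# polyline segments, via clamped projection.
points_to_path_distances <- function(points, path) {
  wp <- path$waypoints
  a <- wp[-nrow(wp), , drop = FALSE]
  b <- wp[-1, , drop = FALSE]
  d <- b - a
  len2 <- rowSums(d^2)
  keep <- len2 > 0
  a <- a[keep, , drop = FALSE]; d <- d[keep, , drop = FALSE]
  len2 <- len2[keep]
  vapply(seq_len(nrow(points)), function(i) {
    p <- points[i, ]
    t_ <- ((p[1] - a[, 1]) * d[, 1] + (p[2] - a[, 2]) * d[, 2]) / len2
    t_ <- pmin(1, pmax(0, t_))
    qx <- a[, 1] + t_ * d[, 1]
    qy <- a[, 2] + t_ * d[, 2]
    sqrt(min((p[1] - qx)^2 + (p[2] - qy)^2))
  }, numeric(1))
}

traj_positions <- function(traj) {
  stopifnot(is.data.frame(traj), all(c("x", "y") %in% names(traj)))
  cbind(traj$x, traj$y)
}

# Speeds by central differences of logged positions at the logging rate;
# one-sided differences at the ends.
traj_speeds <- function(traj) {
  p <- traj_positions(traj)
  t <- traj$t
  n <- nrow(p)
  if (n < 2) rlang::abort("Trajectory needs at least 2 samples.")
  v <- numeric(n)
  v[1] <- sqrt(sum((p[2, ] - p[1, ])^2)) / (t[2] - t[1])
  v[n] <- sqrt(sum((p[n, ] - p[n - 1, ])^2)) / (t[n] - t[n - 1])
  if (n > 2) {
    i <- 2:(n - 1)
    v[i] <- sqrt(rowSums((p[i + 1, , drop = FALSE] - p[i - 1, , drop = FALSE])^2)) /
      (t[i + 1] - t[i - 1])
  }
  v
}

#' Movement smoothness
#'
#' `lambda_s = v_a / v_max`: average over maximum speed within the segment,
#' in `[0, 1]`; values near 1 indicate coherent, even motion.  Speeds are
#' estimated by central differences of the logged positions by default;
#' `speed_source = "logged"` uses the trajectory's own `speed` column
#' instead.
#'
#' @param traj A trajectory data frame with columns `t`, `x`, `y` (and
#'   `speed` for `speed_source = "logged"`).
#' @param speed_source `"positions"` (central differences) or `"logged"`.
#' @return A one-row tibble with `lambda_s`, `v_a`, `v_max`; `lambda_s` is
#'   `NA` (with a warning) when the trajectory never moves.
#' @export
smoothness <- function(traj, speed_source = c("positions", "logged")) {
  speed_source <- match.arg(speed_source)
  v <- if (speed_source == "logged") {
    stopifnot("speed" %in% names(traj))
    traj$speed
  } else {
    traj_speeds(traj)
  }
  v_max <- max(v)
  if (v_max == 0) {
    rlang::warn("All speeds are zero; smoothness is undefined.")
    return(tibble::tibble(lambda_s = NA_real_, v_a = 0, v_max = 0))
  }
  tibble::tibble(lambda_s = mean(v) / v_max, v_a = mean(v), v_max = v_max)
}

#' Range deviation from the standard path
#'
#' `Rx = (1 / L) * (1 / (N - 1)) * sum(ds_k^2)` over the `N` logged samples,
#' where `ds_k` is the distance from the end effector to the standard path and
#' `L` the standard path length; `lambda_d = 1 / (1 + Rx)` in `(0, 1]`.  The
#' squared-distance form is the normative one; `variant = "rms"` replaces the
#' sum of squares by its square root.
#'
#' @param traj Trajectory data frame (`t`, `x`, `y`).
#' @param path A [path_spec()].
#' @param variant `"squared"` (default) or `"rms"`.
#' @return One-row tibble with `lambda_d` and `rx`.
#' @export
range_deviation <- function(traj, path, variant = c("squared", "rms")) {
  variant <- match.arg(variant)
  stopifnot(inherits(path, "path_spec"))
  if (path$length <= 0) rlang::abort("Standard path length must be positive.")
  p <- traj_positions(traj)
  n <- nrow(p)
  if (n < 2) rlang::abort("Trajectory needs at least 2 samples.")
  ds <- points_to_path_distances(p, path)
  ss <- sum(ds^2)
  if (variant == "rms") ss <- sqrt(ss)
  rx <- ss / (path$length * (n - 1))
  tibble::tibble(lambda_d = 1 / (1 + rx), rx = rx)
}

#' Normalized path length
#'
#' `lambda_l = L_r / L`: the ratio of the traveled trajectory length `L_r`
#' (summed segment lengths of the logged positions) to the standard path
#' length `L`.  Values near 1 indicate efficient tracking; the metric alone
#' does not measure similarity to the path, so it is read together with
#' `lambda_d`.
#'
#' @inheritParams range_deviation
#' @return One-row tibble with `lambda_l` and `l_r`.
#' @export
normalized_path_length <- function(traj, path) {
  stopifnot(inherits(path, "path_spec"))
  if (path$length <= 0) rlang::abort("Standard path length must be positive.")
  p <- traj_positions(traj)
  if (nrow(p) < 2) rlang::abort("Trajectory needs at least 2 samples.")
  l_r <- sum(sqrt(rowSums(diff(p)^2)))
  tibble::tibble(lambda_l = l_r / path$length, l_r = l_r)
}

#' Evaluate a trajectory against a standard path
#'
#' Computes all three trajectory-quality metrics and their intermediates.
#'
#' @inheritParams range_deviation
#' @return A one-row tibble of class `metrics_report` with columns
#'   `path`, `lambda_s`, `lambda_d`, `lambda_l`, `rx`, `v_a`, `v_max`, `l_r`,
#'   `l_standard`, `n_samples`.
#' @export
evaluate_trajectory <- function(traj, path, variant = c("squared", "rms")) {
  sm <- smoothness(traj)
  rd <- range_deviation(traj, path, variant = variant)
  pl <- normalized_path_length(traj, path)
  kind <- path$kind
  l_std <- path$length
  out <- tibble::tibble(
    path = kind,
    lambda_s = sm$lambda_s, lambda_d = rd$lambda_d, lambda_l = pl$lambda_l,
    rx = rd$rx, v_a = sm$v_a, v_max = sm$v_max, l_r = pl$l_r,
    l_standard = l_std, n_samples = nrow(traj)
  )
  class(out) <- c("metrics_report", class(out))
  out
}
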