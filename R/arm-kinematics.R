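#' Six-revolute-joint arm model from Denavit--Hartenberg parameters
#'
#' The arm is described by standard DH parameters per joint (`a`, `d`,
#' `alpha`, `theta_offset`), all joints revolute.  The default parameter set
#' is the UR5 manipulator, the arm the control pseudocode drives; any 6R arm
#' can be supplied.
#'
#' @param dh Data frame with 6 rows and columns `a`, `d`, `alpha`,
#'   `theta_offset` (meters / radians).
#' @param limits Optional 6 x 2 matrix of joint limits in radians.
#' @return An object of class `arm_model`.
#' @export
arm_model <- function(dh = ur5_dh(), limits = NULL) {
  dh <- as.data.frame(dh)
  if (nrow(dh) != 6 || !all(c("a", "d", "alpha", "theta_offset") %in% names(dh))) {
    rlang::abort("`dh` must have 6 rows and columns a, d, alpha, theta_offset.")
  }
  if (!is.null(limits)) stopifnot(is.matrix(limits), all(dim(limits) == c(6, 2)))
  structure(list(dh = dh, limits = limits), class = "arm_model")
}

#' UR5 Denavit--Hartenberg parameters
#'
#' @return Data frame of standard DH parameters (meters, radians).
#' @export
ur5_dh <- function() {
  data.frame(
    a = c(0, -0.425, -0.39225, 0, 0, 0),
    d = c(0.089159, 0, 0, 0.10915, 0.09465, 0.0823),
    alpha = c(pi / 2, 0, 0, pi / 2, -pi / 2, 0),
    theta_offset = rep(0, 6)
  )
}

#' @export
print.arm_model <- function(x, ...) {
  cat("<arm_model> 6 revolute joints (DH)\n")
  print(x$dh)
  invisible(x)
}

dh_transform <- function(a, d, alpha, theta) {
  ct <- cos(theta); st <- sin(theta)
  ca <- cos(alpha); sa <- sin(alpha)
  matrix(c(
    ct, -st * ca,  st * sa, a * ct,
    st,  ct * ca, -ct * sa, a * st,
    0,        sa,       ca,      d,
    0,         0,        0,      1
  ), nrow = 4, byrow = TRUE)
}

#' Forward kinematics of a 6R arm
#'
#' Chains the per-joint DH transforms and exposes every intermediate frame
#' (origins `o_0 ... o_6` and z-axes `z_0 ... z_6`) so the geometric Jacobian
#' can be assembled from them.
#'
#' @param model An [arm_model()].
#' @param q Numeric vector of 6 joint angles in radians.
#' @return A list of class `arm_pose`: `position` (3-vector, m), `rotation`
#'   (3 x 3), `origins` (3 x 7 matrix, frame 0 first) and `z_axes` (3 x 7).
#' @export
forward_kinematics <- function(model, q) {
  stopifnot(inherits(model, "arm_model"))
  if (length(q) != 6 || !is.numeric(q)) {
    rlang::abort("`q` must be a numeric vector of 6 joint angles.")
  }
  T_acc <- diag(4)
  origins <- matrix(0, 3, 7)
  z_axes <- matrix(0, 3, 7)
  z_axes[, 1] <- c(0, 0, 1)
  for (i in 1:6) {
    p <- model$dh[i, ]
    T_acc <- T_acc %*% dh_transform(p$a, p$d, p$alpha, q[i] + p$theta_offset)
    origins[, i + 1] <- T_acc[1:3, 4]
    z_axes[, i + 1] <- T_acc[1:3, 3]
  }
  structure(
    list(position = T_acc[1:3, 4], rotation = T_acc[1:3, 1:3],
         origins = origins, z_axes = z_axes),
    class = "arm_pose"
  )
}

#' Geometric Jacobian of a 6R arm
#'
#' Column `i` is `[z_{i-1} x (o_n - o_{i-1}); z_{i-1}]`, the revolute-joint
#' rule: rows 1--3 map joint rates to end-effector linear velocity, rows 4--6
#' to angular velocity.
#'
#' @inheritParams forward_kinematics
#' @return A 6 x 6 numeric matrix.
#' @export
geometric_jacobian <- function(model, q) {
  fk <- forward_kinematics(model, q)
  on <- fk$position
  J <- matrix(0, 6, 6)
  for (i in 1:6) {
    z <- fk$z_axes[, i]
    o <- fk$origins[, i]
    J[1:3, i] <- cross3(z, on - o)
    J[4:6, i] <- z
  }
  J
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Skew-symmetric matrix of an angular-velocity vector
#'
#' Returns `S(w)` with `S(w) %*% u == cross(w, u)` and `S + t(S) == 0`; it is
#' the matrix satisfying `S(w) = Rdot %*% t(R)` for a frame rotating with
#' angular velocity `w`.
#'
#' @param omega Numeric 3-vector.
#' @return A 3 x 3 skew-symmetric matrix.
#' @export
skew <- function(omega) {
  stopifnot(is.numeric(omega), length(omega) == 3)
  matrix(c(
    0, -omega[3], omega[2],
    omega[3], 0, -omega[1],
    -omega[2], omega[1], 0
  ), nrow = 3, byrow = TRUE)
}

#' Euler-rate transform B(alpha)
#'
#' For Euler angles `alpha = c(phi, theta, psi)` (Z-Y-Z convention), `B(alpha)`
#' maps Euler-angle rates to the angular-velocity vector.  Its determinant is
#' `sin(theta)`, so the representation is singular at `theta = 0` or `pi`.
#'
#' @param euler Numeric 3-vector `c(phi, theta, psi)` in radians.
#' @return A 3 x 3 matrix.
#' @export
euler_rate_matrix <- function(euler) {
  stopifnot(is.numeric(euler), length(euler) == 3)
  theta <- euler[2]; psi <- euler[3]
  matrix(c(
    cos(psi) * sin(theta), -sin(psi), 0,
    sin(psi) * sin(theta),  cos(psi), 0,
    cos(theta),                    0, 1
  ), nrow = 3, byrow = TRUE)
}

#' Analytic Jacobian from the geometric Jacobian
#'
#' `Ja = blockdiag(I, B(alpha)^-1) %*% Jg`: the linear-velocity rows pass
#' through unchanged; the angular rows are mapped to Euler-angle rates.
#' Fails with an explicit error at a representation singularity
#' (`det B(alpha)` approximately 0).
#'
#' @param J 6 x 6 geometric Jacobian.
#' @param euler Euler angles `c(phi, theta, psi)` in radians.
#' @param tol Singularity tolerance on `abs(det(B))`.
#' @return The 6 x 6 analytic Jacobian.
#' @export
analytic_from_geometric <- function(J, euler, tol = 1e-8) {
  stopifnot(is.matrix(J), all(dim(J) == c(6, 6)))
  B <- euler_rate_matrix(euler)
  if (abs(det(B)) < tol) {
    rlang::abort(sprintf(
      "Euler representation singularity: |det B(alpha)| = %.3g (theta = %.4f rad).",
      abs(det(B)), euler[2]
    ))
  }
  rbind(J[1:3, , drop = FALSE], solve(B, J[4:6, , drop = FALSE]))
}

#' Joint velocities from an end-effector twist (LU solve)
#'
#' Solves `J %*% qdot = xi` by LU factorization with partial pivoting.
#' Configurations where `J` is singular or nearly so (2-norm condition number
#' above `max_condition`) are rejected with an explicit singularity error.
#'
#' @param J 6 x 6 Jacobian.
#' @param xi Twist `c(v, w)` (m/s, rad/s), length 6.
#' @param max_condition Condition-number threshold.
#' @return Numeric vector of 6 joint velocities (rad/s).
#' @export
joint_velocities <- function(J, xi, max_condition = 1e8) {
  stopifnot(is.matrix(J), all(dim(J) == c(6, 6)), length(xi) == 6)
  sv <- svd(J, nu = 0, nv = 0)$d
  cond <- if (min(sv) == 0) Inf else max(sv) / min(sv)
  if (!is.finite(cond) || cond > max_condition) {
    rlang::abort(sprintf(
      "Singular or ill-conditioned Jacobian (condition number %.3g > %.3g); the arm is at or near a kinematic singularity.",
      cond, max_condition
    ), class = "myointent_singularity")
  }
  # LAPACK dgesv: LU factorization with partial pivoting + triangular solves
  as.numeric(solve(J, xi))
}
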