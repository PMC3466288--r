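#' Parameters of the planar two-joint arm
#'
#' Rigid-body constants of a two-link arm moving in the horizontal plane
#' (no gravity): shoulder at the origin, x to the subject's right, y away
#' from the body, joint angles counter-clockwise positive.
#'
#' @param L link lengths (m), upper arm and forearm+hand.
#' @param m link masses (kg).
#' @param lc distances from the proximal joint to the link center of mass (m).
#' @param I link moments of inertia about the center of mass (kg m^2).
#' @param B 2x2 joint viscosity matrix (N m s/rad), symmetric positive
#'   semi-definite.
#' @param q_lim 2x2 matrix of joint limits (rad), rows = joints,
#'   columns = lower/upper. Used for validation only.
#' @return An object of class \code{arm_parameters}.
#' @export
arm_parameters <- function(L = c(0.30, 0.33),
                           m = c(1.40, 1.10),
                           lc = c(0.11, 0.16),
                           I = c(0.025, 0.045),
                           B = matrix(c(0.8, 0.2, 0.2, 0.8), 2, 2),
                           q_lim = rbind(c(-0.5 * pi, pi), c(0.01, 0.99 * pi))) {
  stopifnot(length(L) == 2, length(m) == 2, length(lc) == 2, length(I) == 2)
  if (any(c(L, m, I) <= 0)) {
    stop("link lengths, masses and inertias must be strictly positive")
  }
  if (any(lc <= 0) || any(lc > L)) {
    stop("centers of mass must lie on the links (0 < lc <= L)")
  }
  B <- as.matrix(B)
  if (!isTRUE(all.equal(B, t(B))) || any(eigen(B, symmetric = TRUE,
                                               only.values = TRUE)$values < -1e-12)) {
    stop("joint viscosity matrix B must be symmetric positive semi-definite")
  }
  structure(list(L = as.numeric(L), m = as.numeric(m), lc = as.numeric(lc),
                 I = as.numeric(I), B = B, q_lim = q_lim),
            class = "arm_parameters")
}

#' Arm state
#'
#' Joint angles and velocities of the two-joint arm at a time point.
#'
#' @param q joint angles (rad), length 2 (shoulder, elbow).
#' @param qdot joint angular velocities (rad/s), length 2.
#' @param time time stamp (s).
#' @param arm optional \code{\link{arm_parameters}}; if given, joint limits
#'   are checked.
#' @return An object of class \code{arm_state}.
#' @export
arm_state <- function(q, qdot = c(0, 0), time = 0, arm = NULL) {
  q <- as.numeric(q); qdot <- as.numeric(qdot)
  if (length(q) != 2 || length(qdot) != 2 || !all(is.finite(c(q, qdot, time)))) {
    stop("arm state must contain finite q, qdot of length 2 and a finite time")
  }
  if (!is.null(arm)) {
    if (any(q < arm$q_lim[, 1]) || any(q > arm$q_lim[, 2])) {
      stop("joint angles outside configured limits")
    }
  }
  structure(list(q = q, qdot = qdot, time = as.numeric(time)),
            class = "arm_state")
}

#' @export
print.arm_state <- function(x, ...) {
  cat(sprintf("arm state at t = %.3f s: q = (%.3f, %.3f) rad, qdot = (%.3f, %.3f) rad/s\n",
              x$time, x$q[1], x$q[2], x$qdot[1], x$qdot[2]))
  invisible(x)
}

#' Inertia matrix of the two-link arm
#'
#' @param q joint angles (rad).
#' @param arm \code{\link{arm_parameters}}.
#' @return 2x2 configuration-dependent inertia matrix (kg m^2).
#' @export
mass_matrix <- function(q, arm) {
  c2 <- cos(q[2])
  a <- arm$I[1] + arm$I[2] + arm$m[1] * arm$lc[1]^2 +
    arm$m[2] * (arm$L[1]^2 + arm$lc[2]^2)
  b <- arm$m[2] * arm$L[1] * arm$lc[2]
  m12 <- arm$I[2] + arm$m[2] * arm$lc[2]^2 + b * c2
  matrix(c(a + 2 * b * c2, m12, m12, arm$I[2] + arm$m[2] * arm$lc[2]^2), 2, 2)
}

#' Coriolis/centripetal matrix of the two-link arm
#'
#' Returns C(q, qdot) such that the velocity-dependent joint torque is
#' \code{-C \%*\% qdot}.
#'
#' @inheritParams mass_matrix
#' @param qdot joint velocities (rad/s).
#' @return 2x2 matrix.
#' @export
coriolis_matrix <- function(q, qdot, arm) {
  h <- arm$m[2] * arm$L[1] * arm$lc[2] * sin(q[2])
  matrix(c(-h * qdot[2], h * qdot[1], -h * (qdot[1] + qdot[2]), 0), 2, 2)
}

#' Forward kinematics: hand position
#'
#' @inheritParams mass_matrix
#' @return hand position (m), length 2.
#' @export
forward_kinematics <- function(q, arm) {
  c(arm$L[1] * cos(q[1]) + arm$L[2] * cos(q[1] + q[2]),
    arm$L[1] * sin(q[1]) + arm$L[2] * sin(q[1] + q[2]))
}

#' Hand Jacobian
#'
#' @inheritParams mass_matrix
#' @return 2x2 Jacobian dp/dq (m/rad); hand velocity is \code{J \%*\% qdot}.
#' @export
jacobian <- function(q, arm) {
  s1 <- sin(q[1]); c1 <- cos(q[1])
  s12 <- sin(q[1] + q[2]); c12 <- cos(q[1] + q[2])
  matrix(c(-arm$L[1] * s1 - arm$L[2] * s12, arm$L[1] * c1 + arm$L[2] * c12,
           -arm$L[2] * s12, arm$L[2] * c12), 2, 2)
}

#' Inverse kinematics of the planar arm
#'
#' Elbow-positive solution (q2 in (0, pi)), the natural posture for a right
#' arm reaching in front of the body.
#'
#' @param p hand position (m), length 2.
#' @param arm \code{\link{arm_parameters}}.
#' @param tol rejection tolerance near the workspace boundary.
#' @return joint angles (rad), length 2.
#' @export
inverse_kinematics <- function(p, arm, tol = 1e-9) {
  r2 <- sum(p^2)
  c2 <- (r2 - arm$L[1]^2 - arm$L[2]^2) / (2 * arm$L[1] * arm$L[2])
  if (c2 > 1 - tol || c2 < -1 + tol) {
    stop(sprintf("hand position (%.3f, %.3f) unreachable or singular", p[1], p[2]))
  }
  q2 <- acos(c2)
  q1 <- atan2(p[2], p[1]) - atan2(arm$L[2] * sin(q2), arm$L[1] + arm$L[2] * cos(q2))
  c(q1, q2)
}

#' Kinetic energy of the arm
#'
#' @inheritParams coriolis_matrix
#' @return scalar energy (J).
#' @export
kinetic_energy <- function(q, qdot, arm) {
  0.5 * drop(crossprod(qdot, mass_matrix(q, arm) %*% qdot))
}

#' Forward dynamics of the arm
#'
#' Joint accelerations of the horizontal-plane two-link arm under joint
#' torques, an external endpoint force, Coriolis/centripetal torques and
#' joint viscosity.
#'
#' @param state \code{\link{arm_state}}.
#' @param tau joint torques (N m), length 2.
#' @param F_ext external force applied at the hand (N), length 2.
#' @param arm \code{\link{arm_parameters}}.
#' @param singular_tol elbow angles within this distance (rad) of full
#'   extension/flexion are rejected as singular.
#' @return joint accelerations (rad/s^2), length 2.
#' @export
forward_dynamics <- function(state, tau, F_ext = c(0, 0), arm,
                             singular_tol = 1e-6) {
  q <- state$q; qdot <- state$qdot
  if (!all(is.finite(c(q, qdot, tau, F_ext)))) {
    stop("non-finite state, torque or external force")
  }
  if (min(abs(sin(q[2])), abs(q[2])) < singular_tol && abs(sin(q[2])) < singular_tol) {
    # elbow fully extended/folded: inertia still invertible, but the posture
    # is kinematically singular for endpoint control; flag it
    if (abs(q[2]) < singular_tol || abs(abs(q[2]) - pi) < singular_tol) {
      stop("singular elbow posture")
    }
  }
  M <- mass_matrix(q, arm)
  Cm <- coriolis_matrix(q, qdot, arm)
  J <- jacobian(q, arm)
  rhs <- tau + drop(t(J) %*% F_ext) - drop(Cm %*% qdot) - drop(arm$B %*% qdot)
  drop(solve(M, rhs))
}
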