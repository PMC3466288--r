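#' Muscle geometry of the six-muscle arm
#'
#' Constant moment arms for the six muscles acting on the two joints:
#' shoulder flexor/extensor, elbow flexor/extensor, biarticular
#' flexor/extensor (in that column order). Muscle lengths are linearized
#' around a reference posture: \code{l = l0 - t(A) \%*\% (q - q_ref)}, so a
#' muscle with a positive moment arm at a joint shortens when that joint
#' flexes (angle increases) and its tension produces positive torque there.
#'
#' @param A 2x6 moment-arm matrix (m); rows = shoulder/elbow joints.
#' @param l0 muscle lengths at the reference posture (m), length 6.
#' @param q_ref reference posture (rad), length 2.
#' @return An object of class \code{muscle_geometry}.
#' @export
muscle_geometry <- function(A = default_moment_arms(),
                            l0 = rep(0.15, 6),
                            q_ref = c(pi / 4, pi / 2)) {
  A <- as.matrix(A)
  stopifnot(nrow(A) == 2, ncol(A) == 6, length(l0) == 6, length(q_ref) == 2)
  mono <- colSums(A != 0)
  if (any(mono[1:4] != 1)) {
    stop("monoarticular muscle columns (1-4) must act on exactly one joint")
  }
  if (any(mono[5:6] != 2)) {
    stop("biarticular muscle columns (5-6) must act on both joints")
  }
  # antagonist pairs: (1,2) shoulder, (3,4) elbow, (5,6) biarticular
  for (p in list(c(1, 2), c(3, 4), c(5, 6))) {
    if (any(sign(A[, p[1]]) * sign(A[, p[2]]) > 0)) {
      stop("antagonist muscle pairs must have opposite-sign moment arms")
    }
  }
  if (any(l0 <= 0)) stop("reference muscle lengths must be positive")
  structure(list(A = A, l0 = as.numeric(l0), q_ref = as.numeric(q_ref)),
            class = "muscle_geometry")
}

#' Default moment-arm matrix
#'
#' Moment arms of a few centimeters, in the range used by planar
#' two-joint six-muscle arm models; antagonist pairs are symmetric so that
#' uniform co-activation is torque-balanced.
#'
#' @return 2x6 matrix (m).
#' @export
default_moment_arms <- function() {
  rbind(c(0.040, -0.040, 0.000, 0.000, 0.040, -0.040),
        c(0.000, 0.000, 0.025, -0.025, 0.025, -0.025))
}

#' Muscle visco-elastic parameters
#'
#' Tension of muscle i at activation u, length l and lengthening velocity
#' ldot is
#' \deqn{T_i = max(0, T0 u_i + (k0 + k1 u_i)(l_i - \lambda_i(t))
#'                    + (b0 + b1 u_i)(ldot_i - \dot\lambda_i(t)))}
#' an active contractile term plus intrinsic elasticity and viscosity that
#' both increase affinely with activation. The visco-elastic rest length
#' \eqn{\lambda_i(t) = l_{r,i}(t) - \rho u_i} travels with the descending
#' reference command and is shortened by activation, so muscle impedance
#' acts instantaneously around the intended trajectory
#' (equilibrium-trajectory control): co-activation of an antagonist pair
#' produces no net torque on the undisturbed path but resists deviations
#' from it. Tension is rectified at zero because muscles only pull.
#'
#' @param T0 active tension per unit activation (N).
#' @param k0,k1 intrinsic stiffness intercept and slope (N/m per unit u).
#' @param b0,b1 intrinsic viscosity intercept and slope (N s/m per unit u).
#' @param rho rest-length shortening per unit activation (m).
#' @return An object of class \code{muscle_parameters}.
#' @export
muscle_parameters <- function(T0 = 400, k0 = 100, k1 = 30000,
                              b0 = 10, b1 = 2000, rho = 0.015) {
  vals <- c(T0 = T0, k0 = k0, k1 = k1, b0 = b0, b1 = b1, rho = rho)
  if (any(vals < 0)) {
    stop(sprintf("negative muscle parameter: %s",
                 paste(names(vals)[vals < 0], collapse = ", ")))
  }
  structure(as.list(vals), class = "muscle_parameters")
}

#' Muscle lengths and lengthening velocities
#'
#' @param state \code{\link{arm_state}}.
#' @param geom \code{\link{muscle_geometry}}.
#' @return list with components \code{l} (lengths, m) and \code{ldot}
#'   (lengthening velocities, m/s), each length 6.
#' @export
muscle_lengths <- function(state, geom) {
  if (!all(is.finite(c(state$q, state$qdot)))) {
    stop("non-finite arm state")
  }
  list(l = geom$l0 - drop(crossprod(geom$A, state$q - geom$q_ref)),
       ldot = -drop(crossprod(geom$A, state$qdot)))
}

#' Muscle tensions
#'
#' @param u muscle activations (dimensionless, >= 0), length 6.
#' @param l muscle lengths (m), length 6.
#' @param ldot muscle lengthening velocities (m/s), length 6.
#' @param geom \code{\link{muscle_geometry}} (provides rest lengths).
#' @param muscle \code{\link{muscle_parameters}}.
#' @param l_r,ldot_r reference muscle lengths and their rates (the
#'   descending equilibrium trajectory); default: the static rest lengths.
#' @return tensions (N), length 6, never negative.
#' @export
muscle_tension <- function(u, l, ldot, geom, muscle = muscle_parameters(),
                           l_r = geom$l0, ldot_r = rep(0, 6)) {
  if (any(u < 0)) stop("muscle activations must be non-negative")
  stretch <- l - l_r + muscle$rho * u
  pmax(0, muscle$T0 * u + (muscle$k0 + muscle$k1 * u) * stretch +
         (muscle$b0 + muscle$b1 * u) * (ldot - ldot_r))
}

#' Joint torques from muscle tensions
#'
#' @param T_m muscle tensions (N), length 6, >= 0.
#' @param geom \code{\link{muscle_geometry}}.
#' @return joint torques (N m), length 2.
#' @export
joint_torque <- function(T_m, geom) {
  if (length(T_m) != ncol(geom$A)) stop("tension vector has wrong length")
  if (any(T_m < 0)) stop("tensions must be non-negative (muscles only pull)")
  drop(geom$A %*% T_m)
}

#' Signal-dependent motor noise
#'
#' Adds one independent zero-mean Gaussian draw per muscle whose standard
#' deviation is proportional to the activation; the result is clipped at
#' zero. Uses the current R RNG stream, so calls are reproducible under
#' \code{set.seed}.
#'
#' @param u muscle activations, length 6, >= 0.
#' @param coef noise coefficient (sd per unit activation).
#' @return perturbed activation vector, >= 0.
#' @export
signal_dependent_noise <- function(u, coef = 0.05) {
  if (any(u < 0)) stop("muscle activations must be non-negative")
  if (coef == 0) return(u)
  pmax(0, u + stats::rnorm(length(u), sd = coef * u))
}
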