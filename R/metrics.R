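#' Horizontal-to-vertical axis ratio of a drawn path
#'
#' Ratio of the horizontal extent (max - min of x) to the vertical extent
#' of a closed hand path; 1 for a perfect circle, below 1 for a vertically
#' elongated one. Invariant to rotation by construction only for the
#' extents, which is the convention used for circular-path distortion.
#'
#' @param path matrix of hand positions (>= 8 rows).
#' @return scalar ratio.
#' @export
axis_ratio <- function(path) {
  path <- as.matrix(path)
  if (nrow(path) < 8) stop("need at least 8 path points")
  ext <- apply(path, 2, function(z) diff(range(z)))
  if (any(ext < 1e-9)) stop("degenerate path: zero extent")
  ext[1] / ext[2]
}

#' Correlation between velocity time series
#'
#' Pearson correlation of the concatenated 2-D hand velocity series of a
#' trial against a template (typically the null-field movement in the same
#' direction). Series of different lengths are linearly resampled to the
#' template grid. Returns NA if either series has zero variance.
#'
#' @param vel T x 2 velocity matrix of the trial.
#' @param template_vel T0 x 2 velocity matrix of the template.
#' @return scalar correlation, or NA.
#' @export
velocity_correlation <- function(vel, template_vel) {
  vel <- as.matrix(vel); template_vel <- as.matrix(template_vel)
  n0 <- nrow(template_vel)
  if (nrow(vel) != n0) {
    tt <- seq(0, 1, length.out = nrow(vel))
    t0 <- seq(0, 1, length.out = n0)
    vel <- cbind(stats::approx(tt, vel[, 1], t0)$y,
                 stats::approx(tt, vel[, 2], t0)$y)
  }
  a <- c(vel[, 1], vel[, 2])
  b <- c(template_vel[, 1], template_vel[, 2])
  if (stats::sd(a) < 1e-12 || stats::sd(b) < 1e-12) return(NA_real_)
  stats::cor(a, b)
}

#' Trailing moving average
#'
#' Each element is the mean of the trailing window (shorter at the start),
#' the smoothing used for trial-by-trial learning curves.
#'
#' @param x numeric vector (NAs are dropped within windows).
#' @param window window length in trials.
#' @return smoothed vector of the same length.
#' @export
moving_average <- function(x, window = 20) {
  vapply(seq_along(x), function(i) {
    w <- x[max(1, i - window + 1):i]
    mean(w, na.rm = TRUE)
  }, 0)
}

#' Endpoint stiffness ellipse from muscle activation
#'
#' Analytic endpoint stiffness at a posture: the intrinsic muscle
#' stiffness, which increases with activation, plus the stiffness
#' equivalent of the V-shaped feedback pathway, both mapped through the
#' moment arms and the hand Jacobian:
#' \deqn{K_j = A \, diag(k(u) + c(u) \, \bar s) \, A^T, \qquad
#'       K_e = J^{-T} K_j J^{-1}}
#' with \eqn{k(u) = k_0 + k_1 u}, pathway coefficient
#' \eqn{c(u) = T_0 + \rho (k_0 + 2 k_1 u)} (tension gained per unit of
#' reflexive activation when the muscle rests at its activation-set
#' equilibrium length) and effective feedback slope
#' \eqn{\bar s = (a_+ - a_-)/2}, the restoring part of the V-shape under
#' symmetric probing.
#'
#' @param u muscle activations (length 6, >= 0).
#' @param q posture (rad).
#' @param cfg model configuration.
#' @param include_feedback include the feedback-pathway term.
#' @return object of class \code{stiffness_ellipse}: \code{K} (2x2, N/m),
#'   eigenvalues, \code{orientation} (degrees of the major axis, in
#'   (-90, 90]), \code{area} (N^2/m^2 ellipse area of the unit-displacement
#'   image).
#' @export
endpoint_stiffness <- function(u, q, cfg, include_feedback = TRUE) {
  if (any(u < 0)) stop("activations must be non-negative")
  A <- cfg$geometry$A
  m <- cfg$muscle
  k_u <- m$k0 + m$k1 * u
  slope <- if (include_feedback) {
    c_u <- m$T0 + m$rho * (m$k0 + 2 * m$k1 * u)
    (cfg$gains$stretch_slope - cfg$gains$shorten_slope) / 2 * c_u
  } else 0
  Kj <- A %*% diag(k_u + slope) %*% t(A)
  J <- jacobian(q, cfg$arm)
  if (abs(det(J)) < 1e-8) stop("singular Jacobian at this posture")
  Ji <- solve(J)
  Ke <- t(Ji) %*% Kj %*% Ji
  Ks <- (Ke + t(Ke)) / 2
  eg <- eigen(Ks, symmetric = TRUE)
  ang <- atan2(eg$vectors[2, 1], eg$vectors[1, 1]) * 180 / pi
  if (ang <= -90) ang <- ang + 180
  if (ang > 90) ang <- ang - 180
  structure(list(K = Ke, eigenvalues = eg$values, orientation = ang,
                 area = pi * prod(abs(eg$values))),
            class = "stiffness_ellipse")
}

#' @export
print.stiffness_ellipse <- function(x, ...) {
  cat(sprintf("endpoint stiffness: eigenvalues %.0f / %.0f N/m, major axis %.1f deg\n",
              x$eigenvalues[1], x$eigenvalues[2], x$orientation))
  invisible(x)
}
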