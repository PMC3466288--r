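#' Force-field specifications
#'
#' Environments applied at the hand during trials.
#' \describe{
#'   \item{NF}{null field, zero force.}
#'   \item{VF}{velocity-dependent field \code{F = B \%*\% v} with a 2x2 gain
#'     matrix (N s/m), typically a curl field.}
#'   \item{VFk}{direction-variant velocity field: a curl gain modulated by
#'     \code{sin(k * theta)} of the movement direction \code{theta}, spatial
#'     frequency k in \{1, 2, 4\}; reduces to a direction-independent field
#'     as the modulation amplitude goes to 0.}
#'   \item{DF}{position-dependent divergent field: force normal to the
#'     start-goal line, proportional to the lateral deviation p (pushing
#'     away from the line), zero inside the start/end circles; beyond the
#'     barrier threshold the negative stiffness is replaced by damping of
#'     the lateral velocity (safety barrier).}
#' }
#'
#' @param variant one of "NF", "VF", "VFk", "DF".
#' @param B 2x2 gain matrix (N s/m) for VF.
#' @param amplitude curl-gain amplitude (N s/m) for VFk.
#' @param k spatial frequency for VFk, one of 1, 2, 4.
#' @param direction movement direction angle (rad) for VFk (the planned
#'   target direction, constant within a trial).
#' @param gain lateral stiffness (N/m) for DF.
#' @param start,goal start and goal hand positions (m) for DF.
#' @param barrier lateral deviation (m) beyond which the safety barrier
#'   engages (default 0.05).
#' @param barrier_damping damping of the lateral hand velocity inside the
#'   barrier (N s/m).
#' @param circle_diameter diameter (m) of the start/end circles inside
#'   which DF applies no force.
#' @return An object of class \code{force_field}.
#' @export
force_field <- function(variant = c("NF", "VF", "VFk", "DF"),
                        B = NULL, amplitude = NULL, k = NULL, direction = NULL,
                        gain = NULL, start = NULL, goal = NULL,
                        barrier = 0.05, barrier_damping = 50,
                        circle_diameter = 0.025) {
  variant <- match.arg(variant)
  spec <- list(variant = variant)
  if (variant == "VF") {
    B <- as.matrix(B)
    stopifnot(all(dim(B) == c(2, 2)), all(is.finite(B)))
    spec$B <- B
  } else if (variant == "VFk") {
    if (is.null(k) || !(k %in% c(1, 2, 4))) stop("k must be one of {1, 2, 4}")
    stopifnot(is.numeric(amplitude), is.numeric(direction))
    spec$amplitude <- amplitude; spec$k <- k; spec$direction <- direction
  } else if (variant == "DF") {
    stopifnot(is.numeric(gain), length(start) == 2, length(goal) == 2)
    if (barrier <= 0) stop("barrier threshold must be positive")
    spec$gain <- gain; spec$start <- start; spec$goal <- goal
    spec$barrier <- barrier; spec$barrier_damping <- barrier_damping
    spec$circle_radius <- circle_diameter / 2
    d <- goal - start
    spec$axis <- d / sqrt(sum(d^2))
  }
  structure(spec, class = "force_field")
}

#' @export
print.force_field <- function(x, ...) {
  cat("force field:", x$variant, "\n")
  if (x$variant == "VF") {
    cat("  B (N s/m):", paste(format(x$B), collapse = " "), "\n")
  } else if (x$variant == "VFk") {
    cat(sprintf("  curl gain %.1f * sin(%d * theta) N s/m, theta = %.3f rad\n",
                x$amplitude, x$k, x$direction))
  } else if (x$variant == "DF") {
    cat(sprintf("  lateral stiffness %.0f N/m, barrier at %.3f m (damping %.0f N s/m)\n",
                x$gain, x$barrier, x$barrier_damping))
  }
  invisible(x)
}

#' Velocity-dependent field force
#'
#' @param v hand velocity (m/s), length 2.
#' @param B 2x2 gain matrix (N s/m).
#' @return endpoint force (N).
#' @export
vf_force <- function(v, B) {
  if (!all(is.finite(v))) stop("non-finite hand velocity")
  drop(B %*% v)
}

#' Direction-variant velocity field force
#'
#' Curl field whose gain is modulated at spatial frequency k of the planned
#' movement direction: \code{F = amplitude * sin(k * theta) * R90 \%*\% v},
#' with \code{R90} the 90-degree rotation. The gain pattern is
#' \code{2*pi/k}-periodic in direction.
#'
#' @param v hand velocity (m/s).
#' @param direction planned movement direction angle (rad).
#' @param k spatial frequency, one of 1, 2, 4.
#' @param amplitude gain amplitude (N s/m).
#' @return endpoint force (N).
#' @export
vfk_force <- function(v, direction, k, amplitude = 13) {
  if (!(k %in% c(1, 2, 4))) stop("k must be one of {1, 2, 4}")
  g <- amplitude * sin(k * direction)
  g * c(-v[2], v[1])
}

#' Divergent-field force
#'
#' @param p hand position (m), length 2.
#' @param v hand velocity (m/s), length 2 (used inside the safety barrier).
#' @param spec DF \code{\link{force_field}}.
#' @return endpoint force (N).
#' @export
df_force <- function(p, v = c(0, 0), spec) {
  if (spec$variant != "DF") stop("spec is not a divergent field")
  if (sqrt(sum((p - spec$start)^2)) <= spec$circle_radius ||
      sqrt(sum((p - spec$goal)^2)) <= spec$circle_radius) {
    return(c(0, 0))
  }
  u <- spec$axis
  n <- c(-u[2], u[1])                     # left normal: positive p to the left
  lat <- sum((p - spec$start) * n)
  if (abs(lat) > spec$barrier) {
    v_lat <- sum(v * n)
    return(-spec$barrier_damping * v_lat * n)
  }
  spec$gain * lat * n
}

#' Evaluate any field at a hand state
#'
#' @param spec \code{\link{force_field}}.
#' @param p hand position (m).
#' @param v hand velocity (m/s).
#' @return endpoint force (N), length 2.
#' @export
field_force <- function(spec, p, v) {
  switch(spec$variant,
         NF = c(0, 0),
         VF = vf_force(v, spec$B),
         VFk = vfk_force(v, spec$direction, spec$k, spec$amplitude),
         DF = df_force(p, v, spec))
}
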