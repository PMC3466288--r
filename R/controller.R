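#' Minimum-jerk point-to-point trajectory
#'
#' Fifth-order polynomial hand trajectory with zero velocity and
#' acceleration at both ends.
#'
#' @param start,goal hand positions (m), length 2.
#' @param duration movement duration (s).
#' @param t evaluation times (s) in \code{[0, duration]}.
#' @return list with \code{pos} and \code{vel}, each \code{length(t)} x 2.
#' @export
minimum_jerk <- function(start, goal, duration, t) {
  if (any(t < -1e-12) || any(t > duration + 1e-12)) {
    stop("evaluation times must lie within [0, duration]")
  }
  tau <- pmin(pmax(t / duration, 0), 1)
  s <- 10 * tau^3 - 15 * tau^4 + 6 * tau^5
  sd <- (30 * tau^2 - 60 * tau^3 + 30 * tau^4) / duration
  d <- goal - start
  list(pos = cbind(start[1] + d[1] * s, start[2] + d[2] * s),
       vel = cbind(d[1] * sd, d[2] * sd))
}

#' Build a reference plan from a hand trajectory
#'
#' Converts a sampled hand path to joint space by inverse kinematics and
#' differentiates through the Jacobian, producing the reference joint
#' trajectory from which reference muscle lengths are derived each step.
#'
#' @param pos,vel hand positions and velocities (T x 2 matrices, m and m/s).
#' @param dt sample interval (s).
#' @param arm \code{\link{arm_parameters}}.
#' @param kind plan label.
#' @return An object of class \code{reference_plan}: time grid, hand and
#'   joint reference trajectories.
#' @keywords internal
make_plan <- function(pos, vel, dt, arm, kind = "custom") {
  n <- nrow(pos)
  q <- matrix(0, n, 2)
  qdot <- matrix(0, n, 2)
  for (i in seq_len(n)) {
    q[i, ] <- inverse_kinematics(pos[i, ], arm)
    qdot[i, ] <- drop(solve(jacobian(q[i, ], arm), vel[i, ]))
  }
  structure(list(kind = kind, dt = dt, time = (seq_len(n) - 1) * dt,
                 pos = pos, vel = vel, q = q, qdot = qdot),
            class = "reference_plan")
}

#' Point-to-point minimum-jerk reference plan
#'
#' @param start,goal hand positions (m).
#' @param duration movement duration (s).
#' @param dt time step (s).
#' @param arm \code{\link{arm_parameters}}.
#' @param hold extra time (s) appended with the reference clamped at the
#'   goal, letting the controller stabilise the endpoint.
#' @return \code{reference_plan}.
#' @export
reach_plan <- function(start, goal, duration, dt, arm, hold = 0.15) {
  t_move <- seq(0, duration, by = dt)
  mj <- minimum_jerk(start, goal, duration, t_move)
  n_hold <- round(hold / dt)
  pos <- rbind(mj$pos, matrix(rep(goal, each = n_hold), n_hold, 2))
  vel <- rbind(mj$vel, matrix(0, n_hold, 2))
  p <- make_plan(pos, vel, dt, arm, kind = "reach")
  p$start <- start; p$goal <- goal; p$duration <- duration
  p$measure_idx <- seq_along(t_move)
  p
}

#' Circular reference plan
#'
#' One full counter-clockwise lap starting at the rightmost point of the
#' circle. With the default \code{"minjerk"} profile the angular progress
#' follows the fifth-order minimum-jerk time course, so the movement
#' starts and ends at rest like the reaching movements and sweeps through
#' the same range of speeds; with \code{"constant"} the lap is traversed
#' at constant hand speed \code{2*pi*radius/duration} and an optional
#' lead-in arc precedes the measured lap (to exclude the start-up
#' transient of a movement that begins mid-draw). The indices of the
#' measured lap are stored in \code{measure_idx}.
#'
#' @param center circle center (m), length 2.
#' @param radius circle radius (m), > 0.
#' @param duration lap duration (s).
#' @param dt time step (s).
#' @param arm \code{\link{arm_parameters}}.
#' @param profile angular speed profile, \code{"minjerk"} or
#'   \code{"constant"}.
#' @param lead_in duration (s) of the lead-in arc (constant profile only).
#' @param hold extra time (s) appended at rest at the end (min-jerk
#'   profile only).
#' @return \code{reference_plan}.
#' @export
circle_plan <- function(center, radius, duration, dt, arm,
                        profile = c("minjerk", "constant"), lead_in = 0.1,
                        hold = 0.1) {
  if (radius <= 0) stop("circle radius must be positive")
  profile <- match.arg(profile)
  if (profile == "minjerk") {
    t <- seq(0, duration, by = dt)
    tau <- t / duration
    sfrac <- 10 * tau^3 - 15 * tau^4 + 6 * tau^5
    sdot <- (30 * tau^2 - 60 * tau^3 + 30 * tau^4) / duration
    n_hold <- round(hold / dt)
    th <- c(2 * pi * sfrac, rep(2 * pi, n_hold))
    om <- c(2 * pi * sdot, rep(0, n_hold))
    measure <- seq_along(th)
  } else {
    t <- seq(-lead_in, duration, by = dt)
    th <- 2 * pi * t / duration
    om <- rep(2 * pi / duration, length(th))
    measure <- which(t >= 0)
  }
  pos <- cbind(center[1] + radius * cos(th), center[2] + radius * sin(th))
  vel <- cbind(-radius * om * sin(th), radius * om * cos(th))
  # reachability of the whole path is enforced by inverse kinematics below
  p <- make_plan(pos, vel, dt, arm, kind = "circle")
  p$center <- center; p$radius <- radius; p$duration <- duration
  p$measure_idx <- measure
  p
}

#' Reference muscle lengths along a plan
#'
#' @param plan \code{reference_plan}.
#' @param geom \code{\link{muscle_geometry}}.
#' @param t time (s) on the plan grid (matched to the nearest sample).
#' @return list with \code{l_r} and \code{ldot_r}, each length 6.
#' @export
reference_muscle_lengths <- function(plan, geom, t) {
  i <- round(t / plan$dt) + 1
  if (i < 1 || i > length(plan$time)) stop("time outside the plan")
  ml <- muscle_lengths(arm_state(plan$q[i, ], plan$qdot[i, ], t), geom)
  list(l_r = ml$l, ldot_r = ml$ldot)
}

#' V-shape feedback gains
#'
#' Slopes of the piecewise-linear feedback response to the delayed sliding
#' error: muscle stretch and shortening both increase activation, stretch
#' with the larger slope.
#'
#' @param stretch_slope activation per m of positive (stretch) error.
#' @param shorten_slope activation per m of negative (shortening) error.
#' @param kappa velocity weighting in the sliding error (s).
#' @param delay neural feedback delay (s), in \code{[0, 0.2]}.
#' @return An object of class \code{vshape_gains}.
#' @export
vshape_gains <- function(stretch_slope = 30, shorten_slope = 15,
                         kappa = 0.05, delay = 0.06) {
  if (!(stretch_slope >= shorten_slope && shorten_slope > 0)) {
    stop("require stretch_slope >= shorten_slope > 0")
  }
  if (kappa < 0 || delay < 0 || delay > 0.2) {
    stop("kappa must be >= 0 and delay within [0, 0.2] s")
  }
  structure(list(stretch_slope = stretch_slope, shorten_slope = shorten_slope,
                 kappa = kappa, delay = delay), class = "vshape_gains")
}

#' Split a signed error into positive and negative parts
#'
#' @param eps signed error vector.
#' @return list with \code{pos} (>= 0) and \code{neg} (<= 0);
#'   \code{pos + neg == eps} componentwise.
#' @export
split_error <- function(eps) {
  list(pos = pmax(eps, 0), neg = pmin(eps, 0))
}

#' Delayed sliding error
#'
#' \eqn{\epsilon(t) = e(t-\delta) + \kappa \dot e(t-\delta)}: the muscle
#' length error and its rate, sampled one feedback delay in the past. Before
#' the delay has elapsed no feedback information is available and the error
#' is zero.
#'
#' @param e_history matrix (steps so far x muscles) of length errors (m).
#' @param edot_history matching matrix of error rates (m/s).
#' @param kappa velocity weighting (s).
#' @param delay feedback delay (s).
#' @param t current time (s); row \code{round(t/dt)+1} is "now".
#' @param dt time step (s).
#' @return sliding error, length = number of muscles.
#' @export
sliding_error <- function(e_history, edot_history, kappa, delay, t, dt) {
  if (is.null(dim(e_history)) || nrow(e_history) == 0) {
    stop("empty error history")
  }
  i_del <- round((t - delay) / dt) + 1
  if (i_del < 1) return(rep(0, ncol(e_history)))
  if (i_del > nrow(e_history)) stop("history does not cover t - delay")
  e_history[i_del, ] + kappa * edot_history[i_del, ]
}

#' V-shaped feedback command
#'
#' Piecewise-linear, non-negative activation increasing with both stretch
#' and shortening of each muscle, with the larger slope on the stretch side;
#' zero exactly at zero error.
#'
#' @param eps sliding error (m), length 6 (signed).
#' @param gains \code{\link{vshape_gains}}.
#' @return feedback activations, >= 0.
#' @export
vshape_feedback <- function(eps, gains) {
  parts <- split_error(eps)
  gains$stretch_slope * parts$pos - gains$shorten_slope * parts$neg
}

#' Compose the motor command
#'
#' Total activation = rectified feedforward + feedback. Both contributions
#' are non-negative because muscles only pull.
#'
#' @param u_ff feedforward activations (rectified at 0).
#' @param u_fb feedback activations (>= 0).
#' @return total activation vector.
#' @export
compose_command <- function(u_ff, u_fb) {
  if (any(u_fb < -1e-12)) stop("feedback command must be non-negative")
  pmax(u_ff, 0) + pmax(u_fb, 0)
}
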