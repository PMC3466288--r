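#' Learning configuration
#'
#' Parameters of the trial-by-trial gradient-descent update of the
#' feedforward activation parameters. The update accumulates the V-shaped
#' error drive over a trial and subtracts a decay that removes superfluous
#' (co-)activation:
#' \deqn{\Delta w = \eta Q \, dt \sum_t \Phi(x_t)^T v(\epsilon(t+\delta))
#'       - \gamma \, d(w), \qquad w \leftarrow \max(0, w + \Delta w)}
#' where \eqn{v(\epsilon) = a_+ \epsilon^+ - a_- \epsilon^-} is the V-shaped
#' drive (non-negative on both sides, steeper for stretch) and the error is
#' shifted forward by the feedback delay so that basis activations are
#' paired with the error they could have prevented. With uniform decay
#' (\code{d(w) = 1}) weakly supported parameters reach zero first
#' (winner-take-all); a proportional variant (\code{d(w) = w}) is provided
#' for sensitivity studies.
#'
#' @param eta learning rate (>= 0).
#' @param Q error-cost weight.
#' @param R activation-cost weight.
#' @param gamma decay per trial (default \code{eta * R}, which makes the
#'   update the exact negative gradient of the error-effort objective).
#' @param stretch_slope,shorten_slope V-shape slopes of the learning drive
#'   (activation per m); default to the feedback values.
#' @param decay \code{"uniform"} or \code{"proportional"}.
#' @return An object of class \code{learning_config}.
#' @export
learning_config <- function(eta = 2, Q = 1, R = 0.001,
                            gamma = eta * R,
                            stretch_slope = 30, shorten_slope = 15,
                            decay = c("uniform", "proportional")) {
  decay <- match.arg(decay)
  if (any(c(eta, Q, R, gamma) < 0)) stop("eta, Q, R, gamma must be >= 0")
  if (!(stretch_slope >= shorten_slope && shorten_slope > 0)) {
    stop("require stretch_slope >= shorten_slope > 0")
  }
  structure(list(eta = eta, Q = Q, R = R, gamma = gamma,
                 stretch_slope = stretch_slope,
                 shorten_slope = shorten_slope, decay = decay),
            class = "learning_config")
}

#' V-shaped learning drive
#'
#' @param eps signed sliding error (vector or matrix).
#' @param cfg \code{\link{learning_config}}.
#' @return non-negative drive of the same shape.
#' @export
vshape_drive <- function(eps, cfg) {
  cfg$stretch_slope * pmax(eps, 0) - cfg$shorten_slope * pmin(eps, 0)
}

#' Asymmetric error potential
#'
#' The per-muscle potential whose slope is the V-shaped drive:
#' \eqn{h(\epsilon) = a_+ (\epsilon^+)^2/2 - a_- (\epsilon^-)^2/2}.
#' Because feedforward activation of a muscle shortens it, descending this
#' potential both opposes systematic error and raises co-activation in
#' response to deviations of either sign.
#'
#' @inheritParams vshape_drive
#' @return potential values, same shape as \code{eps}.
#' @export
error_potential <- function(eps, cfg) {
  cfg$stretch_slope * pmax(eps, 0)^2 / 2 - cfg$shorten_slope * pmin(eps, 0)^2 / 2
}

#' Trial cost of error and effort
#'
#' \eqn{J = Q \, dt \sum_t \sum_i h(\epsilon_i(t)) + R \, dt \sum_t \sum_i
#' u^{ff}_i(t)}: the integrated error potential plus the integrated
#' feedforward activation (effort scales linearly with the command).
#'
#' @param eps_traj T x muscles matrix of sliding errors.
#' @param u_ff_traj T x muscles matrix of feedforward activations.
#' @param cfg \code{\link{learning_config}}.
#' @param dt time step (s).
#' @return scalar cost.
#' @export
cost <- function(eps_traj, u_ff_traj, cfg, dt = 0.001) {
  eps_traj <- rbind(eps_traj); u_ff_traj <- rbind(u_ff_traj)
  if (!all(dim(eps_traj) == dim(u_ff_traj))) {
    stop("error and activation trajectories must have matching dimensions")
  }
  cfg$Q * dt * sum(error_potential(eps_traj, cfg)) +
    cfg$R * dt * sum(u_ff_traj)
}

#' Generic linear-in-parameters primitive model
#'
#' A feedforward model \code{u_ff(x) = pmax(0, Phi(x) \%*\% w)} with
#' non-negative parameters, covering neural networks, force-field
#' primitives or muscle synergies.
#'
#' @param Phi function mapping a state to a (muscles x parameters) matrix
#'   with finite entries.
#' @param w initial parameter vector (>= 0).
#' @return An object of class \code{primitive_model} with fields
#'   \code{Phi}, \code{w} and trial counter \code{k}.
#' @export
primitive_model <- function(Phi, w) {
  if (any(w < 0)) stop("parameters must be non-negative")
  structure(list(Phi = Phi, w = as.numeric(w), k = 0L),
            class = "primitive_model")
}

#' One between-trial gradient update
#'
#' Applies the learning law to a primitive model given the trial's
#' delay-compensated sliding errors and visited states: the accumulated
#' V-shaped error drive projected through the basis, minus decay, clipped
#' at zero.
#'
#' @param model \code{\link{primitive_model}}.
#' @param eps_traj T x muscles matrix of sliding errors, already shifted
#'   forward by the feedback delay (row t aligned with \code{states[t]}).
#' @param states list (or matrix of rows) of the states visited.
#' @param cfg \code{\link{learning_config}}.
#' @param dt time step (s).
#' @return the updated model, with the update decomposition (reciprocal,
#'   co-activation, decay; summing exactly to the pre-clip update) in
#'   attribute \code{"decomposition"}.
#' @export
gradient_update <- function(model, eps_traj, states, cfg, dt = 0.001) {
  eps_traj <- rbind(eps_traj)
  if (anyNA(eps_traj)) {
    warning("NaN in the error trajectory: trial discarded, no update")
    return(model)
  }
  if (is.matrix(states)) states <- lapply(seq_len(nrow(states)), function(i) states[i, ])
  if (length(states) != nrow(eps_traj)) {
    stop("states and error trajectory must be aligned")
  }
  P <- length(model$w)
  grad <- numeric(P); recip <- numeric(P); coact <- numeric(P)
  s_rec <- (cfg$stretch_slope - cfg$shorten_slope) / 2
  s_co <- (cfg$stretch_slope + cfg$shorten_slope) / 2
  for (t in seq_along(states)) {
    Phi_t <- model$Phi(states[[t]])
    eps <- eps_traj[t, ]
    grad <- grad + drop(crossprod(Phi_t, vshape_drive(eps, cfg)))
    recip <- recip + drop(crossprod(Phi_t, s_rec * eps))
    coact <- coact + drop(crossprod(Phi_t, s_co * abs(eps)))
  }
  scale <- cfg$eta * cfg$Q * dt
  dec <- if (cfg$decay == "uniform") rep(cfg$gamma, P) else cfg$gamma * model$w
  delta <- scale * grad - dec
  model$w <- pmax(0, model$w + delta)
  model$k <- model$k + 1L
  attr(model, "decomposition") <- list(reciprocal = scale * recip,
                                       coactivation = scale * coact,
                                       decay = -dec, delta = delta)
  model
}

#' Decompose an update into reciprocal, co-activation and decay terms
#'
#' The V-shaped drive splits exactly as
#' \eqn{v(\epsilon) = \frac{a_+ - a_-}{2}\epsilon +
#' \frac{a_+ + a_-}{2}|\epsilon|}: a signed term opposing systematic error
#' (reciprocal activation), a non-negative term raising co-activation in
#' response to deviation of either sign, plus the decay. The three terms
#' sum to the applied (pre-clip) update.
#'
#' @param eps_pos,eps_neg T x muscles matrices of the positive and negative
#'   error parts.
#' @param Phi_list list of per-step design matrices.
#' @param cfg \code{\link{learning_config}}.
#' @param w current parameters (needed for proportional decay).
#' @param dt time step (s).
#' @return list with \code{reciprocal}, \code{coactivation}, \code{decay},
#'   and their sum \code{delta}.
#' @export
decompose_update <- function(eps_pos, eps_neg, Phi_list, cfg, w, dt = 0.001) {
  eps_pos <- rbind(eps_pos); eps_neg <- rbind(eps_neg)
  stopifnot(all(dim(eps_pos) == dim(eps_neg)),
            length(Phi_list) == nrow(eps_pos))
  P <- length(w)
  recip <- numeric(P); coact <- numeric(P)
  s_rec <- (cfg$stretch_slope - cfg$shorten_slope) / 2
  s_co <- (cfg$stretch_slope + cfg$shorten_slope) / 2
  for (t in seq_along(Phi_list)) {
    eps <- eps_pos[t, ] + eps_neg[t, ]
    recip <- recip + drop(crossprod(Phi_list[[t]], s_rec * eps))
    coact <- coact + drop(crossprod(Phi_list[[t]], s_co * abs(eps)))
  }
  scale <- cfg$eta * cfg$Q * dt
  dec <- if (cfg$decay == "uniform") rep(cfg$gamma, P) else cfg$gamma * w
  list(reciprocal = scale * recip, coactivation = scale * coact,
       decay = -dec, delta = scale * (recip + coact) - dec)
}
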