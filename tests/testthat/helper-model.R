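# Shared fixtures: a fast configuration and tiny networks built in code.

fast_cfg <- function(...) {
  cfg <- default_config()
  mods <- list(...)
  for (nm in names(mods)) {
    cfg[[nm]][names(mods[[nm]])] <- mods[[nm]]
  }
  cfg
}

# a small hand-built network covering the workspace around the default
# reference posture, for tests that need a working feedforward map
toy_network <- function(N = 5, W = NULL, width = 1) {
  set.seed(42)
  centers <- matrix(stats::rnorm(N * 4, sd = 0.5), N, 4)
  rbf_network(centers, matrix(width, N, 4),
              scaling = list(center = c(0.9, 1.5, 0, 0), sd = rep(1, 4)),
              W = W)
}

# RK4 integration of the passive rigid-body arm (no muscles) used by the
# energy-conservation checks
integrate_passive <- function(q0, qd0, arm, dt, n_steps, tau = c(0, 0)) {
  q <- q0; qd <- qd0
  deriv <- function(q, qd) forward_dynamics(arm_state(q, qd), tau, c(0, 0), arm)
  for (i in seq_len(n_steps)) {
    k1v <- deriv(q, qd)
    k2q <- qd + dt / 2 * k1v
    k2v <- deriv(q + dt / 2 * qd, qd + dt / 2 * k1v)
    k3q <- qd + dt / 2 * k2v
    k3v <- deriv(q + dt / 2 * k2q, qd + dt / 2 * k2v)
    k4q <- qd + dt * k3v
    k4v <- deriv(q + dt * k3q, qd + dt * k3v)
    q <- q + dt / 6 * (qd + 2 * k2q + 2 * k3q + k4q)
    qd <- qd + dt / 6 * (k1v + 2 * k2v + 2 * k3v + k4v)
  }
  list(q = q, qd = qd)
}
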