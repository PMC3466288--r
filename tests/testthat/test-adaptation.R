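test_that("trial cost is zero at rest and scales linearly in effort", {
  cfg <- learning_config()
  Tn <- 50
  expect_equal(cost(matrix(0, Tn, 6), matrix(0, Tn, 6), cfg), 0)
  set.seed(9)
  eps <- matrix(rnorm(Tn * 6, sd = 0.01), Tn, 6)
  uff <- matrix(abs(rnorm(Tn * 6, sd = 0.2)), Tn, 6)
  j1 <- cost(eps, uff, cfg)
  j2 <- cost(eps, 3 * uff, cfg)
  # effort term is linear in the command: scaling u by 3 adds 2x the effort
  effort <- cfg$R * 0.001 * sum(uff)
  expect_equal(j2 - j1, 2 * effort, tolerance = 1e-12)
  # naive per-sample re-implementation of the documented functional
  j_naive <- 0
  for (t in seq_len(Tn)) for (i in 1:6) {
    e <- eps[t, i]
    h <- if (e > 0) cfg$stretch_slope * e^2 / 2 else -cfg$shorten_slope * e^2 / 2
    j_naive <- j_naive + cfg$Q * 0.001 * h + cfg$R * 0.001 * uff[t, i]
  }
  expect_equal(j1, j_naive, tolerance = 1e-8)
  expect_error(cost(eps, uff[1:10, ]), "matching")
})

test_that("the update law is gradient descent on the error-effort objective", {
  # toy model: 3 parameters, 2 time steps, linear error surrogate
  set.seed(12)
  Phi_mat <- matrix(abs(rnorm(18)), 6, 3)
  eps0 <- matrix(rnorm(12, sd = 0.02), 2, 6)
  w0 <- c(0.5, 0.3, 0.8)
  cfg <- learning_config(eta = 0.5, Q = 1, R = 0.01)
  dt <- 0.001
  states <- list(1, 2)  # states only index the (constant) design matrix here
  Phi_fun <- function(x) Phi_mat

  eps_of_w <- function(w) eps0 - matrix(rep(drop(Phi_mat %*% w), 2), 2, 6,
                                        byrow = TRUE)
  J <- function(w) {
    cfg$Q * dt * sum(error_potential(eps_of_w(w), cfg)) +
      (cfg$gamma / cfg$eta) * sum(w)
  }
  model <- primitive_model(Phi_fun, w0)
  upd <- gradient_update(model, eps_of_w(w0), states, cfg, dt)
  delta <- attr(upd, "decomposition")$delta
  h <- 1e-6
  grad_num <- vapply(1:3, function(k) {
    dw <- numeric(3); dw[k] <- h
    (J(w0 + dw) - J(w0 - dw)) / (2 * h)
  }, 0)
  expect_equal(delta, -cfg$eta * grad_num, tolerance = 1e-4)
})

test_that("with zero error the update is pure decay toward zero", {
  Phi_fun <- function(x) diag(6)[, 1:3]
  cfg <- learning_config(eta = 1, gamma = 0.05)
  model <- primitive_model(Phi_fun, c(0.2, 0.04, 0.5))
  m1 <- gradient_update(model, matrix(0, 10, 6), as.list(1:10), cfg)
  expect_equal(m1$w, c(0.15, 0, 0.45))
  # repeated decay shrinks the norm monotonically to zero
  norms <- numeric(12)
  m <- model
  for (i in 1:12) {
    m <- gradient_update(m, matrix(0, 10, 6), as.list(1:10), cfg)
    norms[i] <- sqrt(sum(m$w^2))
  }
  expect_true(all(diff(norms) <= 0))
  expect_equal(m$w, rep(0, 3))
})

test_that("a single-step identity-basis update is proportional to the V drive", {
  cfg <- learning_config(eta = 2, Q = 1, R = 0, gamma = 0)
  Phi_fun <- function(x) diag(6)
  model <- primitive_model(Phi_fun, rep(0.1, 6))
  eps <- matrix(c(0.01, -0.01, 0.002, -0.002, 0, 0.005), 1, 6)
  m1 <- gradient_update(model, eps, list(1), cfg, dt = 0.001)
  expect_equal(m1$w - model$w,
               2 * 0.001 * drop(vshape_drive(eps, cfg)), tolerance = 1e-12)
})

test_that("update decomposition sums exactly to the applied update", {
  set.seed(13)
  cfg <- learning_config(eta = 1.3, gamma = 0.003)
  for (rep in 1:20) {
    P <- sample(2:5, 1)
    Tn <- sample(3:8, 1)
    Phi_list <- replicate(Tn, matrix(abs(rnorm(6 * P)), 6, P),
                          simplify = FALSE)
    eps <- matrix(rnorm(Tn * 6, sd = 0.01), Tn, 6)
    parts <- split_error(eps)
    w <- abs(rnorm(P))
    dec <- decompose_update(parts$pos, parts$neg, Phi_list, cfg, w)
    expect_equal(dec$reciprocal + dec$coactivation + dec$decay, dec$delta,
                 tolerance = 1e-14)
    # cross-check against the gradient_update path
    k <- 0
    Phi_fun <- function(x) Phi_list[[x]]
    model <- primitive_model(Phi_fun, w)
    upd <- gradient_update(model, eps, as.list(seq_len(Tn)), cfg)
    expect_equal(attr(upd, "decomposition")$delta, dec$delta,
                 tolerance = 1e-12)
  }
})

test_that("weights stay non-negative over many random updates", {
  set.seed(14)
  cfg <- learning_config(eta = 5, gamma = 0.05)
  Phi_fun <- function(x) matrix(abs(rnorm(18)), 6, 3)
  model <- primitive_model(Phi_fun, abs(rnorm(3)))
  ok <- TRUE
  for (i in 1:10000) {
    eps <- matrix(rnorm(6, sd = 0.02), 1, 6)
    model <- gradient_update(model, eps, list(1), cfg)
    if (any(model$w < 0)) { ok <- FALSE; break }
  }
  expect_true(ok)
})

test_that("uniform decay extinguishes the weaker parameter first", {
  cfg <- learning_config(eta = 1, Q = 1, gamma = 0.1)
  Phi_fun <- function(x) matrix(c(1, 0, 0, 0, 0, 0,
                                  0, 1, 0, 0, 0, 0), 6, 2)
  model <- primitive_model(Phi_fun, c(0.3, 0.3))
  # parameter 1 receives a far stronger error-driven increment than the
  # decay removes; parameter 2 a weaker one
  eps <- matrix(0, 1, 6); eps[1, 1] <- 0.018; eps[1, 2] <- 0.002
  died_at <- c(NA, NA)
  for (k in 1:200) {
    model <- gradient_update(model, eps, list(1), cfg, dt = 1)
    for (j in 1:2) if (is.na(died_at[j]) && model$w[j] == 0) died_at[j] <- k
  }
  expect_false(is.na(died_at[2]))
  expect_true(is.na(died_at[1]) || died_at[1] > died_at[2])
})

test_that("NaN errors discard the trial without an update", {
  cfg <- learning_config()
  model <- primitive_model(function(x) diag(6), rep(0.2, 6))
  eps <- matrix(0.01, 2, 6); eps[2, 3] <- NaN
  expect_warning(m1 <- gradient_update(model, eps, list(1, 2), cfg),
                 "discarded")
  expect_equal(m1$w, model$w)
})

test_that("run_learning with zero trials leaves the model unchanged", {
  cfg <- fast_cfg()
  plan <- reach_plan(c(0, 0.3), c(0, 0.42), 0.3, cfg$simulation$dt, cfg$arm)
  net <- toy_network(W = matrix(0.1, 6, 5))
  fit <- run_learning(list(plan), force_field("NF"), net, cfg, n_trials = 0)
  expect_equal(fit$net$W, net$W)
  expect_equal(fit$n_trials, 0)
})

test_that("continued null-field practice from a converged state stays stable", {
  cfg <- fast_cfg()
  set.seed(31)
  plan <- reach_plan(c(0, 0.30), c(0, 0.42), 0.3, cfg$simulation$dt, cfg$arm)
  net <- select_network(nf_state_data(list(plan), cfg),
                        scale_factor = cfg$network$scale_factor)
  fit1 <- run_learning(list(plan), force_field("NF"), net, cfg,
                       n_trials = 250, schedule = rep(1L, 250))
  w1 <- sqrt(sum(fit1$net$W^2))
  fit2 <- run_learning(list(plan), force_field("NF"), fit1$net, cfg,
                       n_trials = 50, schedule = rep(1L, 50))
  h <- fit2$history
  expect_lt(mean(h$error[41:50]), 2 * mean(h$error[1:10]) + 1e-3)
  expect_lt(sqrt(sum(fit2$net$W^2)), 1.1 * w1)
})

test_that("pure motor noise raises co-activation without systematic error", {
  cfg <- fast_cfg(noise = list(coef = 0.1), learning = list(eta = 4))
  set.seed(17)
  # hold task: the plan is a stationary posture, so all error is noise-driven
  plan <- reach_plan(c(0, 0.35), c(0, 0.35), 0.3, cfg$simulation$dt, cfg$arm,
                     hold = 0.2)
  # wide-field network with baseline tone, so signal-dependent noise is active
  net <- toy_network(N = 5, W = matrix(0.15, 6, 5), width = 3)
  fit <- run_learning(list(plan), force_field("NF"), net, cfg,
                      n_trials = 50, schedule = rep(1L, 50))
  h <- fit$history
  expect_gt(mean(h$coactivation[41:50]), h$coactivation[1])
})
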