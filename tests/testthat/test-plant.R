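test_that("muscle lengths follow the linearized geometry", {
  geom <- muscle_geometry()
  st0 <- arm_state(geom$q_ref)
  ml <- muscle_lengths(st0, geom)
  expect_equal(ml$l, geom$l0)
  expect_equal(ml$ldot, rep(0, 6))

  # +0.1 rad at the shoulder shortens the shoulder flexor by a * dq
  st <- arm_state(geom$q_ref + c(0.1, 0))
  ml <- muscle_lengths(st, geom)
  expect_equal(ml$l[1] - geom$l0[1], -0.04 * 0.1)

  # lengthening velocity of a biarticular muscle under pure shoulder rotation
  geom2 <- muscle_geometry(A = rbind(c(0.04, -0.04, 0, 0, 0.03, -0.03),
                                     c(0, 0, 0.025, -0.025, 0.025, -0.025)))
  st <- arm_state(geom2$q_ref, qdot = c(1, 0))
  ml <- muscle_lengths(st, geom2)
  expect_equal(ml$ldot[5], -0.03)

  expect_error(muscle_lengths(list(q = c(NA, 1), qdot = c(0, 0)), geom),
               "finite")
})

test_that("muscle tension is rectified, elastic, and torque-balanced under co-activation", {
  geom <- muscle_geometry()
  musc <- muscle_parameters()
  # silent muscle at rest produces no tension
  expect_equal(muscle_tension(rep(0, 6), geom$l0, rep(0, 6), geom, musc),
               rep(0, 6))
  # stretch increases tension at fixed activation
  u <- rep(0.2, 6)
  T_rest <- muscle_tension(u, geom$l0, rep(0, 6), geom, musc)
  T_str <- muscle_tension(u, geom$l0 + 0.005, rep(0, 6), geom, musc)
  expect_true(all(T_str > T_rest))
  # uniform co-activation doubles tension but leaves joint torque zero
  # (antagonist moment arms are symmetric by construction)
  for (c_act in c(0.1, 0.2, 0.4)) {
    T_c <- muscle_tension(rep(c_act, 6), geom$l0, rep(0, 6), geom, musc)
    expect_equal(drop(geom$A %*% T_c), c(0, 0), tolerance = 1e-10)
  }
  expect_error(muscle_tension(c(-0.1, rep(0, 5)), geom$l0, rep(0, 6), geom),
               "non-negative")
})

test_that("joint torques are the moment-arm map of tensions", {
  geom <- muscle_geometry()
  expect_equal(joint_torque(rep(0, 6), geom), c(0, 0))
  # equal tensions in a perfectly antagonist pair cancel
  expect_equal(joint_torque(c(10, 10, 0, 0, 0, 0), geom), c(0, 0))
  # unit tension on one monoarticular muscle
  expect_equal(joint_torque(c(1, 0, 0, 0, 0, 0), geom), c(0.04, 0))
  expect_equal(joint_torque(c(0, 0, 1, 0, 0, 0), geom), c(0, 0.025))
  expect_error(joint_torque(c(-1, rep(0, 5)), geom), "pull")
})

test_that("signal-dependent noise scales with activation and is reproducible", {
  expect_equal(signal_dependent_noise(rep(0, 6)), rep(0, 6))
  u <- c(0.3, 0.1, 0.5, 0.2, 0.4, 0.6)
  expect_equal(signal_dependent_noise(u, coef = 0), u)
  set.seed(11)
  a <- signal_dependent_noise(u, coef = 0.1)
  set.seed(11)
  expect_identical(a, signal_dependent_noise(u, coef = 0.1))
  # Monte-Carlo check of the noise law at u = 1, coef = 0.1
  set.seed(5)
  draws <- replicate(2e4, signal_dependent_noise(c(1, 1, 1, 1, 1, 1), 0.1)[1])
  expect_equal(sd(draws), 0.1, tolerance = 0.02)
  expect_true(all(draws >= 0))
})

test_that("forward dynamics matches closed-form limits", {
  arm <- arm_parameters()
  # at rest with no torque, no field, nothing moves
  expect_equal(forward_dynamics(arm_state(c(0.8, 1.5)), c(0, 0), c(0, 0), arm),
               c(0, 0))
  # vanishing distal mass/inertia reduces to a single rigid link
  arm1 <- arm_parameters(m = c(1.4, 1e-9), I = c(0.025, 1e-9),
                         lc = c(0.11, 1e-6), B = matrix(0, 2, 2))
  qdd <- forward_dynamics(arm_state(c(0.8, 1.5)), c(1, 0), c(0, 0), arm1)
  expect_equal(qdd[1], 1 / (0.025 + 1.4 * 0.11^2), tolerance = 1e-4)
})

test_that("passive arm conserves kinetic energy", {
  arm <- arm_parameters(B = matrix(0, 2, 2))
  q0 <- c(0.7, 1.4); qd0 <- c(1.2, -0.8)
  E0 <- kinetic_energy(q0, qd0, arm)
  out <- integrate_passive(q0, qd0, arm, dt = 0.001, n_steps = 1000)
  E1 <- kinetic_energy(out$q, out$qd, arm)
  expect_lt(abs(E1 - E0) / E0, 1e-4)
})

test_that("forward dynamics agrees with a finite-difference Lagrangian oracle", {
  arm <- arm_parameters()
  h <- 1e-6
  set.seed(3)
  for (i in 1:100) {
    q <- c(runif(1, 0.2, 1.4), runif(1, 0.5, 2.2))
    qd <- rnorm(2, sd = 2)
    tau <- rnorm(2, sd = 3)
    # d/dt(dL/dqd) - dL/dq = tau - B qd with L the kinetic energy
    Mdot <- matrix(0, 2, 2)
    for (k in 1:2) {
      dq <- c(0, 0); dq[k] <- h
      Mdot <- Mdot + (mass_matrix(q + dq, arm) - mass_matrix(q - dq, arm)) /
        (2 * h) * qd[k]
    }
    dKE_dq <- vapply(1:2, function(k) {
      dq <- c(0, 0); dq[k] <- h
      (kinetic_energy(q + dq, qd, arm) - kinetic_energy(q - dq, qd, arm)) / (2 * h)
    }, 0)
    rhs <- tau - drop(Mdot %*% qd) + dKE_dq - drop(arm$B %*% qd)
    qdd_oracle <- solve(mass_matrix(q, arm), rhs)
    qdd <- forward_dynamics(arm_state(q, qd), tau, c(0, 0), arm)
    expect_equal(qdd, qdd_oracle, tolerance = 1e-6)
  }
})

test_that("tensions never go negative along a perturbed trial", {
  cfg <- fast_cfg()
  set.seed(8)
  plan <- reach_plan(c(0, 0.3), c(0, 0.42), 0.3, cfg$simulation$dt, cfg$arm)
  net <- toy_network(W = matrix(0.1, 6, 5))
  tr <- simulate_trial(plan, net, force_field("VF", B = curl_matrix(10)), cfg)
  expect_true(all(tr$tension >= 0))
})

test_that("plant step is stationary at rest and converges at integrator order", {
  cfg <- fast_cfg()
  geom <- cfg$geometry
  st <- arm_state(geom$q_ref)
  out <- plant_step(st, rep(0, 6), force_field("NF"), 0.001, cfg$arm, geom,
                    cfg$muscle)
  expect_equal(out$state$q, st$q, tolerance = 1e-12)
  expect_equal(out$state$qdot, st$qdot, tolerance = 1e-12)
  expect_false(out$diverged)

  # step-halving: error against a fine-grid reference shrinks at ~4th order
  u <- c(0.3, 0.1, 0.2, 0.3, 0.1, 0.2)
  roll <- function(dt, t_end) {
    s <- arm_state(geom$q_ref, c(0.5, -0.3))
    for (i in seq_len(round(t_end / dt))) {
      s <- plant_step(s, u, force_field("NF"), dt, cfg$arm, geom, cfg$muscle)$state
    }
    c(s$q, s$qdot)
  }
  ref <- roll(0.00025, 0.05)
  e1 <- sqrt(sum((roll(0.002, 0.05) - ref)^2))
  e2 <- sqrt(sum((roll(0.001, 0.05) - ref)^2))
  expect_gt(e1 / e2, 8)

  expect_error(plant_step(st, u, force_field("NF"), -0.001, cfg$arm, geom),
               "positive")
})

test_that("a trial produces one log row per time step", {
  cfg <- fast_cfg()
  plan <- reach_plan(c(0, 0.3), c(0, 0.42), 0.3, cfg$simulation$dt, cfg$arm,
                     hold = 0)
  net <- toy_network()
  set.seed(1)
  tr <- simulate_trial(plan, net, force_field("NF"), cfg)
  expect_equal(nrow(tr$q), nrow(plan$q))
  expect_equal(nrow(tr$u), 301)
})

test_that("compiled and reference engines agree to machine precision", {
  cfg <- fast_cfg()
  plan <- reach_plan(c(0, 0.3), c(0.08, 0.38), 0.3, cfg$simulation$dt, cfg$arm)
  net <- toy_network(W = matrix(0.05, 6, 5))
  for (fld in list(force_field("NF"),
                   force_field("VF", B = matrix(cfg$fields$vf_B, 2, 2)),
                   force_field("DF", gain = 300, start = c(0, 0.3),
                               goal = c(0.08, 0.38)))) {
    set.seed(21)
    a <- simulate_trial(plan, net, fld, cfg, engine = "cpp")
    set.seed(21)
    b <- simulate_trial(plan, net, fld, cfg, engine = "R")
    for (comp in c("q", "qdot", "hand", "e", "eps", "u", "tension", "F_ext")) {
      expect_equal(a[[comp]], b[[comp]], tolerance = 1e-12)
    }
  }
})

test_that("divergent trials are aborted and flagged", {
  cfg <- fast_cfg(simulation = list(speed_limit = 0.2))
  plan <- reach_plan(c(0, 0.3), c(0, 0.42), 0.3, cfg$simulation$dt, cfg$arm)
  net <- toy_network()
  set.seed(2)
  tr <- simulate_trial(plan, net, force_field("NF"), cfg)
  expect_true(tr$aborted)
  expect_gt(tr$abort_step, 0)
})

test_that("torque-balanced co-activation leaves the path but stiffens the arm", {
  cfg <- fast_cfg(noise = list(coef = 0))
  plan <- reach_plan(c(0, 0.3), c(0, 0.42), 0.3, cfg$simulation$dt, cfg$arm)
  # probe field: constant-curl disturbance scaled with velocity
  dist <- force_field("VF", B = curl_matrix(5))
  peak_dev <- function(co) {
    net <- toy_network(W = matrix(co, 6, 5), width = 5)
    set.seed(1)
    tr <- simulate_trial(plan, net, dist, cfg)
    max(abs(tr$hand[, 1] - plan$pos[, 1]))
  }
  devs <- vapply(c(0, 0.1, 0.3), peak_dev, 0)
  expect_true(all(diff(devs) < 0))
})
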