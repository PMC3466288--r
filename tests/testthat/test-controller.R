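test_that("minimum-jerk trajectories satisfy boundary and peak-speed laws", {
  mj <- minimum_jerk(c(0, 0.3), c(0, 0.42), 0.3, c(0, 0.15, 0.3))
  expect_equal(mj$pos[1, ], c(0, 0.3))
  expect_equal(mj$vel[1, ], c(0, 0))
  expect_equal(mj$pos[3, ], c(0, 0.42))
  expect_equal(mj$vel[3, ], c(0, 0))
  # peak speed of a 12 cm, 300 ms reach: 1.875 * d / T at mid-time
  expect_equal(sqrt(sum(mj$vel[2, ]^2)), 1.875 * 0.12 / 0.3, tolerance = 1e-12)
  expect_error(minimum_jerk(c(0, 0), c(1, 0), 0.3, 0.4), "within")
})

test_that("circle plans close and have the stated speed profile", {
  arm <- arm_parameters()
  p <- circle_plan(c(0, 0.40), 0.10, 0.3, 0.001, arm, profile = "constant",
                   lead_in = 0)
  sp <- sqrt(rowSums(p$vel^2))
  expect_equal(sp, rep(2 * pi * 0.10 / 0.3, length(sp)), tolerance = 1e-12)
  expect_equal(p$pos[1, ], p$pos[nrow(p$pos), ], tolerance = 1e-9)

  pm <- circle_plan(c(0, 0.40), 0.10, 0.3, 0.001, arm)
  expect_equal(pm$vel[1, ], c(0, 0), tolerance = 1e-9)
  expect_equal(pm$vel[nrow(pm$vel), ], c(0, 0), tolerance = 1e-9)
  expect_equal(pm$pos[1, ], pm$pos[nrow(pm$pos), ], tolerance = 1e-9)

  expect_error(circle_plan(c(0, 0.40), -0.1, 0.3, 0.001, arm), "positive")
  expect_error(circle_plan(c(0, 0.40), 0.7, 0.3, 0.001, arm), "unreachable")
})

test_that("reference muscle lengths track the plan geometry", {
  cfg <- fast_cfg()
  geom <- cfg$geometry
  # stationary plan: constant reference lengths, zero rates
  p <- reach_plan(c(0, 0.35), c(0, 0.35), 0.3, 0.001, cfg$arm)
  r1 <- reference_muscle_lengths(p, geom, 0)
  r2 <- reference_muscle_lengths(p, geom, 0.2)
  expect_equal(r1$l_r, r2$l_r)
  expect_equal(r2$ldot_r, rep(0, 6))

  # motion equal to the plan gives zero error downstream
  p2 <- reach_plan(c(0, 0.3), c(0, 0.42), 0.3, 0.001, cfg$arm)
  i <- 150
  ml <- muscle_lengths(arm_state(p2$q[i, ], p2$qdot[i, ]), geom)
  rr <- reference_muscle_lengths(p2, geom, (i - 1) * 0.001)
  expect_equal(ml$l - rr$l_r, rep(0, 6), tolerance = 1e-12)

  # an elbow-only rotation only changes elbow and biarticular references
  q0 <- geom$q_ref
  l_a <- muscle_lengths(arm_state(q0), geom)$l
  l_b <- muscle_lengths(arm_state(q0 + c(0, 0.2)), geom)$l
  moved <- which(abs(l_b - l_a) > 1e-12)
  expect_setequal(moved, c(3, 4, 5, 6))

  expect_error(reference_muscle_lengths(p, geom, 5), "outside")
})

test_that("sliding error delays and weights the muscle error", {
  e <- matrix(0, 200, 6)
  ed <- matrix(0, 200, 6)
  expect_equal(sliding_error(e, ed, 0.05, 0.06, 0.15, 0.001), rep(0, 6))

  e2 <- matrix(0.01, 200, 6)
  # constant error: eps equals the plain error once the delay has elapsed
  expect_equal(sliding_error(e2, ed, 0.05, 0.06, 0.1, 0.001), rep(0.01, 6))
  # kappa = 0 reduces to the delayed length error even with nonzero rates
  ed2 <- matrix(0.5, 200, 6)
  expect_equal(sliding_error(e2, ed2, 0, 0.06, 0.1, 0.001), rep(0.01, 6))
  expect_equal(sliding_error(e2, ed2, 0.05, 0.06, 0.1, 0.001),
               rep(0.01 + 0.05 * 0.5, 6))
  # before one delay has elapsed there is no feedback information
  expect_equal(sliding_error(e2, ed2, 0.05, 0.06, 0.03, 0.001), rep(0, 6))
  expect_error(sliding_error(matrix(0, 0, 6), matrix(0, 0, 6), 0.05, 0.06,
                             0.1, 0.001), "empty")
})

test_that("V-shaped feedback is non-negative with a steeper stretch side", {
  g <- vshape_gains(stretch_slope = 2, shorten_slope = 1, kappa = 0, delay = 0.06)
  expect_equal(vshape_feedback(rep(0, 6), g), rep(0, 6))
  expect_equal(vshape_feedback(c(0.01, -0.01, 0, 0, 0, 0), g)[1:2],
               c(0.02, 0.01))
  # symmetry holds exactly when the slopes are equal
  gs <- vshape_gains(stretch_slope = 1.5, shorten_slope = 1.5, kappa = 0,
                     delay = 0.06)
  eps <- c(0.01, -0.02, 0.003, -0.004, 0.005, -0.006)
  expect_equal(vshape_feedback(eps, gs), vshape_feedback(-eps, gs))
  expect_false(isTRUE(all.equal(vshape_feedback(eps, g),
                                vshape_feedback(-eps, g))))
  expect_error(vshape_gains(stretch_slope = 1, shorten_slope = 2),
               "stretch_slope")
  expect_error(vshape_gains(delay = 0.5), "delay")
})

test_that("error split and command composition respect the pull-only constraint", {
  set.seed(4)
  for (i in 1:50) {
    eps <- rnorm(6, sd = 0.01)
    parts <- split_error(eps)
    expect_equal(parts$pos + parts$neg, eps)
    expect_true(all(parts$pos >= 0) && all(parts$neg <= 0))
    expect_true(all(parts$pos * parts$neg == 0))
  }
  expect_equal(compose_command(c(-0.2, 0.3, 0, 0.1, -0.1, 0.5), rep(0, 6)),
               c(0, 0.3, 0, 0.1, 0, 0.5))
  expect_equal(compose_command(rep(0, 6), rep(0.1, 6)), rep(0.1, 6))
})

test_that("feedback co-activates antagonists and restores a perturbed movement", {
  cfg <- fast_cfg(noise = list(coef = 0))
  plan <- reach_plan(c(0, 0.3), c(0, 0.42), 0.3, cfg$simulation$dt, cfg$arm)
  # start the arm displaced 1 cm laterally from the plan
  plan_disp <- plan
  plan_disp$q[1, ] <- inverse_kinematics(plan$pos[1, ] + c(0.01, 0), cfg$arm)
  net <- toy_network()
  set.seed(6)
  tr <- simulate_trial(plan_disp, net, force_field("NF"), cfg)
  # after the delay, every antagonist pair shows feedback in BOTH members
  t_look <- 80
  for (p in list(c(1, 2), c(3, 4), c(5, 6))) {
    expect_true(any(tr$u_fb[t_look:150, p[1]] > 0))
    expect_true(any(tr$u_fb[t_look:150, p[2]] > 0))
  }
  # feedback pulls the hand back toward the plan: terminal lateral deviation
  # is smaller than with (near-)zero feedback gains
  cfg_off <- cfg
  cfg_off$gains <- vshape_gains(stretch_slope = 1e-6, shorten_slope = 1e-6,
                                kappa = 0.05, delay = 0.06)
  set.seed(6)
  tr_off <- simulate_trial(plan_disp, net, force_field("NF"), cfg_off)
  n <- nrow(tr$hand)
  expect_lt(abs(tr$hand[n, 1] - plan$pos[n, 1]),
            abs(tr_off$hand[n, 1] - plan$pos[n, 1]))
  # eps decomposition identity holds at every logged step
  parts <- split_error(tr$eps)
  expect_equal(parts$pos + parts$neg, tr$eps)
})
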