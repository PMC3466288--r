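test_that("Gaussian activation is 1 at the center and decays with distance", {
  c0 <- c(0.5, 1.2, 0, 0)
  expect_equal(gaussian_activation(c0, c0, rep(1, 4)), 1)
  # one isotropic width from the center
  x <- c0 + c(1, 0, 0, 0)
  expect_equal(gaussian_activation(x, c0, rep(1, 4)), exp(-0.5))
  expect_lt(gaussian_activation(c0 + c(2, 0, 0, 0), c0, rep(1, 4)),
            gaussian_activation(x, c0, rep(1, 4)))
  expect_error(gaussian_activation(x, c0, c(1, 0, 1, 1)), "positive")
})

test_that("network evaluation equals the generic linear-primitive form", {
  set.seed(23)
  net <- toy_network(N = 7, W = matrix(abs(rnorm(42)), 6, 7))
  expect_equal(rbf_evaluate(toy_network(N = 7), c(0.9, 1.5, 0, 0)), rep(0, 6))
  for (i in 1:100) {
    x <- rnorm(4)
    direct <- rbf_evaluate(net, x)
    via_phi <- pmax(0, drop(rbf_design(net, x) %*% as.vector(net$W)))
    expect_equal(direct, via_phi, tolerance = 1e-13)
  }
  # single neuron: output is the weight column scaled by its activation
  n1 <- rbf_network(matrix(0, 3, 4), matrix(1, 3, 4),
                    scaling = list(center = rep(0, 4), sd = rep(1, 4)),
                    W = cbind(1:6, 0, 0) / 10)
  x <- c(0.5, 0, 0, 0)
  expect_equal(rbf_evaluate(n1, x), (1:6) / 10 * exp(-0.125))
})

test_that("network learning law equals the generic update through the design matrix", {
  set.seed(24)
  net <- toy_network(N = 4, W = matrix(abs(rnorm(24, sd = 0.1)), 6, 4))
  cfg <- learning_config(eta = 2, gamma = 0.001)
  Tn <- 30
  states <- matrix(rnorm(Tn * 4), Tn, 4)
  s <- matrix(rnorm(Tn * 6, sd = 0.01), Tn, 6)
  # matrix form used by the trial-level fitter
  G <- rbf_basis(net, states)
  D <- cfg$stretch_slope * pmax(s, 0) - cfg$shorten_slope * pmin(s, 0)
  dW <- cfg$eta * cfg$Q * 0.001 * crossprod(D, G)
  W_fast <- pmax(net$W + dW - cfg$gamma, 0)
  # generic path on the vectorized parameters
  model <- primitive_model(function(x) rbf_design(net, x), as.vector(net$W))
  upd <- gradient_update(model, s,
                         lapply(seq_len(Tn), function(i) states[i, ]), cfg)
  expect_equal(matrix(upd$w, 6, 4), W_fast, tolerance = 1e-12)
})

test_that("k-means finds exact solutions on separable data", {
  # all copies of one point
  pts <- matrix(1.5, 10, 2)
  f <- kmeans_fit(pts, 1)
  expect_equal(drop(f$centers), c(1.5, 1.5))
  expect_equal(f$D, 0)
  # two well-separated pairs: centroids are the pair means
  pts2 <- rbind(c(0, 0), c(0.2, 0), c(5, 5), c(5.2, 5))
  set.seed(25)
  f2 <- kmeans_fit(pts2, 2)
  cen <- f2$centers[order(f2$centers[, 1]), ]
  expect_equal(cen, rbind(c(0.1, 0), c(5.1, 5)), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(f2$D, 2 * 0.1^2 + 2 * 0.1^2, tolerance = 1e-12)
  expect_error(kmeans_fit(pts, 2), "distinct")
})

test_that("fitted k-means beats random centroid placements", {
  set.seed(26)
  pts <- matrix(rnorm(200), 100, 2)
  f <- kmeans_fit(pts, 6, n_restarts = 5)
  rand_D <- replicate(1000, {
    cen <- pts[sample.int(100, 6), , drop = FALSE]
    d2 <- vapply(seq_len(100), function(i) {
      min(rowSums((cen - matrix(pts[i, ], 6, 2, byrow = TRUE))^2))
    }, 0)
    sum(d2)
  })
  expect_lte(f$D, min(rand_D))
})

test_that("widths cover clusters, scale homogeneously, and floor singletons", {
  set.seed(27)
  pts <- rbind(matrix(rnorm(40, sd = 0.3), 20, 2),
               matrix(rnorm(40, mean = 4, sd = 0.3), 20, 2),
               c(10, 10))
  f <- kmeans_fit(pts, 3)
  w1 <- width_assignment(pts, f, scale_factor = 1, floor = 0.05)
  w2 <- width_assignment(pts, f, scale_factor = 2, floor = 0.05)
  singleton <- which(tabulate(f$cluster, 3) == 1)
  if (length(singleton) == 1) {
    expect_equal(w1[singleton, ], c(0.05, 0.05))
  }
  big <- w1 > 0.05
  expect_equal(w2[big], 2 * w1[big])
  expect_error(width_assignment(pts, f, scale_factor = -1), "positive")
})

test_that("network selection respects bounds and covers the training states", {
  cfg <- fast_cfg()
  set.seed(28)
  plans <- impedance_plans(cfg)  # two straight reaches 35 degrees apart
  states <- nf_state_data(plans, cfg)
  net5 <- select_network(states, K_min = 5, K_max = 5, K_init = 5)
  expect_equal(net5$N, 5)
  net <- select_network(states, scale_factor = cfg$network$scale_factor)
  expect_gte(net$N, 3)
  expect_lte(net$N, 80)
  # coverage/overlap: every training state activates at least 2 neurons
  # appreciably
  G <- rbf_basis(net, states)
  expect_gte(min(apply(G, 1, function(g) sort(g, decreasing = TRUE)[2])), 0.05)
  expect_error(select_network(matrix(0, 5, 4)), "distinct")
})

test_that("learning transfers only through overlapping activation fields", {
  # weights supported on neurons along one region produce near-zero output
  # far away in state space
  set.seed(29)
  centers <- rbind(matrix(rnorm(12, sd = 0.3), 3, 4),
                   matrix(rnorm(12, mean = 6, sd = 0.3), 3, 4))
  net <- rbf_network(centers, matrix(0.5, 6, 4),
                     scaling = list(center = rep(0, 4), sd = rep(1, 4)),
                     W = cbind(matrix(0.5, 6, 3), matrix(0, 6, 3)))
  near <- rnorm(4, sd = 0.3)
  far <- rnorm(4, mean = 6, sd = 0.3)
  expect_gt(max(rbf_evaluate(net, near)), 0.1)
  expect_lt(max(rbf_evaluate(net, far)), 1e-6)
})
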