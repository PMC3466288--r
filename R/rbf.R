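#' Gaussian basis activation
#'
#' \eqn{g_j(x) = \exp(-\sum_d (x_d - c_{jd})^2 / (2 \sigma_{jd}^2))}: 1 at
#' the center, strictly decreasing with distance.
#'
#' @param x state vector.
#' @param center neuron center (same length as x).
#' @param width per-dimension widths (> 0), or a scalar for an isotropic
#'   field.
#' @return scalar in (0, 1].
#' @export
gaussian_activation <- function(x, center, width) {
  if (any(width <= 0)) stop("widths must be positive")
  exp(-sum((x - center)^2 / (2 * width^2)))
}

#' Radial-basis-function feedforward network
#'
#' Maps the 4-D joint state (q, qdot) to six non-negative feedforward
#' muscle activations: \code{u_ff = pmax(0, W \%*\% g(x))}. States are
#' standardized with a scaling frozen at network construction so that
#' positions (rad) and velocities (rad/s) are commensurable; centers and
#' widths live in the standardized space.
#'
#' @param centers N x 4 matrix of centers (standardized units).
#' @param widths N x 4 matrix of per-dimension widths (> 0).
#' @param scaling list with \code{center} and \code{sd} (length-4 each)
#'   defining the standardization \code{z = (x - center) / sd}.
#' @param W 6 x N non-negative weight matrix (defaults to zeros).
#' @return An object of class \code{rbf_network}.
#' @export
rbf_network <- function(centers, widths, scaling, W = NULL) {
  centers <- as.matrix(centers); widths <- as.matrix(widths)
  N <- nrow(centers)
  if (N < 3 || N > 80) stop("neuron count must lie in [3, 80]")
  stopifnot(ncol(centers) == 4, all(dim(widths) == dim(centers)),
            all(widths > 0), length(scaling$center) == 4,
            length(scaling$sd) == 4, all(scaling$sd > 0))
  if (is.null(W)) W <- matrix(0, 6, N)
  W <- as.matrix(W)
  stopifnot(nrow(W) == 6, ncol(W) == N)
  if (any(W < 0)) stop("weights must be non-negative")
  structure(list(centers = centers, widths = widths, scaling = scaling,
                 W = W, N = N), class = "rbf_network")
}

#' @export
print.rbf_network <- function(x, ...) {
  cat(sprintf("RBF network: %d neurons over 4-D joint state, weight norm %.4f\n",
              x$N, sqrt(sum(x$W^2))))
  invisible(x)
}

#' Basis activations of all neurons at a state
#'
#' @param net \code{\link{rbf_network}}.
#' @param x raw state (q1, q2, qd1, qd2) or a matrix of such rows.
#' @return vector of length N (or a matrix, rows matching \code{x}).
#' @export
rbf_basis <- function(net, x) {
  x <- rbind(x)
  z <- sweep(sweep(x, 2, net$scaling$center), 2, net$scaling$sd, "/")
  g <- matrix(0, nrow(z), net$N)
  for (j in seq_len(net$N)) {
    d <- sweep(z, 2, net$centers[j, ])
    g[, j] <- exp(-rowSums(sweep(d, 2, net$widths[j, ], "/")^2) / 2)
  }
  if (nrow(g) == 1) drop(g) else g
}

#' Evaluate the feedforward command
#'
#' @param net \code{\link{rbf_network}}.
#' @param x raw state vector (length 4).
#' @return feedforward activations, length 6, >= 0.
#' @export
rbf_evaluate <- function(net, x) {
  pmax(0, drop(net$W %*% rbf_basis(net, x)))
}

#' Linear-primitive design matrix of the network at a state
#'
#' The network in the generic linear-in-parameters form: with
#' \code{w = as.vector(W)} (columns stacked), \code{Phi(x) \%*\% w} equals
#' \code{W \%*\% g(x)} exactly, so the generic learning law applies
#' unchanged to the RBF basis.
#'
#' @param net \code{\link{rbf_network}}.
#' @param x raw state vector.
#' @return 6 x (6N) matrix.
#' @export
rbf_design <- function(net, x) {
  g <- rbf_basis(net, x)
  kronecker(matrix(g, nrow = 1), diag(6))
}

#' K-means clustering with restarts
#'
#' Lloyd iterations from random initial centers, repeated over restarts;
#' the solution with the smallest total within-cluster sum of squared
#' distances D is kept. A restart that produces an empty cluster is
#' repaired by re-seeding that centroid from the point farthest from its
#' assigned centroid.
#'
#' @param states matrix of points (rows).
#' @param K number of clusters (<= number of distinct points).
#' @param n_restarts number of random restarts.
#' @param iter_max Lloyd iteration cap per restart.
#' @return list: \code{cluster} (assignments), \code{centers}, \code{D}
#'   (objective), \code{iterations} (total Lloyd iterations used).
#' @export
kmeans_fit <- function(states, K, n_restarts = 5, iter_max = 100) {
  states <- as.matrix(states)
  uniq <- unique(states)
  if (K > nrow(uniq)) stop("K exceeds the number of distinct points")
  run_lloyd <- function(init) {
    suppressWarnings(stats::kmeans(states, centers = init,
                                   iter.max = iter_max, algorithm = "Lloyd"))
  }
  best <- NULL
  iters <- 0
  for (r in seq_len(n_restarts)) {
    init <- uniq[sample.int(nrow(uniq), K), , drop = FALSE]
    km <- tryCatch(run_lloyd(init), error = function(e) NULL)
    # empty-cluster repair: re-seed the empty centroid from the point
    # farthest from its current centroid, then re-run
    tries <- 0
    while ((is.null(km) || any(km$size == 0)) && tries < 10) {
      if (is.null(km)) {
        init <- uniq[sample.int(nrow(uniq), K), , drop = FALSE]
      } else {
        far <- which.max(rowSums(
          (states - km$centers[km$cluster, , drop = FALSE])^2))
        init <- km$centers
        init[which(km$size == 0)[1], ] <- states[far, ]
      }
      km <- tryCatch(run_lloyd(init), error = function(e) NULL)
      tries <- tries + 1
    }
    if (is.null(km)) next
    iters <- iters + km$iter
    if (is.null(best) || km$tot.withinss < best$D) {
      best <- list(cluster = km$cluster, centers = km$centers,
                   D = km$tot.withinss)
    }
  }
  if (is.null(best)) stop("k-means failed on all restarts")
  best$iterations <- iters
  best
}

#' Per-neuron width assignment
#'
#' The base width of a neuron in each dimension is the maximum absolute
#' distance from its centroid to the members of its cluster in that
#' dimension ("include all data within the cluster"), multiplied by a
#' scaling factor so the activation fields of adjacent neurons overlap.
#' Singleton or degenerate clusters get a floor width.
#'
#' @param states matrix of (standardized) points.
#' @param clustering result of \code{\link{kmeans_fit}}.
#' @param scale_factor positive multiplier of the base widths; a scalar, or
#'   one value per state dimension (e.g. wider fields along the velocity
#'   dimensions than along position).
#' @param floor minimum width (standardized units); scalar or per
#'   dimension. The default keeps a wider floor along the velocity
#'   dimensions so that sparse high-speed clusters still overlap their
#'   slower neighbours.
#' @return K x ncol(states) width matrix.
#' @export
width_assignment <- function(states, clustering, scale_factor = 1.5,
                             floor = c(0.15, 0.15, 0.4, 0.4)) {
  if (any(scale_factor <= 0)) stop("scale_factor must be positive")
  d <- ncol(states)
  scale_factor <- rep_len(scale_factor, d)
  floor <- rep_len(floor, d)
  K <- nrow(clustering$centers)
  w <- matrix(floor, K, d, byrow = TRUE)
  for (j in seq_len(K)) {
    mem <- states[clustering$cluster == j, , drop = FALSE]
    if (nrow(mem) > 1) {
      ext <- apply(abs(sweep(mem, 2, clustering$centers[j, ])), 2, max)
      w[j, ] <- pmax(scale_factor * ext, floor)
    }
  }
  w
}

#' Cluster the visited states and build an unweighted network
#'
#' Standardizes the 4-D states, then searches for the smallest neuron count
#' K within \code{[K_min, K_max]}, starting from \code{K_init} and moving
#' up or down, such that the states lie within \code{coverage} of some
#' centroid (95th percentile of standardized Euclidean distance, robust to
#' stray excursions). Each candidate K is fit by
#' restarted K-means; the total Lloyd-iteration budget of the whole stage
#' is capped (default 2000). Widths are assigned from the winning
#' clustering and the weight matrix starts at zero.
#'
#' @param states T x 4 matrix of raw joint states (q, qdot).
#' @param K_min,K_max neuron-count bounds.
#' @param K_init starting neuron count for the search.
#' @param coverage maximal allowed state-to-centroid distance
#'   (standardized units).
#' @param scale_factor width scaling factor (see
#'   \code{\link{width_assignment}}).
#' @param iter_budget total Lloyd-iteration budget.
#' @param n_restarts restarts per candidate K.
#' @return unweighted \code{\link{rbf_network}} with the clustering
#'   attached as attribute \code{"clustering"}.
#' @export
select_network <- function(states, K_min = 3, K_max = 80, K_init = 20,
                           coverage = 0.9, scale_factor = 1.5,
                           iter_budget = 2000, n_restarts = 3) {
  states <- as.matrix(states)
  if (nrow(states) == 0) stop("no states supplied")
  if (nrow(unique(states)) < K_min) stop("fewer distinct states than K_min")
  ctr <- colMeans(states)
  sd_ <- apply(states, 2, stats::sd)
  sd_[sd_ < 1e-9] <- 1                    # constant dimension: leave unscaled
  z <- sweep(sweep(states, 2, ctr), 2, sd_, "/")

  covered <- function(fit) {
    d2 <- rowSums((z - fit$centers[fit$cluster, , drop = FALSE])^2)
    # robust coverage statistic: the odd feedback-driven excursion should
    # not force extra neurons
    stats::quantile(sqrt(d2), 0.95, names = FALSE)
  }
  used <- 0
  fit_K <- function(K) {
    f <- kmeans_fit(z, K, n_restarts = n_restarts,
                    iter_max = max(10, min(100, iter_budget - used)))
    used <<- used + f$iterations
    f
  }
  K <- max(K_min, min(K_max, K_init))
  fit <- fit_K(K)
  if (covered(fit) > coverage) {
    while (K < K_max && covered(fit) > coverage && used < iter_budget) {
      K <- K + 1
      fit <- fit_K(K)
    }
  } else {
    while (K > K_min && used < iter_budget) {
      cand <- fit_K(K - 1)
      if (covered(cand) > coverage) break
      K <- K - 1
      fit <- cand
    }
  }
  widths <- width_assignment(z, fit, scale_factor = scale_factor)
  net <- rbf_network(fit$centers, widths,
                     scaling = list(center = ctr, sd = sd_))
  attr(net, "clustering") <- fit
  net
}
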