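#' Movement plans of the generalization experiment
#'
#' Eight 12 cm center-out minimum-jerk reaches spanning 360 degrees plus a
#' 10 cm-radius circle, all 300 ms, around the workspace center.
#'
#' @param cfg model configuration.
#' @return list with \code{reaches} (8 plans) and \code{circle}.
#' @export
generalization_plans <- function(cfg = default_config()) {
  c0 <- cfg$workspace$center
  dt <- cfg$simulation$dt
  dirs <- seq(0, 2 * pi, length.out = 9)[1:8]
  reaches <- lapply(dirs, function(th) {
    p <- reach_plan(c0, c0 + 0.12 * c(cos(th), sin(th)), 0.3, dt, cfg$arm)
    attr(p, "direction") <- th
    p
  })
  circle <- circle_plan(c0, 0.10, 0.3, dt, cfg$arm)
  list(reaches = reaches, circle = circle)
}

#' Movement plans of the granularity experiment
#'
#' Sixteen 12 cm center-out reaches from 0 to 337.5 degrees separated by
#' 22.5 degrees, 300 ms each.
#'
#' @param cfg model configuration.
#' @return list of 16 plans, each carrying its direction attribute.
#' @export
granularity_plans <- function(cfg = default_config()) {
  c0 <- cfg$workspace$center
  dt <- cfg$simulation$dt
  dirs <- seq(0, 2 * pi, length.out = 17)[1:16]
  lapply(dirs, function(th) {
    p <- reach_plan(c0, c0 + 0.12 * c(cos(th), sin(th)), 0.3, dt, cfg$arm)
    attr(p, "direction") <- th
    p
  })
}

#' Movement plans of the impedance-learning experiment
#'
#' Two 25 cm, 600 ms point-to-point movements separated by 35 degrees
#' (D1 straight ahead of the shoulder, D2 rotated 35 degrees clockwise),
#' the geometry of the divergent-field task.
#'
#' @param cfg model configuration.
#' @param start start position (m) relative to the shoulder.
#' @param length movement length (m).
#' @return list with plans \code{D1} and \code{D2}.
#' @export
impedance_plans <- function(cfg = default_config(), start = c(0, 0.18),
                            length = 0.25) {
  dt <- cfg$simulation$dt
  a35 <- 35 * pi / 180
  g1 <- start + length * c(0, 1)
  g2 <- start + length * c(sin(a35), cos(a35))
  list(D1 = reach_plan(start, g1, 0.6, dt, cfg$arm),
       D2 = reach_plan(start, g2, 0.6, dt, cfg$arm))
}

#' Joint states visited by a set of plans
#'
#' @param plans list of reference plans.
#' @param thin keep every thin-th sample.
#' @return matrix with columns q1, q2, qd1, qd2.
#' @export
plan_states <- function(plans, thin = 2) {
  do.call(rbind, lapply(plans, function(p) {
    idx <- seq(1, nrow(p$q), by = thin)
    cbind(p$q[idx, , drop = FALSE], p$qdot[idx, , drop = FALSE])
  }))
}

#' Joint-state data from free movements
#'
#' States visited while actually performing the plans in the null field
#' under feedback alone (no feedforward command), pooled with the planned
#' states. This is the data on which the network centers are placed:
#' early, unpracticed movements deviate substantially from the plan, and
#' the activation fields must cover those states for learning to engage.
#'
#' @param plans list of reference plans.
#' @param cfg model configuration.
#' @param n_per_plan free trials per plan.
#' @param thin keep every thin-th sample.
#' @return matrix with columns q1, q2, qd1, qd2.
#' @export
nf_state_data <- function(plans, cfg, n_per_plan = 2, thin = 2) {
  # dummy wide network with zero weights: feedforward is identically zero
  dummy <- rbf_network(centers = matrix(0, 3, 4),
                       widths = matrix(1, 3, 4),
                       scaling = list(center = rep(0, 4), sd = rep(1, 4)))
  nf <- force_field("NF")
  visited <- lapply(plans, function(p) {
    do.call(rbind, lapply(seq_len(n_per_plan), function(i) {
      tr <- simulate_trial(p, dummy, nf, cfg)
      idx <- seq(1, nrow(tr$q), by = thin)
      cbind(tr$q[idx, , drop = FALSE], tr$qdot[idx, , drop = FALSE])
    }))
  })
  rbind(plan_states(plans, thin = thin), do.call(rbind, visited))
}

# run frozen probe trials of one plan and return axis ratios / logs
.probe <- function(plan, field, net, cfg, n) {
  fit <- run_learning(list(plan), field, net, cfg, n_trials = n,
                      schedule = rep(1L, n), keep_logs = "all",
                      learn = FALSE)
  list(logs = lapply(fit$logs, `[[`, "log"), history = fit$history)
}

.circle_ratios <- function(probe, plan) {
  idx <- if (!is.null(plan$measure_idx)) plan$measure_idx else seq_len(nrow(plan$pos))
  vapply(probe$logs, function(lg) {
    if (lg$aborted) return(NA_real_)
    axis_ratio(lg$hand[idx, , drop = FALSE])
  }, 0)
}

#' Movement-generalization experiment
#'
#' Trains the model on a velocity-dependent curl field either directly on
#' circular movements or on center-out reaches in eight directions, and
#' probes circular movements in each phase: null field, first field
#' exposure, post-learning in the field, and after-effect catch trials with
#' the field silently removed. Both trained networks start from the same
#' null-field practice phase (reaches and circles intermixed), whose states
#' also place the RBF centers.
#'
#' @param cfg model configuration.
#' @param seed RNG seed for the whole protocol.
#' @param n_nf_reach,n_nf_circle null-field practice trials.
#' @param n_train field-training trials per arm.
#' @param n_probe circle probes per phase.
#' @return object of class \code{generalization_results}: axis-ratio table,
#'   per-probe ratios, the fitted networks and probe logs.
#' @export
run_generalization <- function(cfg = default_config(), seed = 1,
                        n_nf_reach = 100, n_nf_circle = 100,
                        n_train = 100, n_probe = 5) {
  set.seed(seed)
  plans <- generalization_plans(cfg)
  all_plans <- c(plans$reaches, list(plans$circle))
  net0 <- select_network(nf_state_data(all_plans, cfg),
                         K_min = cfg$network$K_min, K_max = cfg$network$K_max,
                         K_init = cfg$network$K_init,
                         coverage = cfg$network$coverage,
                         scale_factor = cfg$network$scale_factor,
                         iter_budget = cfg$network$iter_budget,
                         n_restarts = cfg$network$n_restarts)
  nf <- force_field("NF")
  vf <- force_field("VF", B = matrix(cfg$fields$vf_B, 2, 2))

  sched_nf <- sample(c(rep_len(seq_len(8), n_nf_reach),
                       rep(9L, n_nf_circle)))
  fit_nf <- run_learning(all_plans, nf, net0, cfg,
                         n_trials = n_nf_reach + n_nf_circle,
                         schedule = sched_nf)
  net_nf <- fit_nf$net

  pr_nf <- .probe(plans$circle, nf, net_nf, cfg, n_probe)
  pr_exposure <- .probe(plans$circle, vf, net_nf, cfg, n_probe)

  fit_direct <- run_learning(list(plans$circle), vf, net_nf, cfg,
                             n_trials = n_train,
                             schedule = rep(1L, n_train))
  pr_direct_vf <- .probe(plans$circle, vf, fit_direct$net, cfg, n_probe)
  pr_direct_ae <- .probe(plans$circle, nf, fit_direct$net, cfg, n_probe)

  fit_reach <- run_learning(plans$reaches, vf, net_nf, cfg,
                            n_trials = n_train)
  pr_transfer_vf <- .probe(plans$circle, vf, fit_reach$net, cfg, n_probe)
  pr_transfer_ae <- .probe(plans$circle, nf, fit_reach$net, cfg, n_probe)

  probes <- list(nf = pr_nf, exposure = pr_exposure,
                 direct_vf = pr_direct_vf, direct_ae = pr_direct_ae,
                 transfer_vf = pr_transfer_vf, transfer_ae = pr_transfer_ae)
  ratios <- lapply(probes, .circle_ratios, plan = plans$circle)
  tab <- data.frame(phase = names(ratios),
                    ratio = vapply(ratios, mean, 0, na.rm = TRUE),
                    n_valid = vapply(ratios, function(r) sum(!is.na(r)), 0L),
                    row.names = NULL)
  structure(list(ratios = tab, probe_ratios = ratios, probes = probes,
                 neurons = net0$N, seed = seed,
                 fits = list(nf = fit_nf, direct = fit_direct,
                             reach = fit_reach)),
            class = "generalization_results")
}

#' @export
print.generalization_results <- function(x, ...) {
  cat("Movement-generalization experiment (seed", x$seed, ")\n")
  cat(sprintf("  network: %d neurons\n", x$neurons))
  print(x$ratios, row.names = FALSE)
  invisible(x)
}

#' Field-granularity experiment
#'
#' Reaches to sixteen directions: a null-field block followed by learning
#' in a direction-variant velocity field of spatial frequency k (1, 2 or
#' 4), with identical network hyperparameters across fields. The learning
#' curve is the per-trial correlation of the hand velocity time series with
#' the null-field template of the same direction, smoothed with a
#' 20-movement moving average. After-effect catch trials (field removed)
#' are run once per direction.
#'
#' @param cfg model configuration.
#' @param seed RNG seed.
#' @param ks spatial frequencies to run.
#' @param n_nf null-field practice trials.
#' @param n_field field-learning trials.
#' @return object of class \code{granularity_results}: per-field smoothed
#'   learning curves, final correlations and after-effect lateral
#'   deviations.
#' @export
run_granularity <- function(cfg = default_config(), seed = 1,
                            ks = c(1, 2, 4), n_nf = 80, n_field = 160) {
  set.seed(seed)
  plans <- granularity_plans(cfg)
  net0 <- select_network(nf_state_data(plans, cfg),
                         K_min = cfg$network$K_min, K_max = cfg$network$K_max,
                         K_init = cfg$network$K_init,
                         coverage = cfg$network$coverage,
                         scale_factor = cfg$network$scale_factor,
                         iter_budget = cfg$network$iter_budget,
                         n_restarts = cfg$network$n_restarts)
  nf <- force_field("NF")
  fit_nf <- run_learning(plans, nf, net0, cfg, n_trials = n_nf,
                         keep_logs = "all")
  # template per direction: hand velocity of the last null-field trial
  # there, over the movement portion of the plan
  mvw <- lapply(plans, `[[`, "measure_idx")
  templates <- vector("list", length(plans))
  for (lg in fit_nf$logs) {
    templates[[lg$plan]] <- lg$log$hand_vel[mvw[[lg$plan]], , drop = FALSE]
  }
  if (any(vapply(templates, is.null, TRUE))) {
    stop("null-field phase left some directions without a template")
  }
  fit_nf$logs <- list()

  out <- list()
  for (k in ks) {
    fld <- force_field("VFk", amplitude = cfg$fields$vfk_amplitude, k = k,
                       direction = 0)
    fit_k <- run_learning(plans, fld, fit_nf$net, cfg, n_trials = n_field,
                          keep_logs = "all")
    corr <- vapply(fit_k$logs, function(lg) {
      if (lg$log$aborted) return(NA_real_)
      velocity_correlation(lg$log$hand_vel[mvw[[lg$plan]], , drop = FALSE],
                           templates[[lg$plan]])
    }, 0)
    fit_k$logs <- list()
    ae <- vapply(seq_along(plans), function(i) {
      pr <- .probe(plans[[i]], nf, fit_k$net, cfg, 1)
      max(abs(.lateral_deviation(pr$logs[[1]]$hand, plans[[i]])))
    }, 0)
    sm <- moving_average(corr, 20)
    out[[paste0("VF", k)]] <- list(correlation = corr, smoothed = sm,
                                   final = sm[length(sm)],
                                   after_effect = ae, fit = fit_k)
  }
  structure(list(fields = out, neurons = net0$N, seed = seed,
                 templates = templates, nf_fit = fit_nf),
            class = "granularity_results")
}

#' @export
print.granularity_results <- function(x, ...) {
  cat("Field-granularity experiment (seed", x$seed, ")\n")
  cat(sprintf("  network: %d neurons (identical across fields)\n", x$neurons))
  for (nm in names(x$fields)) {
    f <- x$fields[[nm]]
    cat(sprintf("  %s: final smoothed velocity correlation %.3f, mean after-effect %.1f mm\n",
                nm, f$final, 1000 * mean(f$after_effect)))
  }
  invisible(x)
}

#' Multi-direction impedance-learning experiment
#'
#' Two point-to-point movements separated by 35 degrees, randomly
#' intermixed, performed in a divergent force field with a safety barrier.
#' Error is measured from the running mean of recent successful trials.
#' Endpoint stiffness ellipses are computed before and after learning for
#' each direction from the muscle activation at mid-movement.
#'
#' @param cfg model configuration.
#' @param seed RNG seed.
#' @param n_nf null-field practice trials.
#' @param n_df divergent-field learning trials.
#' @param n_probe probes per direction for initial exposure and stiffness.
#' @return object of class \code{impedance_results}.
#' @export
run_impedance <- function(cfg = default_config(), seed = 1,
                          n_nf = 100, n_df = 300, n_probe = 5) {
  set.seed(seed)
  plans <- impedance_plans(cfg)
  net0 <- select_network(nf_state_data(plans, cfg),
                         K_min = cfg$network$K_min, K_max = cfg$network$K_max,
                         K_init = cfg$network$K_init,
                         coverage = cfg$network$coverage,
                         scale_factor = cfg$network$scale_factor,
                         iter_budget = cfg$network$iter_budget,
                         n_restarts = cfg$network$n_restarts)
  nf <- force_field("NF")
  df <- force_field("DF", gain = cfg$fields$df_gain,
                    start = plans$D1$start, goal = plans$D1$goal,
                    barrier = cfg$fields$df_barrier,
                    barrier_damping = cfg$fields$df_barrier_damping,
                    circle_diameter = cfg$fields$df_circle_diameter)
  fit_nf <- run_learning(plans, nf, net0, cfg, n_trials = n_nf)

  stiff_at <- function(net, plan, field) {
    pr <- .probe(plan, field, net, cfg, 1)
    lg <- pr$logs[[1]]
    mid <- seq(floor(nrow(lg$u) / 3), ceiling(2 * nrow(lg$u) / 3))
    u_mid <- colMeans(lg$u[mid, , drop = FALSE])
    q_mid <- lg$q[round(nrow(lg$q) / 2), ]
    endpoint_stiffness(u_mid, q_mid, cfg)
  }
  stiff_before <- lapply(plans, function(p) stiff_at(fit_nf$net, p, nf))

  init <- lapply(plans, function(p) {
    pr <- .probe(p, df, fit_nf$net, cfg, n_probe)
    vapply(pr$logs, function(lg) {
      lat <- .lateral_deviation(lg$hand, p)
      lat[which.max(abs(lat))]
    }, 0)
  })

  fit_df <- run_learning(plans, df, fit_nf$net, cfg, n_trials = n_df,
                         adaptive_reference = TRUE)
  stiff_after <- lapply(plans, function(p) stiff_at(fit_df$net, p, df))
  final <- lapply(plans, function(p) {
    pr <- .probe(p, df, fit_df$net, cfg, n_probe)
    vapply(pr$logs, function(lg) max(abs(.lateral_deviation(lg$hand, p))), 0)
  })

  structure(list(plans = plans, neurons = net0$N, seed = seed,
                 initial_lateral = init, final_lateral = final,
                 stiffness_before = stiff_before,
                 stiffness_after = stiff_after,
                 fits = list(nf = fit_nf, df = fit_df)),
            class = "impedance_results")
}

#' @export
print.impedance_results <- function(x, ...) {
  cat("Impedance-learning experiment (seed", x$seed, ")\n")
  for (d in names(x$plans)) {
    cat(sprintf("  %s: initial |lateral| %.1f mm -> final %.1f mm; stiffness major axis %.0f -> %.0f deg\n",
                d, 1000 * mean(abs(x$initial_lateral[[d]])),
                1000 * mean(x$final_lateral[[d]]),
                x$stiffness_before[[d]]$orientation,
                x$stiffness_after[[d]]$orientation))
  }
  invisible(x)
}

#' Movement direction and lateral instability angle of a plan
#'
#' @param plan a reach plan.
#' @return list with \code{movement} and \code{lateral} angles (degrees,
#'   in (-90, 90]).
#' @export
plan_angles <- function(plan) {
  d <- plan$goal - plan$start
  mov <- atan2(d[2], d[1]) * 180 / pi
  fold <- function(a) {
    while (a <= -90) a <- a + 180
    while (a > 90) a <- a - 180
    a
  }
  list(movement = fold(mov), lateral = fold(mov + 90))
}
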