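#' One plant time step
#'
#' Advances the arm by one fixed RK4 step under a given activation and
#' environment, chaining muscle lengths, tensions, joint torques, field
#' force and forward dynamics (activation is held within the step). This is
#' the reference implementation of the per-step loop; whole trials are run
#' by the compiled engine in \code{\link{simulate_trial}}, which is tested
#' against it.
#'
#' @param state \code{\link{arm_state}}.
#' @param u muscle activations (length 6, >= 0).
#' @param field \code{\link{force_field}}.
#' @param dt time step (s), > 0.
#' @param arm \code{\link{arm_parameters}}.
#' @param geom \code{\link{muscle_geometry}}.
#' @param muscle \code{\link{muscle_parameters}}.
#' @param speed_limit hand speed (m/s) above which the trial is flagged
#'   divergent.
#' @param l_r,ldot_r reference muscle lengths and rates (the descending
#'   equilibrium trajectory around which muscle impedance acts), held
#'   constant within the step; default: the static rest lengths.
#' @return list: \code{state} (next \code{arm_state}), \code{log} (row with
#'   l, ldot, u, tensions, field force, hand position/velocity), and
#'   \code{diverged}.
#' @export
plant_step <- function(state, u, field, dt, arm, geom,
                 muscle = muscle_parameters(), speed_limit = 8,
                 l_r = geom$l0, ldot_r = rep(0, 6)) {
  if (dt <= 0) stop("dt must be positive")
  deriv <- function(q, qdot) {
    st <- arm_state(q, qdot, state$time)
    ml <- muscle_lengths(st, geom)
    T_m <- muscle_tension(u, ml$l, ml$ldot, geom, muscle, l_r, ldot_r)
    tau <- joint_torque(T_m, geom)
    p <- forward_kinematics(q, arm)
    v <- drop(jacobian(q, arm) %*% qdot)
    F <- field_force(field, p, v)
    list(qdd = forward_dynamics(st, tau, F, arm), T_m = T_m, F = F,
         l = ml$l, ldot = ml$ldot, p = p, v = v)
  }
  d1 <- deriv(state$q, state$qdot)
  d2 <- deriv(state$q + dt / 2 * state$qdot,
              state$qdot + dt / 2 * d1$qdd)
  k2q <- state$qdot + dt / 2 * d1$qdd
  d3 <- deriv(state$q + dt / 2 * k2q, state$qdot + dt / 2 * d2$qdd)
  k3q <- state$qdot + dt / 2 * d2$qdd
  d4 <- deriv(state$q + dt * k3q, state$qdot + dt * d3$qdd)
  k4q <- state$qdot + dt * d3$qdd
  q_new <- state$q + dt / 6 * (state$qdot + 2 * k2q + 2 * k3q + k4q)
  qd_new <- state$qdot + dt / 6 * (d1$qdd + 2 * d2$qdd + 2 * d3$qdd + d4$qdd)
  sp <- sqrt(sum(d1$v^2))
  list(state = arm_state(q_new, qd_new, state$time + dt),
       log = c(l = d1$l, ldot = d1$ldot, u = u, tension = d1$T_m,
               F_ext = d1$F, hand = d1$p, hand_vel = d1$v),
       diverged = !is.finite(sp) || sp > speed_limit)
}

#' Simulate one trial
#'
#' Runs a whole reference plan through the closed loop: RBF feedforward,
#' delayed V-shaped feedback, band-limited signal-dependent noise, muscle
#' visco-elasticity and rigid-body dynamics, in a given environment. The
#' arm starts at the plan's initial state. Noise draws are taken from the
#' current R RNG stream, so the trial is reproducible under
#' \code{set.seed}.
#'
#' @param plan \code{reference_plan} (or a list with \code{q}, \code{qdot}
#'   reference matrices on the plan's grid, e.g. an empirical-mean
#'   reference).
#' @param net \code{\link{rbf_network}}.
#' @param field \code{\link{force_field}}.
#' @param cfg model configuration, see \code{\link{default_config}}.
#' @param engine \code{"cpp"} (compiled loop) or \code{"R"} (step-by-step
#'   reference implementation; slow, used for validation).
#' @return list of per-step logs (class \code{trial_log}): state, hand,
#'   errors, delayed sliding error \code{eps}, delay-compensated sliding
#'   error \code{s}, commands, tensions, field force, basis activations
#'   \code{G}, and the abort flag.
#' @export
simulate_trial <- function(plan, net, field, cfg, engine = c("cpp", "R")) {
  engine <- match.arg(engine)
  dt <- cfg$simulation$dt
  Tn <- nrow(plan$q)
  Z <- matrix(stats::rnorm(Tn * 6), Tn, 6)
  gains <- cfg$gains
  delay_steps <- as.integer(round(gains$delay / dt))
  alpha <- exp(-2 * pi * cfg$noise$cutoff_hz * dt)
  fld <- field
  if (fld$variant == "VFk") {
    g <- fld$amplitude * sin(fld$k * fld$direction)
    fld <- force_field("VF", B = matrix(c(0, g, -g, 0), 2, 2))
  }
  ftype <- switch(fld$variant, NF = 0L, VF = 1L, DF = 3L)
  Bf <- if (ftype == 1L) fld$B else matrix(0, 2, 2)
  df_par <- if (ftype == 3L) {
    c(fld$gain, fld$start, fld$goal, fld$axis, fld$barrier,
      fld$barrier_damping, fld$circle_radius)
  } else numeric(10)
  if (engine == "cpp") {
    arm <- cfg$arm
    res <- .simulate_trial_cpp(
      c(arm$L, arm$m, arm$lc, arm$I), arm$B, cfg$geometry$A,
      cfg$geometry$q_ref,
      unlist(cfg$muscle[c("T0", "k0", "k1", "b0", "b1", "rho")]),
      net$centers, net$widths, net$scaling$center, net$scaling$sd, net$W,
      c(gains$stretch_slope, gains$shorten_slope, gains$kappa),
      delay_steps, plan$q, plan$qdot, ftype, Bf, df_par,
      dt, cfg$noise$coef, alpha, Z, plan$q[1, ], plan$qdot[1, ],
      cfg$simulation$speed_limit)
  } else {
    res <- .simulate_trial_r(plan, net, fld, cfg, Z, delay_steps, alpha)
  }
  res$s <- res$e + gains$kappa * res$edot
  res$time <- (seq_len(Tn) - 1) * dt
  res$dt <- dt
  class(res) <- "trial_log"
  res
}

# Pure-R trial loop mirroring the compiled engine exactly (same noise
# stream layout); used to validate the compiled path.
.simulate_trial_r <- function(plan, net, field, cfg, Z, delay_steps, alpha) {
  dt <- cfg$simulation$dt
  Tn <- nrow(plan$q)
  gains <- cfg$gains
  geom <- cfg$geometry
  nm <- sqrt(1 - alpha^2)
  out <- list(q = matrix(0, Tn, 2), qdot = matrix(0, Tn, 2),
              hand = matrix(0, Tn, 2), hand_vel = matrix(0, Tn, 2),
              e = matrix(0, Tn, 6), edot = matrix(0, Tn, 6),
              eps = matrix(0, Tn, 6), u_ff = matrix(0, Tn, 6),
              u_fb = matrix(0, Tn, 6), u = matrix(0, Tn, 6),
              tension = matrix(0, Tn, 6), F_ext = matrix(0, Tn, 2),
              G = matrix(0, Tn, net$N), aborted = FALSE, abort_step = -1L)
  st <- arm_state(plan$q[1, ], plan$qdot[1, ])
  nstate <- numeric(6)
  for (t in seq_len(Tn)) {
    out$e[t, ] <- -drop(crossprod(geom$A, st$q - plan$q[t, ]))
    out$edot[t, ] <- -drop(crossprod(geom$A, st$qdot - plan$qdot[t, ]))
    eps <- if (t > delay_steps) {
      sliding_error(out$e[seq_len(t), , drop = FALSE],
                    out$edot[seq_len(t), , drop = FALSE],
                    gains$kappa, gains$delay, (t - 1) * dt, dt)
    } else rep(0, 6)
    out$eps[t, ] <- eps
    u_fb <- vshape_feedback(eps, gains)
    g <- rbf_basis(net, c(st$q, st$qdot))
    out$G[t, ] <- g
    u_ff <- pmax(0, drop(net$W %*% g))
    udes <- u_ff + u_fb
    nstate <- alpha * nstate + nm * cfg$noise$coef * udes * Z[t, ]
    u <- pmax(0, udes + nstate)
    out$u_ff[t, ] <- u_ff; out$u_fb[t, ] <- u_fb; out$u[t, ] <- u
    out$q[t, ] <- st$q; out$qdot[t, ] <- st$qdot
    ref_ml <- muscle_lengths(arm_state(plan$q[t, ], plan$qdot[t, ]), geom)
    stp <- plant_step(st, u, field, dt, cfg$arm, geom, cfg$muscle,
                      cfg$simulation$speed_limit, ref_ml$l, ref_ml$ldot)
    out$tension[t, ] <- stp$log[paste0("tension", 1:6)]
    out$F_ext[t, ] <- stp$log[c("F_ext1", "F_ext2")]
    out$hand[t, ] <- stp$log[c("hand1", "hand2")]
    out$hand_vel[t, ] <- stp$log[c("hand_vel1", "hand_vel2")]
    if (stp$diverged) {
      out$aborted <- TRUE
      out$abort_step <- t
      break
    }
    st <- stp$state
  }
  out
}

#' @export
print.trial_log <- function(x, ...) {
  cat(sprintf("trial log: %d steps of %.0f ms%s\n", nrow(x$q), x$dt * 1000,
              if (x$aborted) sprintf(" (ABORTED at step %d)", x$abort_step) else ""))
  invisible(x)
}

#' Co-activation index of a trial
#'
#' Time-averaged overlap of feedforward activation within each antagonist
#' pair, summed over the three pairs: \code{sum_p mean_t min(u_i, u_j)}.
#' Torque cancels inside a pair, so this measures activation spent purely
#' on impedance.
#'
#' @param u_ff T x 6 feedforward activation matrix.
#' @return scalar index.
#' @export
coactivation_index <- function(u_ff) {
  pairs <- list(c(1, 2), c(3, 4), c(5, 6))
  sum(vapply(pairs, function(p) mean(pmin(u_ff[, p[1]], u_ff[, p[2]])), 0))
}

#' Fit the feedforward model by trial-by-trial learning
#'
#' The central fitting routine: simulates a sequence of trials in an
#' environment and updates the RBF weights between trials by the V-shaped
#' gradient-descent law (accumulated error drive minus uniform decay,
#' clipped at zero). Returns a fitted \code{motor_adaptation} object with
#' the usual methods (\code{print}, \code{summary}, \code{coef},
#' \code{predict}, \code{simulate}, \code{plot}, \code{residuals}).
#'
#' @param plans list of \code{reference_plan}s (the movement repertoire).
#' @param field \code{\link{force_field}} the trials are performed in. For
#'   VFk fields the per-trial direction is taken from each plan's
#'   \code{direction} attribute.
#' @param net starting \code{\link{rbf_network}} (centers frozen; only
#'   weights adapt).
#' @param cfg model configuration (see \code{\link{default_config}}).
#' @param n_trials number of trials.
#' @param schedule integer vector (length \code{n_trials}) of plan indices;
#'   by default plans are presented in random order.
#' @param adaptive_reference use the running mean of the last few
#'   successful trials (per plan) as the reference trajectory, warm-started
#'   with the plan itself; the convention for unstable tasks where error is
#'   measured from the mean trajectory.
#' @param ref_window number of successful trials in the running mean.
#' @param keep_logs \code{"none"}, \code{"ends"} (first/last trial per
#'   plan) or \code{"all"}.
#' @param learn if \code{FALSE}, weights are frozen (probe/catch trials).
#' @return fitted object of class \code{motor_adaptation}.
#' @export
run_learning <- function(plans, field, net, cfg, n_trials,
                         schedule = NULL, adaptive_reference = FALSE,
                         ref_window = 5, keep_logs = c("none", "ends", "all"),
                         learn = TRUE) {
  keep_logs <- match.arg(keep_logs)
  if (inherits(plans, "reference_plan")) plans <- list(plans)
  if (is.null(schedule)) {
    schedule <- if (n_trials > 0) sample(rep_len(seq_along(plans), n_trials)) else integer(0)
  }
  stopifnot(length(schedule) == n_trials)
  lcfg <- cfg$learning
  dt <- cfg$simulation$dt
  refs <- lapply(plans, function(p) list(q = p$q, qdot = p$qdot, hist = list()))
  hist <- vector("list", n_trials)
  logs <- list()
  for (k in seq_len(n_trials)) {
    pid <- schedule[k]
    plan <- plans[[pid]]
    ref_plan <- plan
    if (adaptive_reference) {
      ref_plan$q <- refs[[pid]]$q
      ref_plan$qdot <- refs[[pid]]$qdot
    }
    fld <- field
    if (fld$variant == "VFk") fld$direction <- attr(plan, "direction")
    if (fld$variant == "DF") {
      fld <- force_field("DF", gain = fld$gain, start = plan$start,
                         goal = plan$goal, barrier = fld$barrier,
                         barrier_damping = fld$barrier_damping,
                         circle_diameter = 2 * fld$circle_radius)
    }
    tr <- simulate_trial(ref_plan, net, fld, cfg)
    err <- sqrt(rowSums((tr$hand - plan$pos)^2))
    lat <- .lateral_deviation(tr$hand, plan)
    success <- !tr$aborted &&
      sqrt(sum((tr$hand[nrow(tr$hand), ] - plan$pos[nrow(plan$pos), ])^2)) <=
        cfg$simulation$success_radius &&
      (fld$variant != "DF" || max(abs(lat)) < fld$barrier)
    if (learn && !tr$aborted && !anyNA(tr$s)) {
      s_learn <- tr$s
      if (adaptive_reference) {
        # on-line control uses the error from the mean trajectory, but the
        # feedforward update is driven by the error from the intended path
        A <- cfg$geometry$A
        e_p <- -(tr$q - plan$q) %*% A
        edot_p <- -(tr$qdot - plan$qdot) %*% A
        s_learn <- e_p + cfg$gains$kappa * edot_p
      }
      D <- lcfg$stretch_slope * pmax(s_learn, 0) -
        lcfg$shorten_slope * pmin(s_learn, 0)
      dW <- lcfg$eta * lcfg$Q * dt * crossprod(D, tr$G)   # 6 x N
      dec <- if (lcfg$decay == "uniform") lcfg$gamma else lcfg$gamma * net$W
      net$W <- pmax(net$W + dW - dec, 0)
    }
    if (adaptive_reference && success) {
      h <- refs[[pid]]$hist
      h[[length(h) + 1]] <- list(q = tr$q, qdot = tr$qdot)
      if (length(h) > ref_window) h <- h[-1]
      refs[[pid]]$hist <- h
      refs[[pid]]$q <- Reduce(`+`, lapply(h, `[[`, "q")) / length(h)
      refs[[pid]]$qdot <- Reduce(`+`, lapply(h, `[[`, "qdot")) / length(h)
    }
    hist[[k]] <- data.frame(
      trial = k, plan = pid, aborted = tr$aborted, success = success,
      error = mean(err), max_lateral = max(abs(lat)),
      mean_lateral = mean(abs(lat)),
      cost = cost(tr$s, tr$u_ff, lcfg, dt),
      weight_norm = sqrt(sum(net$W^2)),
      coactivation = coactivation_index(tr$u_ff))
    if (keep_logs == "all" ||
        (keep_logs == "ends" && (k <= length(plans) || k > n_trials - length(plans)))) {
      logs[[length(logs) + 1]] <- list(trial = k, plan = pid, log = tr)
    }
  }
  structure(list(net = net, history = do.call(rbind, hist), plans = plans,
                 field = field, cfg = cfg, logs = logs,
                 references = if (adaptive_reference) refs else NULL,
                 n_trials = n_trials),
            class = "motor_adaptation")
}

# signed lateral deviation of the hand from a plan's geometry: distance to
# the start-goal line for reaches, radial error for circles
.lateral_deviation <- function(hand, plan) {
  if (identical(plan$kind, "circle")) {
    sqrt(rowSums(sweep(hand, 2, plan$center)^2)) - plan$radius
  } else if (!is.null(plan$start)) {
    d <- plan$goal - plan$start
    u <- d / sqrt(sum(d^2))
    n <- c(-u[2], u[1])
    drop(sweep(hand, 2, plan$start) %*% n)
  } else {
    sqrt(rowSums((hand - plan$pos)^2))
  }
}
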