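#' @export
print.motor_adaptation <- function(x, ...) {
  h <- x$history
  cat("Motor adaptation fit\n")
  cat(sprintf("  environment: %s, %d trials over %d movement plan(s)\n",
              x$field$variant, x$n_trials, length(x$plans)))
  cat(sprintf("  network: %d neurons, weight norm %.4f\n",
              x$net$N, sqrt(sum(x$net$W^2))))
  if (!is.null(h) && nrow(h) > 0) {
    n10 <- max(1, round(nrow(h) / 10))
    cat(sprintf("  mean hand error: %.2f mm (first %d trials) -> %.2f mm (last %d)\n",
                1000 * mean(h$error[seq_len(n10)]), n10,
                1000 * mean(h$error[seq(nrow(h) - n10 + 1, nrow(h))]), n10))
  }
  invisible(x)
}

#' @export
summary.motor_adaptation <- function(object, ...) {
  h <- object$history
  n10 <- max(1, round(nrow(h) / 10))
  first <- h[seq_len(n10), ]
  last <- h[seq(nrow(h) - n10 + 1, nrow(h)), ]
  out <- list(
    n_trials = object$n_trials,
    field = object$field$variant,
    neurons = object$net$N,
    weight_norm = sqrt(sum(object$net$W^2)),
    error_first = mean(first$error), error_last = mean(last$error),
    lateral_first = mean(first$max_lateral), lateral_last = mean(last$max_lateral),
    coactivation_first = mean(first$coactivation),
    coactivation_last = mean(last$coactivation),
    cost_last = mean(last$cost),
    aborted = sum(h$aborted)
  )
  class(out) <- "summary.motor_adaptation"
  out
}

#' @export
print.summary.motor_adaptation <- function(x, ...) {
  cat(sprintf("Motor adaptation over %d trials in %s (%d neurons)\n",
              x$n_trials, x$field, x$neurons))
  cat(sprintf("  mean hand error     : %.2f -> %.2f mm\n",
              1000 * x$error_first, 1000 * x$error_last))
  cat(sprintf("  max lateral dev     : %.2f -> %.2f mm\n",
              1000 * x$lateral_first, 1000 * x$lateral_last))
  cat(sprintf("  co-activation index : %.4f -> %.4f\n",
              x$coactivation_first, x$coactivation_last))
  cat(sprintf("  weight norm %.4f, aborted trials %d\n",
              x$weight_norm, x$aborted))
  invisible(x)
}

#' @export
coef.motor_adaptation <- function(object, ...) object$net$W

#' @export
residuals.motor_adaptation <- function(object, ...) object$history$error

#' Predict feedforward activations at new states
#'
#' @param object fitted \code{motor_adaptation}.
#' @param newdata matrix of joint states (rows of q1, q2, qd1, qd2).
#' @param ... unused.
#' @return matrix (rows = states, columns = 6 muscles) of feedforward
#'   activations.
#' @export
predict.motor_adaptation <- function(object, newdata, ...) {
  newdata <- rbind(newdata)
  out <- t(apply(newdata, 1, function(x) rbf_evaluate(object$net, x)))
  colnames(out) <- c("sh_flex", "sh_ext", "el_flex", "el_ext",
                     "bi_flex", "bi_ext")
  out
}

#' Simulate catch or probe trials from a fitted model
#'
#' Runs trials with the learned weights frozen, optionally in a different
#' environment (e.g. the field silently removed for after-effect trials).
#'
#' @param object fitted \code{motor_adaptation}.
#' @param nsim number of trials.
#' @param seed optional RNG seed.
#' @param plan reference plan (defaults to the first fitted plan).
#' @param field environment (defaults to the fitted one); pass
#'   \code{force_field("NF")} for after-effect trials.
#' @param ... unused.
#' @return list of \code{trial_log}s.
#' @export
simulate.motor_adaptation <- function(object, nsim = 1, seed = NULL,
                                      plan = NULL, field = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(plan)) plan <- object$plans[[1]]
  if (is.null(field)) field <- object$field
  if (field$variant == "VFk" && is.null(field$direction)) {
    field$direction <- attr(plan, "direction")
  }
  lapply(seq_len(nsim), function(i) {
    simulate_trial(plan, object$net, field, object$cfg)
  })
}

#' Plot learning curve and hand paths
#'
#' @param x fitted \code{motor_adaptation}.
#' @param which \code{"curve"} (per-trial hand error) or \code{"paths"}
#'   (hand paths of the kept trial logs over the references).
#' @param ... passed to the underlying plot call.
#' @export
plot.motor_adaptation <- function(x, which = c("curve", "paths"), ...) {
  which <- match.arg(which)
  if (which == "curve") {
    graphics::plot(x$history$trial, 1000 * x$history$error, type = "l",
                   xlab = "trial", ylab = "mean hand error (mm)", ...)
  } else {
    if (length(x$logs) == 0) stop("no trial logs kept; refit with keep_logs")
    rng <- do.call(rbind, lapply(x$plans, function(p) p$pos))
    graphics::plot(rng[, 1], rng[, 2], type = "n", asp = 1,
                   xlab = "x (m)", ylab = "y (m)", ...)
    for (p in x$plans) {
      graphics::lines(p$pos[, 1], p$pos[, 2], col = "grey70", lty = 2)
    }
    for (lg in x$logs) {
      graphics::lines(lg$log$hand[, 1], lg$log$hand[, 2], col = "steelblue")
    }
  }
  invisible(x)
}
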