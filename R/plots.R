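#' Render summary figures for an experiment results bundle
#'
#' Writes deterministic base-graphics figures from a results object:
#' probe hand paths per phase for the generalization experiment, learning
#' curves per field for the granularity experiment, and trajectories for
#' the impedance-learning experiment.
#'
#' @param results a \code{generalization_results}, \code{granularity_results} or
#'   \code{impedance_results} object.
#' @param dir output directory.
#' @return invisibly, the paths of the files written.
#' @export
plot_figures <- function(results, dir = ".") {
  if (is.null(results) || length(results) == 0) {
    stop("empty results bundle")
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  if (inherits(results, "generalization_results")) {
    f <- file.path(dir, "generalization.pdf")
    grDevices::pdf(f, width = 9, height = 6)
    graphics::par(mfrow = c(2, 3), mar = c(3, 3, 2, 1))
    for (nm in names(results$probes)) {
      pr <- results$probes[[nm]]
      if (length(pr$logs) == 0) {
        warning("missing phase in bundle: ", nm)
        next
      }
      graphics::plot(NA, xlim = c(-0.15, 0.15) + 0,
                     ylim = c(0.25, 0.55), asp = 1, main = nm,
                     xlab = "", ylab = "")
      for (lg in pr$logs) {
        graphics::lines(lg$hand[, 1], lg$hand[, 2], col = "steelblue")
      }
      r <- results$ratios$ratio[results$ratios$phase == nm]
      graphics::mtext(sprintf("ratio %.2f", r), side = 3, line = -1.2,
                      adj = 0.95, cex = 0.7)
    }
    grDevices::dev.off()
    files <- c(files, f)
  } else if (inherits(results, "granularity_results")) {
    f <- file.path(dir, "granularity.pdf")
    grDevices::pdf(f, width = 6, height = 4)
    graphics::plot(NA, xlim = c(1, length(results$fields[[1]]$smoothed)),
                   ylim = c(0, 1), xlab = "field trial",
                   ylab = "velocity correlation (20-trial MA)")
    cols <- c("black", "steelblue", "firebrick")
    i <- 0
    for (nm in names(results$fields)) {
      i <- i + 1
      graphics::lines(results$fields[[nm]]$smoothed, col = cols[i])
    }
    graphics::abline(h = 0.9, lty = 3)
    graphics::legend("bottomright", names(results$fields), col = cols[seq_len(i)],
                     lty = 1, bty = "n")
    grDevices::dev.off()
    files <- c(files, f)
  } else if (inherits(results, "impedance_results")) {
    f <- file.path(dir, "impedance.pdf")
    grDevices::pdf(f, width = 6, height = 6)
    graphics::plot(NA, xlim = c(-0.25, 0.1), ylim = c(0.25, 0.58), asp = 1,
                   xlab = "x (m)", ylab = "y (m)",
                   main = "divergent-field movements")
    cols <- c(D1 = "steelblue", D2 = "firebrick")
    for (d in names(results$plans)) {
      p <- results$plans[[d]]
      graphics::lines(p$pos[, 1], p$pos[, 2], col = cols[[d]], lty = 2)
    }
    grDevices::dev.off()
    files <- c(files, f)
  } else {
    stop("unrecognised results object")
  }
  invisible(files)
}
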