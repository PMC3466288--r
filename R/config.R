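#' Default model configuration
#'
#' Assembles the full parameter tree of the simulation: arm rigid-body
#' constants, muscle geometry and visco-elasticity, feedback gains,
#' learning rates, noise, integration settings, network-selection settings
#' and the force-field gain constants. All values can be overridden through
#' a YAML file (\code{\link{load_config}}); the shipped file
#' \code{system.file("extdata", "default_config.yaml", package =
#' "impedadapt")} mirrors these defaults with units in comments.
#'
#' @return nested list of class \code{impedadapt_config}.
#' @export
default_config <- function() {
  structure(list(
    arm = arm_parameters(),
    geometry = muscle_geometry(),
    muscle = muscle_parameters(),
    gains = vshape_gains(),
    learning = learning_config(),
    noise = list(coef = 0.02, cutoff_hz = 10),
    simulation = list(dt = 0.001, speed_limit = 8, success_radius = 0.0125),
    network = list(K_min = 3, K_max = 80, K_init = 20, coverage = 0.85,
                   scale_factor = c(1.5, 1.5, 2.5, 2.5),
                   iter_budget = 2000, n_restarts = 3),
    fields = list(vf_B = c(-10.1, -11.2, -11.2, 11.1),
                  vfk_amplitude = 70, df_gain = 600,
                  df_barrier = 0.05, df_barrier_damping = 50,
                  df_circle_diameter = 0.025),
    workspace = list(center = c(0, 0.40))
  ), class = "impedadapt_config")
}

#' Curl gain matrix of the velocity-dependent field
#'
#' \code{B = g * [[0, 1], [-1, 0]]}: forces rotate the hand velocity
#' clockwise for positive g.
#'
#' @param g curl gain (N s/m).
#' @return 2x2 matrix.
#' @export
curl_matrix <- function(g) matrix(c(0, -g, g, 0), 2, 2)

.config_schema <- function() {
  list(
    arm = list(L = 2, m = 2, lc = 2, I = 2, B = 4,
               q_lim = 4),
    geometry = list(A = 12, l0 = 6, q_ref = 2),
    muscle = list(T0 = 1, k0 = 1, k1 = 1, b0 = 1, b1 = 1, rho = 1),
    gains = list(stretch_slope = 1, shorten_slope = 1, kappa = 1, delay = 1),
    learning = list(eta = 1, Q = 1, R = 1, gamma = 1, stretch_slope = 1,
                    shorten_slope = 1, decay = 1),
    noise = list(coef = 1, cutoff_hz = 1),
    simulation = list(dt = 1, speed_limit = 1, success_radius = 1),
    network = list(K_min = 1, K_max = 1, K_init = 1, coverage = 1,
                   scale_factor = 4, iter_budget = 1, n_restarts = 1),
    fields = list(vf_B = 4, vfk_amplitude = 1, df_gain = 1,
                  df_barrier = 1, df_barrier_damping = 1,
                  df_circle_diameter = 1),
    workspace = list(center = 2)
  )
}

#' Load and validate a configuration file
#'
#' Reads a YAML configuration, checks that every key is known, that all
#' required keys are present and that physical values are in range, and
#' returns the assembled \code{impedadapt_config}. Matrix-valued entries
#' (arm viscosity \code{B}, moment arms \code{A}, joint limits) are given
#' in column-major flattened form.
#'
#' @param path path to a YAML file.
#' @return \code{impedadapt_config}.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  schema <- .config_schema()
  unknown_sec <- setdiff(names(raw), names(schema))
  if (length(unknown_sec)) {
    stop("unknown config section(s): ", paste(unknown_sec, collapse = ", "))
  }
  missing_sec <- setdiff(names(schema), names(raw))
  if (length(missing_sec)) {
    stop("missing required config section(s): ",
         paste(missing_sec, collapse = ", "))
  }
  for (sec in names(schema)) {
    unknown <- setdiff(names(raw[[sec]]), names(schema[[sec]]))
    if (length(unknown)) {
      stop(sprintf("unknown key(s) in section '%s': %s", sec,
                   paste(unknown, collapse = ", ")))
    }
    miss <- setdiff(names(schema[[sec]]), names(raw[[sec]]))
    if (length(miss)) {
      stop(sprintf("missing required key(s) in section '%s': %s", sec,
                   paste(miss, collapse = ", ")))
    }
    for (key in names(schema[[sec]])) {
      v <- raw[[sec]][[key]]
      want <- schema[[sec]][[key]]
      if (key == "decay") next
      if (!is.numeric(v) || length(v) != want || anyNA(v)) {
        stop(sprintf("key '%s/%s' must be numeric of length %d", sec, key, want))
      }
    }
  }
  cfg <- list(
    arm = arm_parameters(L = raw$arm$L, m = raw$arm$m, lc = raw$arm$lc,
                         I = raw$arm$I, B = matrix(raw$arm$B, 2, 2),
                         q_lim = matrix(raw$arm$q_lim, 2, 2)),
    geometry = muscle_geometry(A = matrix(raw$geometry$A, 2, 6),
                               l0 = raw$geometry$l0,
                               q_ref = raw$geometry$q_ref),
    muscle = do.call(muscle_parameters, raw$muscle),
    gains = do.call(vshape_gains, raw$gains),
    learning = do.call(learning_config, raw$learning),
    noise = raw$noise,
    simulation = raw$simulation,
    network = raw$network,
    fields = raw$fields,
    workspace = raw$workspace
  )
  .validate_extra(cfg)
  structure(cfg, class = "impedadapt_config")
}

.validate_extra <- function(cfg) {
  if (cfg$noise$coef < 0) stop("key 'noise/coef' must be >= 0")
  if (cfg$noise$cutoff_hz <= 0) stop("key 'noise/cutoff_hz' must be > 0")
  if (cfg$simulation$dt <= 0) stop("key 'simulation/dt' must be > 0")
  with(cfg$network, {
    if (!(K_min >= 1 && K_min <= K_init && K_init <= K_max)) {
      stop("network K bounds must satisfy 1 <= K_min <= K_init <= K_max")
    }
  })
  with(cfg$fields, {
    if (df_gain < 0) stop("key 'fields/df_gain' must be >= 0")
    if (df_barrier <= 0) stop("key 'fields/df_barrier' must be > 0")
  })
  invisible(TRUE)
}

#' @export
print.impedadapt_config <- function(x, ...) {
  cat("impedadapt configuration\n")
  cat(sprintf("  arm: L = (%.2f, %.2f) m, dt = %.0f ms, delay = %.0f ms\n",
              x$arm$L[1], x$arm$L[2], x$simulation$dt * 1000,
              x$gains$delay * 1000))
  cat(sprintf("  fields: VF B [%s] N s/m, VFk amplitude %.1f N s/m, DF %.0f N/m\n",
              paste(format(x$fields$vf_B), collapse = " "),
              x$fields$vfk_amplitude, x$fields$df_gain))
  invisible(x)
}

#' Save a results bundle to a directory
#'
#' Writes a manifest (JSON: seed, trial counts, checksums, config
#' snapshot), the trial history as a columnar text table, and the numeric
#' arrays (network, logs) in an exact binary container so that
#' \code{\link{load_bundle}} restores them bit-identically.
#'
#' @param results named list; data.frames are written as TSV, everything
#'   else into the binary container.
#' @param dir output directory (created if needed).
#' @param seed master seed recorded in the manifest.
#' @return invisibly, the manifest list.
#' @export
save_bundle <- function(results, dir, seed = NA) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tabs <- Filter(is.data.frame, results)
  rest <- results[setdiff(names(results), names(tabs))]
  files <- character(0)
  for (nm in names(tabs)) {
    f <- file.path(dir, paste0(nm, ".tsv"))
    utils::write.table(tabs[[nm]], f, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    files <- c(files, f)
  }
  if (length(rest)) {
    f <- file.path(dir, "arrays.rds")
    saveRDS(rest, f, version = 2)
    files <- c(files, f)
  }
  manifest <- list(
    package = "impedadapt",
    version = as.character(utils::packageVersion("impedadapt")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    components = basename(files),
    checksums = as.list(tools::md5sum(files))
  )
  names(manifest$checksums) <- basename(files)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Load a results bundle
#'
#' Verifies the manifest checksums and restores tables and arrays.
#'
#' @param dir bundle directory.
#' @return named list of restored components plus \code{manifest}.
#' @export
load_bundle <- function(dir) {
  mf <- file.path(dir, "manifest.json")
  if (!file.exists(mf)) stop("no manifest.json in ", dir)
  manifest <- jsonlite::read_json(mf, simplifyVector = TRUE)
  out <- list(manifest = manifest)
  missing <- character(0)
  for (comp in manifest$components) {
    f <- file.path(dir, comp)
    if (!file.exists(f)) {
      missing <- c(missing, comp)
      next
    }
    sum_now <- unname(tools::md5sum(f))
    if (!identical(sum_now, manifest$checksums[[comp]])) {
      stop("checksum mismatch for bundle component: ", comp)
    }
    if (grepl("\\.tsv$", comp)) {
      out[[sub("\\.tsv$", "", comp)]] <-
        utils::read.table(f, header = TRUE, sep = "\t")
    } else if (comp == "arrays.rds") {
      out <- c(out, readRDS(f))
    }
  }
  if (length(missing)) {
    stop("bundle incomplete; missing component(s): ",
         paste(missing, collapse = ", "))
  }
  out
}
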