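#' Record a time-series row from the current state
#'
#' Exact counts from the registry plus the per-iteration division, death and
#' treatment tallies; the tallies are reset afterwards so the next row
#' starts from zero.
#'
#' @param sim a `tumor_sim`.
#' @param t iteration label for the row; defaults to the simulation's
#'   completed iteration count.
#' @return a one-row data.frame with the [sim_run()] trajectory columns.
#' @export
record_counts <- function(sim, t = NULL) {
  row <- sim_counts(sim, reset = TRUE)
  if (!is.null(t)) row$iteration <- as.integer(t)
  row
}

slice_categories <- c("empty", "healthy", "dcc", "csc")

#' Central 2D cross-section of the lattice
#'
#' The plane through `index` (default `side %/% 2`, the central section)
#' perpendicular to `axis`, with each site classified as empty, healthy,
#' DCC or CSC.
#'
#' @param sim a `tumor_sim`.
#' @param axis `"x"`, `"y"` or `"z"`.
#' @param index 0-based plane coordinate; default `side %/% 2`.
#' @return an object of class `ca_slice`: an integer side x side matrix
#'   (codes 0-3, level names in attribute `categories`) with `axis` and
#'   `index` attributes.
#' @export
central_slice <- function(sim, axis = c("z", "x", "y"), index = NULL) {
  stopifnot(inherits(sim, "tumor_sim"))
  axis <- match.arg(axis)
  if (is.null(index)) index <- sim$side %/% 2L
  if (index < 0 || index >= sim$side) stop("`index` out of bounds")
  occ <- sim_occupancy(sim)
  m <- switch(axis,
              x = occ[index + 1L, , ],
              y = occ[, index + 1L, ],
              z = occ[, , index + 1L])
  structure(m, class = "ca_slice", axis = axis, index = index,
            categories = slice_categories)
}

#' @export
print.ca_slice <- function(x, ...) {
  tab <- table(factor(as.vector(x), levels = 0:3, labels = slice_categories))
  cat(sprintf("<ca_slice> axis %s, plane %d, %dx%d: %s\n",
              attr(x, "axis"), attr(x, "index"), nrow(x), ncol(x),
              paste(names(tab), tab, sep = "=", collapse = " ")))
  invisible(x)
}

#' Write / read a trajectory as CSV
#'
#' One row per iteration with a header naming every field; reading restores
#' all counts bit-exactly.
#'
#' @param rows a trajectory data.frame from [sim_run()].
#' @param path file path.
#' @return `write_timeseries` returns `path` invisibly; `read_timeseries`
#'   returns the data.frame.
#' @export
write_timeseries <- function(rows, path) {
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_timeseries
#' @export
read_timeseries <- function(path) {
  utils::read.csv(path)
}

#' Write a cross-section snapshot
#'
#' CSV writes the raw category-code matrix; PGM writes a plain-text (P2)
#' grayscale image with fixed gray levels per category (empty 0, healthy
#' 170, DCC 85, CSC 255).
#'
#' @param snapshot a `ca_slice`.
#' @param path file path.
#' @param format `"csv"` or `"pgm"`.
#' @return `path`, invisibly.
#' @export
write_slice <- function(snapshot, path, format = c("csv", "pgm")) {
  format <- match.arg(format)
  m <- unclass(snapshot)
  if (format == "csv") {
    utils::write.table(m, path, sep = ",", row.names = FALSE,
                       col.names = FALSE)
  } else {
    gray <- c(0L, 170L, 85L, 255L)[m + 1L]
    dim(gray) <- dim(m)
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("P2", sprintf("%d %d", ncol(m), nrow(m)), "255"), con)
    writeLines(apply(gray, 1, paste, collapse = " "), con)
  }
  invisible(path)
}

config_run_keys <- c("side", "iterations", "seed")
config_csc_keys <- c("fraction", "p_s", "exempt_random_death")
config_treatment_keys <- c("mode", "start", "end", "period", "pulse_duration",
                           "kill_prob", "threshold_fraction", "exact")

#' Default JSON-able configuration
#'
#' @param side grid side.
#' @param iterations iteration budget.
#' @param seed RNG seed (mandatory in any loaded config).
#' @return a nested list with `run`, `params`, `csc` and `treatment`
#'   sections, ready for [save_config()].
#' @export
default_config <- function(side = 50, iterations = 6000, seed = 1) {
  p <- hallmark_params()
  list(run = list(side = side, iterations = iterations, seed = seed),
       params = unclass(p),
       csc = list(fraction = 0.01, p_s = p$p_s, exempt_random_death = TRUE),
       treatment = list(mode = "none", start = 1, end = Inf, period = 100,
                        pulse_duration = 100, kill_prob = 0,
                        threshold_fraction = 0, exact = FALSE))
}

#' Save / load a simulation configuration as JSON
#'
#' The JSON document has explicit keys for every parameter and the RNG
#' seed. `load_config` validates strictly: unknown keys anywhere are
#' rejected, and a missing `seed` is an error.
#'
#' @param config a configuration list as produced by [default_config()].
#' @param path file path.
#' @return `save_config` returns `path` invisibly; `load_config` returns a
#'   list with `params` (a `ca_params`), `csc` (a `csc_config`), `treatment`
#'   (a `treatment_plan`) and `run` (side, iterations, seed).
#' @export
save_config <- function(config, path) {
  cfg <- config
  if (is.infinite(cfg$treatment$end)) cfg$treatment$end <- "Inf"
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname save_config
#' @export
load_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- c("run", "params", "csc", "treatment")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    stop("unknown config section(s): ", paste(unknown, collapse = ", "))
  miss <- setdiff(c("run", "params"), names(cfg))
  if (length(miss))
    stop("config missing section(s): ", paste(miss, collapse = ", "))

  unknown <- setdiff(names(cfg$run), config_run_keys)
  if (length(unknown))
    stop("unknown run key(s): ", paste(unknown, collapse = ", "))
  for (k in config_run_keys)
    if (is.null(cfg$run[[k]]))
      stop(sprintf("config missing required run field \"%s\"", k))

  pkeys <- names(formals(hallmark_params))
  unknown <- setdiff(names(cfg$params), pkeys)
  if (length(unknown))
    stop("unknown params key(s): ", paste(unknown, collapse = ", "))
  params <- do.call(hallmark_params, cfg$params)

  csc <- csc_config(0)
  if (!is.null(cfg$csc)) {
    unknown <- setdiff(names(cfg$csc), config_csc_keys)
    if (length(unknown))
      stop("unknown csc key(s): ", paste(unknown, collapse = ", "))
    csc <- do.call(csc_config, cfg$csc)
  }

  plan <- treatment_plan("none")
  if (!is.null(cfg$treatment)) {
    unknown <- setdiff(names(cfg$treatment), config_treatment_keys)
    if (length(unknown))
      stop("unknown treatment key(s): ", paste(unknown, collapse = ", "))
    tr <- cfg$treatment
    if (identical(tr$end, "Inf")) tr$end <- Inf
    plan <- do.call(treatment_plan, tr)
  }

  list(params = params, csc = csc, treatment = plan,
       run = list(side = as.integer(cfg$run$side),
                  iterations = as.integer(cfg$run$iterations),
                  seed = as.integer(cfg$run$seed)))
}

#' Run a simulation from a loaded configuration
#'
#' Convenience wrapper: builds the simulator, seeds CSCs, runs the full
#' iteration budget under the configured treatment plan.
#'
#' @param config the list returned by [load_config()] (or assembled to the
#'   same shape).
#' @param verbose passed to [sim_run()].
#' @return list with `trajectory` and `sim`.
#' @export
run_config <- function(config, verbose = FALSE) {
  sim <- tumor_sim(config$run$side, config$params, seed = config$run$seed)
  if (config$csc$fraction > 0) seed_cscs(sim, config$csc)
  plan <- if (config$treatment$mode == "none") NULL else config$treatment
  traj <- sim_run(sim, config$run$iterations, plan, verbose = verbose)
  list(trajectory = traj, sim = sim)
}
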