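outcome_levels <- c("stale", "died_random", "died_damage", "died_telomere",
                    "died_competition", "divided", "quiescent")

outcome_name <- function(code) {
  if (code == -1L) return("empty_queue")
  outcome_levels[code + 1L]
}

#' Create a tumor simulation
#'
#' Builds the discrete-event simulator: a cubic lattice whose sites hold
#' cells, and a priority queue of mitosis events ordered by (iteration time,
#' insertion order). With `fill = TRUE` (the default, and the model's stated
#' initial condition) every site receives a healthy cell with a fresh
#' telomere and one mitosis event scheduled a uniform 5-10 iterations ahead.
#'
#' All randomness is drawn from R's global RNG; pass `seed` (or call
#' `set.seed()` yourself beforehand) for reproducible runs.
#'
#' @param side sites per dimension (>= 3).
#' @param params a [hallmark_params()] object.
#' @param seed optional integer seed applied with `set.seed()`.
#' @param fill fill the grid with healthy cells and schedule their mitoses
#'   (default TRUE). `fill = FALSE` yields an empty lattice for constructing
#'   bespoke configurations with [place_cells()].
#' @return an object of class `tumor_sim`.
#' @examples
#' sim <- tumor_sim(10, seed = 1)
#' sim_counts(sim)$n_healthy  # 1000
#' @export
tumor_sim <- function(side, params = hallmark_params(), seed = NULL,
                      fill = TRUE) {
  if (!inherits(params, "ca_params")) stop("`params` must be a ca_params object")
  if (!is.numeric(side) || length(side) != 1L || side < 3 ||
      side != as.integer(side))
    stop("`side` must be a single integer >= 3")
  side <- as.integer(side)
  if (!is.null(seed)) set.seed(seed)
  margin <- growth_margin_for(side, params$boundary_fraction)
  if (margin >= side / 2) stop("growth margin must be smaller than side/2")
  cpar <- list(a = params$a, e = params$e, g = params$g,
               gi_factor = params$gi_factor, m = params$m, p_s = params$p_s,
               tl0 = params$tl0,
               delay_min = params$mitosis_delay[1],
               delay_max = params$mitosis_delay[2],
               igi_failure_kills = params$igi_failure_kills,
               csc_exempt_random_death = params$csc_exempt_random_death,
               csc_protected_from_competition =
                 params$csc_protected_from_competition,
               csc_daughter_mutations = params$csc_daughter_mutations)
  ptr <- engine_create(side, margin, params$neighborhood == "moore", cpar)
  if (fill) engine_fill_healthy(ptr)
  structure(list(ptr = ptr, side = side, n_sites = side^3,
                 growth_margin = margin, params = params),
            class = "tumor_sim")
}

#' @export
print.tumor_sim <- function(x, ...) {
  ct <- engine_counts(x$ptr, FALSE)
  cat(sprintf(
    "<tumor_sim> side=%d (%d sites), iteration %d: %d healthy, %d DCC, %d CSC, %d empty\n",
    x$side, x$n_sites, ct$iteration, ct$n_healthy, ct$n_dcc, ct$n_csc,
    ct$n_empty))
  invisible(x)
}

#' Run a simulation for a number of iterations
#'
#' Processes every queued mitosis event with time up to the iteration budget
#' in (time, insertion) order. When a treatment plan is given it is applied
#' at each iteration boundary — before that iteration's events — whenever the
#' plan's phase is active and the DCC count is at or above its threshold
#' gate. One time-series row is recorded per iteration.
#'
#' @param sim a [tumor_sim()] object (modified in place).
#' @param n_iterations iterations to advance (>= 0).
#' @param plan an optional [treatment_plan()].
#' @param verbose if TRUE, print a summary line every 100 iterations.
#' @return a data.frame with one row per iteration: population counts
#'   (`n_healthy`, `n_dcc`, `n_csc`, `n_empty`), per-hallmark counts among
#'   DCCs (`hall_sg` ... `hall_gi`), division and death tallies, and
#'   `treatment_kills`. Attributes `side` and `n_sites` carry the geometry.
#' @export
sim_run <- function(sim, n_iterations, plan = NULL, verbose = FALSE) {
  stopifnot(inherits(sim, "tumor_sim"))
  if (n_iterations < 0) stop("`n_iterations` must be >= 0")
  cplan <- if (is.null(plan)) NULL else plan_for_engine(plan)
  if (n_iterations == 0) {
    out <- engine_run(sim$ptr, 0L, cplan)
  } else if (verbose) {
    chunks <- c(rep(100L, n_iterations %/% 100L),
                if (n_iterations %% 100L) n_iterations %% 100L)
    parts <- vector("list", length(chunks))
    for (i in seq_along(chunks)) {
      parts[[i]] <- engine_run(sim$ptr, chunks[i], cplan)
      last <- parts[[i]][nrow(parts[[i]]), ]
      message(sprintf(
        "iteration %d: healthy=%d dcc=%d csc=%d empty=%d kills=%d",
        last$iteration, last$n_healthy, last$n_dcc, last$n_csc, last$n_empty,
        sum(parts[[i]]$treatment_kills)))
    }
    out <- do.call(rbind, parts)
  } else {
    out <- engine_run(sim$ptr, as.integer(n_iterations), cplan)
  }
  attr(out, "side") <- sim$side
  attr(out, "n_sites") <- sim$n_sites
  out
}

#' Process the single next event in the queue
#'
#' Pops the head of the event queue and runs the full decision cascade:
#' random-death test, genetic-damage test, telomere check, growth-factor
#' check, then the space/competition check and, if all pass, the division.
#' Events whose cell has already died are discarded as `"stale"`.
#'
#' @param sim a `tumor_sim`.
#' @return a list with `outcome` (one of stale, died_random, died_damage,
#'   died_telomere, died_competition, divided, quiescent, empty_queue),
#'   `cell` id and event `time`.
#' @export
sim_step <- function(sim) {
  stopifnot(inherits(sim, "tumor_sim"))
  r <- engine_step(sim$ptr)
  list(outcome = outcome_name(r$code), cell = r$cell, time = r$time)
}

#' Schedule a mitosis event for a live cell
#'
#' Pushes an event at the current iteration plus a uniform integer delay in
#' the configured 5-10 window.
#'
#' @param sim a `tumor_sim`.
#' @param cell_id cell identity (from [sim_cells()]).
#' @return the simulation, invisibly.
#' @export
schedule_mitosis <- function(sim, cell_id) {
  stopifnot(inherits(sim, "tumor_sim"))
  engine_schedule(sim$ptr, as.integer(cell_id))
  invisible(sim)
}

#' Perform a mitotic division into an empty target site
#'
#' Copies the mother's genome to the target site, decrements the telomere of
#' both cells (floor 0), applies independent mutation draws to both, and
#' schedules fresh mitosis events for both. Errors if the target is occupied
#' (takeover of an occupied site only happens through [compete_igi()]).
#'
#' @param sim a `tumor_sim`.
#' @param cell_id the mother's identity.
#' @param target_site 0-based coordinate triple of an empty neighbor.
#' @return the simulation, invisibly.
#' @export
divide_cell <- function(sim, cell_id, target_site) {
  stopifnot(inherits(sim, "tumor_sim"))
  target_site <- as.integer(target_site)
  if (length(target_site) == 3L)
    target_site <- site_index(sim$side, target_site)
  engine_divide(sim$ptr, as.integer(cell_id), target_site)
  invisible(sim)
}

#' Ignore-growth-inhibit competition for a fully surrounded cell
#'
#' With probability `1/g` the competition succeeds: a uniformly chosen
#' occupied neighbor dies and the daughter takes its site. On failure the
#' dividing cell dies (default) or requeues, per
#' `params$igi_failure_kills`. Errors if the cell still has empty neighbors.
#'
#' @param sim a `tumor_sim`.
#' @param cell_id the dividing cell's identity.
#' @return outcome string, `"divided"` or `"died_competition"` (or
#'   `"quiescent"` in requeue mode).
#' @export
compete_igi <- function(sim, cell_id) {
  stopifnot(inherits(sim, "tumor_sim"))
  r <- engine_compete(sim$ptr, as.integer(cell_id))
  outcome_name(r$code)
}

#' Current population counts
#'
#' @param sim a `tumor_sim`.
#' @param reset reset the per-iteration division/death counters after
#'   reading (default FALSE).
#' @return a one-row data.frame matching the [sim_run()] trajectory columns.
#' @export
sim_counts <- function(sim, reset = FALSE) {
  stopifnot(inherits(sim, "tumor_sim"))
  as.data.frame(engine_counts(sim$ptr, isTRUE(reset)))
}

#' Registry of live cells
#' @param sim a `tumor_sim`.
#' @return a data.frame: id, 0-based coordinates, hallmark flags, `is_csc`,
#'   `telomere`, `divisions` (lineage division count) and
#'   `mutation_denominator`.
#' @export
sim_cells <- function(sim) {
  stopifnot(inherits(sim, "tumor_sim"))
  engine_cells(sim$ptr)
}

#' Occupancy categories as a 3D array
#' @param sim a `tumor_sim`.
#' @return a side^3 integer array; 0 empty, 1 healthy, 2 DCC, 3 CSC.
#' @export
sim_occupancy <- function(sim) {
  stopifnot(inherits(sim, "tumor_sim"))
  array(engine_occupancy(sim$ptr), dim = rep(sim$side, 3))
}

#' Cumulative engine statistics
#'
#' Lifetime tallies of processed events, outcomes by kind, competition
#' attempts/successes, mutation opportunities/flips (split by whether
#' genetic instability was ON), symmetric/asymmetric divisions and
#' treatment kills — the raw material for empirical rate checks.
#'
#' @param sim a `tumor_sim`.
#' @return a named list.
#' @export
sim_stats <- function(sim) {
  stopifnot(inherits(sim, "tumor_sim"))
  engine_stats(sim$ptr)
}

#' Consistency check of the occupancy/registry invariants
#' @param sim a `tumor_sim`.
#' @return TRUE, or an error describing the violated invariant.
#' @export
sim_validate <- function(sim) {
  stopifnot(inherits(sim, "tumor_sim"))
  engine_validate(sim$ptr)
}

#' Number of queued (possibly stale) events
#' @param sim a `tumor_sim`.
#' @return integer.
#' @export
sim_queue_size <- function(sim) {
  stopifnot(inherits(sim, "tumor_sim"))
  engine_queue_size(sim$ptr)
}

#' Queued event times and cell ids (small queues; for inspection)
#' @param sim a `tumor_sim`.
#' @return list with `time` and `cell` vectors.
#' @export
sim_queue <- function(sim) {
  stopifnot(inherits(sim, "tumor_sim"))
  engine_queue_times(sim$ptr)
}

#' Completed iteration count
#' @param sim a `tumor_sim`.
#' @return integer.
#' @export
sim_iteration <- function(sim) {
  stopifnot(inherits(sim, "tumor_sim"))
  engine_completed(sim$ptr)
}

#' Place cells at given sites (test/scenario plumbing)
#'
#' Replaces any current occupants silently (no death is tallied) and
#' schedules a mitosis event for each new cell.
#'
#' @param sim a `tumor_sim`.
#' @param sites 0-based linear indices, or an n x 3 matrix of 0-based
#'   coordinates.
#' @param hallmarks character vector of hallmarks ON for every placed cell.
#' @param is_csc logical, recycled.
#' @param telomere integer, recycled; defaults to the params' `tl0`.
#' @param mutation_denominator recycled; defaults to the params' `m`.
#' @param delay fixed scheduling delay (recycled); -1 (default) draws the
#'   usual uniform delay.
#' @return integer vector of new cell ids, invisibly.
#' @export
place_cells <- function(sim, sites, hallmarks = character(), is_csc = FALSE,
                        telomere = NULL, mutation_denominator = NULL,
                        delay = -1L) {
  stopifnot(inherits(sim, "tumor_sim"))
  if (is.matrix(sites)) sites <- site_index(sim$side, sites)
  n <- length(sites)
  flags <- sum(2^(match(hallmarks, hallmark_names) - 1L))
  if (any(is_csc)) flags <- bitwOr(as.integer(flags), 4L + 8L)  # EA|EI
  telomere <- if (is.null(telomere)) sim$params$tl0 else telomere
  md <- if (is.null(mutation_denominator)) sim$params$m else mutation_denominator
  ids <- engine_place_cells(sim$ptr, as.integer(sites),
                            rep(as.integer(flags), n),
                            rep(as.integer(is_csc), length.out = n),
                            rep(as.integer(telomere), length.out = n),
                            rep(as.numeric(md), length.out = n),
                            rep(as.integer(delay), length.out = n))
  invisible(ids)
}

#' Remove the occupants of the given sites (test plumbing; no death tallied)
#' @param sim a `tumor_sim`.
#' @param sites 0-based linear indices or an n x 3 coordinate matrix.
#' @return the simulation, invisibly.
#' @export
remove_cells <- function(sim, sites) {
  stopifnot(inherits(sim, "tumor_sim"))
  if (is.matrix(sites)) sites <- site_index(sim$side, sites)
  engine_remove_sites(sim$ptr, as.integer(sites))
  invisible(sim)
}

#' Override a tunable engine option on a live simulation
#'
#' Supported: `p_s`, `a`, `e`, `g`, `gi_factor`, the CSC behavior switches
#' and `igi_failure_kills`. Intended for sensitivity tests.
#'
#' @param sim a `tumor_sim`.
#' @param name option name.
#' @param value new value.
#' @return the simulation, invisibly.
#' @export
sim_set_option <- function(sim, name, value) {
  stopifnot(inherits(sim, "tumor_sim"))
  engine_set_option(sim$ptr, name, value)
  if (name %in% names(sim$params)) sim$params[[name]] <- value
  invisible(sim)
}
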