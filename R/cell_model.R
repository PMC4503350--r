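#' Model parameters
#'
#' Bundles the hallmark and simulation parameters with their standard values.
#' All rates are expressed as denominators: the per-hallmark mutation
#' probability at division is `1/m`, the random-death probability per
#' processed event is `1/a`, the genetic-damage death probability is `n/e`
#' for `n` active hallmarks (zero when evade-apoptosis is ON), and an
#' ignore-growth-inhibit competition succeeds with probability `1/g`.
#'
#' Mitoses are scheduled a uniform integer 5-10 iterations ahead, standing in
#' for a 15-24 h cell cycle, so one iteration averages
#' `mean(cycle_hours) / mean(mitosis_delay) = 19.5/7.5 = 2.6` hours.
#'
#' @param m hallmark mutation denominator (default 100000).
#' @param a random cell-death denominator (default 1000).
#' @param e genetic-damage denominator (default 10).
#' @param g competition denominator for ignore-growth-inhibit (default 30).
#' @param tl0 initial telomere length, divisions allowed per lineage
#'   (default 50).
#' @param p_s probability that a cancer stem cell divides symmetrically
#'   (default 0.01).
#' @param gi_factor multiplicative increase of the mutation probability while
#'   genetic instability is ON (default 100); the resulting probability is
#'   capped at 1.
#' @param boundary_fraction per-dimension extent of the growth-factor region
#'   (default 0.95).
#' @param mitosis_delay integer interval for the scheduling delay, inclusive
#'   (default `c(5, 10)`).
#' @param cycle_hours real interval of cell-cycle durations the delay stands
#'   for (default `c(15, 24)`).
#' @param neighborhood `"moore"` or `"von_neumann"`.
#' @param igi_failure_kills if TRUE a cell losing an ignore-growth-inhibit
#'   competition dies; if FALSE (default) the mitosis is merely aborted and
#'   the cell requeued. The default is the requeue mode because the
#'   loser-dies reading makes crowded IGI proliferation subcritical
#'   (expected offspring `2/g < 1` for `g > 2`), which contradicts the
#'   IGI-driven invasion the model is meant to produce; see the methods
#'   vignette.
#' @param csc_exempt_random_death if TRUE (default) cancer stem cells skip
#'   the random-death test.
#' @param csc_protected_from_competition if TRUE (default) cancer stem cells
#'   cannot be killed by a neighbor's competition.
#' @param csc_daughter_mutations if TRUE, asymmetric-division daughters also
#'   receive a standard `1/m` mutation draw at birth (default FALSE).
#' @return an object of class `ca_params`.
#' @examples
#' p <- hallmark_params()
#' random_death_probability(p)  # 0.001
#' @export
hallmark_params <- function(m = 100000, a = 1000, e = 10, g = 30, tl0 = 50,
                            p_s = 0.01, gi_factor = 100,
                            boundary_fraction = 0.95,
                            mitosis_delay = c(5L, 10L),
                            cycle_hours = c(15, 24),
                            neighborhood = c("moore", "von_neumann"),
                            igi_failure_kills = FALSE,
                            csc_exempt_random_death = TRUE,
                            csc_protected_from_competition = TRUE,
                            csc_daughter_mutations = FALSE) {
  neighborhood <- match.arg(neighborhood)
  for (nm in c("m", "a", "e", "g", "gi_factor")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || v <= 0)
      stop(sprintf("`%s` must be a positive number", nm))
  }
  if (!is.numeric(tl0) || length(tl0) != 1L || tl0 < 1 || tl0 != as.integer(tl0))
    stop("`tl0` must be a positive integer")
  if (!is.numeric(p_s) || length(p_s) != 1L || p_s < 0 || p_s > 1)
    stop("`p_s` must be in [0, 1]")
  if (!is.numeric(boundary_fraction) || length(boundary_fraction) != 1L ||
      boundary_fraction <= 0 || boundary_fraction > 1)
    stop("`boundary_fraction` must be in (0, 1]")
  if (length(mitosis_delay) != 2L || mitosis_delay[1] > mitosis_delay[2] ||
      any(mitosis_delay < 1) || any(mitosis_delay != as.integer(mitosis_delay)))
    stop("`mitosis_delay` must be an ordered pair of positive integers")
  if (length(cycle_hours) != 2L || cycle_hours[1] > cycle_hours[2] ||
      any(cycle_hours <= 0))
    stop("`cycle_hours` must be an ordered pair of positive numbers")
  structure(
    list(m = m, a = a, e = e, g = g, tl0 = as.integer(tl0), p_s = p_s,
         gi_factor = gi_factor, boundary_fraction = boundary_fraction,
         mitosis_delay = as.integer(mitosis_delay), cycle_hours = cycle_hours,
         neighborhood = neighborhood,
         igi_failure_kills = isTRUE(igi_failure_kills),
         csc_exempt_random_death = isTRUE(csc_exempt_random_death),
         csc_protected_from_competition = isTRUE(csc_protected_from_competition),
         csc_daughter_mutations = isTRUE(csc_daughter_mutations)),
    class = "ca_params")
}

#' @export
print.ca_params <- function(x, ...) {
  cat(sprintf(
    "<ca_params> m=%g a=%g e=%g g=%g tl0=%d p_s=%g gi_factor=%g boundary=%g\n",
    x$m, x$a, x$e, x$g, x$tl0, x$p_s, x$gi_factor, x$boundary_fraction))
  invisible(x)
}

hallmark_names <- c("sg", "igi", "ea", "ei", "gi")

#' A per-cell genome
#'
#' Five binary hallmark flags (self-growth, ignore growth inhibit, evade
#' apoptosis, effective immortality, genetic instability) plus the two
#' per-cell parameters: remaining telomere length and the cell's own
#' mutation denominator. Once a hallmark is ON it is never cleared.
#'
#' @param hallmarks character vector among `c("sg","igi","ea","ei","gi")`,
#'   or a named logical vector.
#' @param telomere remaining divisions (default 50).
#' @param mutation_denominator the cell's `m` (default 100000).
#' @return an object of class `ca_genome`.
#' @export
new_genome <- function(hallmarks = character(), telomere = 50L,
                       mutation_denominator = 100000) {
  h <- stats::setNames(rep(FALSE, 5L), hallmark_names)
  if (is.logical(hallmarks)) {
    stopifnot(all(names(hallmarks) %in% hallmark_names))
    h[names(hallmarks)] <- hallmarks
  } else if (length(hallmarks)) {
    bad <- setdiff(hallmarks, hallmark_names)
    if (length(bad)) stop("unknown hallmark(s): ", paste(bad, collapse = ", "))
    h[hallmarks] <- TRUE
  }
  if (telomere < 0) stop("`telomere` must be >= 0")
  if (mutation_denominator <= 0) stop("`mutation_denominator` must be > 0")
  structure(list(hallmarks = h, telomere = as.integer(telomere),
                 mutation_denominator = mutation_denominator),
            class = "ca_genome")
}

#' Effective per-hallmark mutation probability of a genome
#'
#' `1/m` normally; `min(1, gi_factor/m)` while genetic instability is ON.
#' The increase is a fixed multiplicative factor and does not compound.
#'
#' @param genome a `ca_genome`.
#' @param params a `ca_params`.
#' @return a probability.
#' @export
effective_mutation_probability <- function(genome, params = hallmark_params()) {
  m <- genome$mutation_denominator
  if (genome$hallmarks[["gi"]]) min(1, params$gi_factor / m) else 1 / m
}

#' Apply mutation draws to a genome (one division's worth)
#'
#' Each OFF hallmark independently turns ON with the genome's effective
#' mutation probability; ON hallmarks and the telomere are untouched.
#'
#' @inheritParams effective_mutation_probability
#' @return the (possibly) mutated genome.
#' @export
acquire_mutations <- function(genome, params = hallmark_params()) {
  p <- effective_mutation_probability(genome, params)
  off <- !genome$hallmarks
  if (any(off))
    genome$hallmarks[off] <- stats::runif(sum(off)) < p
  genome
}

#' Genetic-damage death probability
#'
#' `min(1, n/e)` for `n` hallmarks ON; exactly 0 when evade-apoptosis is ON
#' (damage-induced death is not applied to such cells).
#'
#' @inheritParams effective_mutation_probability
#' @return a probability.
#' @examples
#' g <- new_genome(c("sg", "igi", "gi"))
#' damage_death_probability(g)  # 0.3
#' @export
damage_death_probability <- function(genome, params = hallmark_params()) {
  if (genome$hallmarks[["ea"]]) return(0)
  min(1, sum(genome$hallmarks) / params$e)
}

#' Random cell-death probability per processed event
#' @param params a `ca_params`.
#' @return `1/a`.
#' @export
random_death_probability <- function(params = hallmark_params()) {
  1 / params$a
}

#' Convert iteration counts to simulated hours
#'
#' One iteration stands for `mean(cycle_hours)/mean(mitosis_delay)` hours;
#' with defaults 19.5/7.5 = 2.6 h, so 5000 iterations are 13000 h
#' (77.4 weeks).
#'
#' @param k iterations (non-negative, vectorized).
#' @param params a `ca_params`.
#' @return hours.
#' @examples
#' iterations_to_hours(1)               # 2.6
#' iterations_to_hours(5000) / (24 * 7) # 77.4 weeks
#' @export
iterations_to_hours <- function(k, params = hallmark_params()) {
  k * mean(params$cycle_hours) / mean(params$mitosis_delay)
}

#' @rdname iterations_to_hours
#' @export
iterations_to_days <- function(k, params = hallmark_params()) {
  iterations_to_hours(k, params) / 24
}

#' @rdname iterations_to_hours
#' @export
iterations_to_weeks <- function(k, params = hallmark_params()) {
  iterations_to_hours(k, params) / (24 * 7)
}

#' Derived cell classification
#'
#' Healthy: non-stem with no hallmark ON. DCC (differentiated cancer cell):
#' non-stem with at least one hallmark ON. CSC: cancer stem cell.
#'
#' @param genome a `ca_genome`.
#' @param is_csc logical.
#' @return one of `"healthy"`, `"dcc"`, `"csc"`.
#' @export
classify_cell <- function(genome, is_csc = FALSE) {
  if (isTRUE(is_csc)) return("csc")
  if (any(genome$hallmarks)) "dcc" else "healthy"
}
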