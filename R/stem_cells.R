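#' Cancer-stem-cell compartment configuration
#'
#' CSCs carry evade-apoptosis and effective-immortality permanently ON, are
#' resistant to treatment, and divide only when an empty site exists in the
#' immediate neighborhood: symmetrically (two CSCs) with probability `p_s`,
#' otherwise asymmetrically into one CSC plus one differentiated cancer cell
#' bearing a single uniformly chosen hallmark and a fresh telomere.
#'
#' @param fraction CSCs as a share of total lattice sites, in [0, 1]
#'   (the experiments use 0.01-0.05).
#' @param p_s probability of symmetric division; `NULL` keeps the
#'   simulation's current value (default 0.01).
#' @param exempt_random_death CSCs skip the random-death test
#'   (default TRUE; without it the stable CSC counts seen over thousands of
#'   iterations would be impossible).
#' @return an object of class `csc_config`.
#' @export
csc_config <- function(fraction, p_s = NULL, exempt_random_death = TRUE) {
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      fraction < 0 || fraction > 1)
    stop("`fraction` must be in [0, 1]")
  if (!is.null(p_s) && (!is.numeric(p_s) || p_s < 0 || p_s > 1))
    stop("`p_s` must be in [0, 1]")
  structure(list(fraction = fraction, p_s = p_s,
                 exempt_random_death = isTRUE(exempt_random_death)),
            class = "csc_config")
}

#' Seed cancer stem cells into a freshly initialized grid
#'
#' Replaces the healthy occupants of `round(fraction * side^3)` distinct
#' uniformly chosen sites inside the growth-factor region with CSCs
#' (evade-apoptosis and effective-immortality ON, telomere `tl0`) and
#' schedules a mitosis event for each.
#'
#' @param sim a [tumor_sim()] object.
#' @param config a [csc_config()], or a bare fraction.
#' @return the new CSC cell ids, invisibly.
#' @examples
#' sim <- tumor_sim(10, seed = 1)
#' seed_cscs(sim, 0.01)
#' sim_counts(sim)$n_csc  # 10
#' @export
seed_cscs <- function(sim, config) {
  stopifnot(inherits(sim, "tumor_sim"))
  if (is.numeric(config)) config <- csc_config(config)
  stopifnot(inherits(config, "csc_config"))
  if (!is.null(config$p_s)) sim_set_option(sim, "p_s", config$p_s)
  sim_set_option(sim, "csc_exempt_random_death", config$exempt_random_death)
  count <- round(config$fraction * sim$n_sites)
  if (count == 0) return(invisible(integer()))
  region <- growth_region_sites(sim$side, sim$growth_margin)
  if (count > length(region))
    stop(sprintf("requested %d CSCs but the growth region has only %d sites",
                 count, length(region)))
  sites <- region[sample.int(length(region), count)]
  place_cells(sim, sites, is_csc = TRUE, telomere = sim$params$tl0,
              mutation_denominator = sim$params$m)
}

#' Attempt a cancer-stem-cell division
#'
#' The CSC's event handler: quiescent requeue when no empty neighbor exists;
#' otherwise a symmetric division with probability `p_s` (daughter CSC, full
#' copy) or an asymmetric division (daughter DCC with exactly one uniformly
#' chosen hallmark ON, telomere `tl0`, fresh mutation denominator). The CSC
#' itself is unchanged and requeued. Called automatically when the engine
#' pops a CSC's event; exposed for direct use in tests.
#'
#' @param sim a `tumor_sim`.
#' @param cell_id id of a CSC (errors otherwise).
#' @return outcome string, `"divided"` or `"quiescent"`.
#' @export
csc_attempt_division <- function(sim, cell_id) {
  stopifnot(inherits(sim, "tumor_sim"))
  r <- engine_csc_divide(sim$ptr, as.integer(cell_id))
  outcome_name(r$code)
}
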