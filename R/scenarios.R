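scenario_names <- c("fig2", "fig3", "fig4a", "fig4b", "fig4c", "fig4d",
                    "fig5a", "fig5b", "fig5c", "fig5d")

#' Named experiment presets
#'
#' Fully specified configurations for the reference experiments:
#' \itemize{
#'   \item `fig2` — high-invasion scenario (`g = 5`), 1% CSCs, a single
#'     100%-kill pulse at iteration 5000, 6000 iterations: tumor regrowth
#'     after a high-intensity treatment.
#'   \item `fig3` — same scenario, continuous 1%-per-iteration kill between
#'     iterations 5000 and 6000, 8000 iterations: regrowth after a
#'     low-intensity treatment.
#'   \item `fig4a`-`fig4d` — `g = 5`, 5% CSCs, treatment from the beginning
#'     gated on a DCC threshold of 1% of grid size: (a) continuous 1% kill;
#'     (b) 10% kill sustained for 60 of every 100 iterations; (c) 50% kill
#'     every 100 iterations; (d) 75% kill every 100 iterations.
#'   \item `fig5a`-`fig5d` — as fig4 but in the high-mutation scenario
#'     (`m = 1000`, `g` standard), with the continuous variant (a) killing
#'     5% per iteration.
#' }
#'
#' `scale` shrinks the experiment for quick runs: the side and every time
#' quantity (iteration budget, treatment start/end, period, pulse duration)
#' scale linearly, while probabilities, rates and fractions — including the
#' threshold gate, which is a fraction of grid size — are preserved exactly.
#' The scaled side is floored at 10.
#'
#' @param name one of `"fig2"`, `"fig3"`, `"fig4a"`-`"fig4d"`,
#'   `"fig5a"`-`"fig5d"`.
#' @param scale factor in (0, 1].
#' @return an object of class `ca_scenario` with fields `name`, `side`,
#'   `params`, `csc_fraction`, `plan`, `n_iterations`, `scale`.
#' @examples
#' sc <- scenario_preset("fig2", scale = 0.4)
#' sc$side          # 20
#' sc$plan$start    # 2000
#' @export
scenario_preset <- function(name, scale = 1) {
  if (!is.character(name) || length(name) != 1L || !(name %in% scenario_names))
    stop("unknown scenario; valid names: ", paste(scenario_names, collapse = ", "))
  if (!is.numeric(scale) || scale <= 0 || scale > 1)
    stop("`scale` must be in (0, 1]")
  g5 <- hallmark_params(g = 5)
  m1k <- hallmark_params(m = 1000)
  def <- switch(name,
    fig2 = list(params = g5, csc = 0.01, n = 6000,
                plan = treatment_plan("pulse", start = 5000, kill_prob = 1)),
    fig3 = list(params = g5, csc = 0.01, n = 8000,
                plan = treatment_plan("continuous", start = 5000, end = 6000,
                                      kill_prob = 0.01)),
    fig4a = list(params = g5, csc = 0.05, n = 8000,
                 plan = treatment_plan("continuous", start = 1, kill_prob = 0.01,
                                       threshold_fraction = 0.01)),
    fig4b = list(params = g5, csc = 0.05, n = 8000,
                 plan = treatment_plan("periodic_sustained", start = 1,
                                       period = 100, pulse_duration = 60,
                                       kill_prob = 0.10,
                                       threshold_fraction = 0.01)),
    fig4c = list(params = g5, csc = 0.05, n = 8000,
                 plan = treatment_plan("periodic_pulse", start = 1, period = 100,
                                       kill_prob = 0.50,
                                       threshold_fraction = 0.01)),
    fig4d = list(params = g5, csc = 0.05, n = 8000,
                 plan = treatment_plan("periodic_pulse", start = 1, period = 100,
                                       kill_prob = 0.75,
                                       threshold_fraction = 0.01)),
    fig5a = list(params = m1k, csc = 0.05, n = 8000,
                 plan = treatment_plan("continuous", start = 1, kill_prob = 0.05,
                                       threshold_fraction = 0.01)),
    fig5b = list(params = m1k, csc = 0.05, n = 8000,
                 plan = treatment_plan("periodic_sustained", start = 1,
                                       period = 100, pulse_duration = 60,
                                       kill_prob = 0.10,
                                       threshold_fraction = 0.01)),
    fig5c = list(params = m1k, csc = 0.05, n = 8000,
                 plan = treatment_plan("periodic_pulse", start = 1, period = 100,
                                       kill_prob = 0.50,
                                       threshold_fraction = 0.01)),
    fig5d = list(params = m1k, csc = 0.05, n = 8000,
                 plan = treatment_plan("periodic_pulse", start = 1, period = 100,
                                       kill_prob = 0.75,
                                       threshold_fraction = 0.01)))
  side <- max(10L, as.integer(round(50 * scale)))
  st <- function(x, lo = 1) if (is.infinite(x)) x else max(lo, round(x * scale))
  plan <- def$plan
  plan$start <- as.integer(st(plan$start))
  plan$end <- st(plan$end)
  plan$period <- as.integer(st(plan$period))
  plan$pulse_duration <- as.integer(min(plan$period, st(plan$pulse_duration)))
  structure(list(name = name, side = side, params = def$params,
                 csc_fraction = def$csc, plan = plan,
                 n_iterations = as.integer(round(def$n * scale)),
                 scale = scale),
            class = "ca_scenario")
}

#' @export
print.ca_scenario <- function(x, ...) {
  cat(sprintf("<ca_scenario> %s (scale %g): side=%d, %d iterations, CSC %g%%\n",
              x$name, x$scale, x$side, x$n_iterations, 100 * x$csc_fraction))
  print(x$plan)
  invisible(x)
}

#' Run a scenario
#'
#' @param scenario a [scenario_preset()] object.
#' @param seed RNG seed.
#' @param n_iterations optional override of the iteration budget.
#' @param verbose passed to [sim_run()].
#' @return list with `trajectory`, `sim` and `scenario`.
#' @export
run_scenario <- function(scenario, seed, n_iterations = NULL,
                         verbose = FALSE) {
  stopifnot(inherits(scenario, "ca_scenario"))
  sim <- tumor_sim(scenario$side, scenario$params, seed = seed)
  if (scenario$csc_fraction > 0) seed_cscs(sim, scenario$csc_fraction)
  n <- if (is.null(n_iterations)) scenario$n_iterations else n_iterations
  traj <- sim_run(sim, n, scenario$plan, verbose = verbose)
  list(trajectory = traj, sim = sim, scenario = scenario)
}

#' Initial-growth and regrowth times of the DCC population
#'
#' `t_initial` is the first iteration at which the DCC count reaches
#' `occupancy_target` of the grid, measured from iteration 0; `t_regrow` is
#' the first such iteration at or after `treatment_end`, measured from
#' `treatment_end`. Regrowth after a high-intensity pulse is driven by
#' surviving CSC differentiation and is typically faster than the initial
#' growth. A component is `NA` when the target is never reached.
#'
#' @param trajectory a [sim_run()] trajectory (needs the `n_sites`
#'   attribute, or pass `total_sites`).
#' @param treatment_end iteration at which the treatment ended.
#' @param occupancy_target DCC count target as a fraction of grid size
#'   (default 0.2).
#' @param total_sites grid size override.
#' @return list with `t_initial`, `t_regrow` (iterations, `NA` = never
#'   reached) and the absolute `target` count.
#' @export
regrowth_metrics <- function(trajectory, treatment_end,
                             occupancy_target = 0.2, total_sites = NULL) {
  if (is.null(total_sites)) total_sites <- attr(trajectory, "n_sites")
  if (is.null(total_sites))
    stop("supply `total_sites` or a trajectory with an n_sites attribute")
  if (!is.data.frame(trajectory) || nrow(trajectory) == 0)
    stop("empty trajectory")
  target <- occupancy_target * total_sites
  hit <- trajectory$iteration[trajectory$n_dcc >= target]
  t_initial <- if (length(hit)) hit[1] else NA_integer_
  hit2 <- hit[hit >= treatment_end]
  t_regrow <- if (length(hit2)) hit2[1] - treatment_end else NA_integer_
  list(t_initial = t_initial, t_regrow = t_regrow, target = target)
}
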