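plan_modes <- c("none", "pulse", "continuous", "periodic_pulse",
                "periodic_sustained")

#' Parameterized treatment schedule
#'
#' Treatments are "ideal": each application kills differentiated cancer
#' cells only — healthy cells and cancer stem cells are never affected.
#' A threshold gate restricts application to iterations where the DCC count
#' is at or above `threshold_fraction` of the grid size (0 disables the
#' gate). Active phases by mode:
#' \itemize{
#'   \item `pulse`: the single iteration `t == start`;
#'   \item `continuous`: every iteration with `start <= t <= end`;
#'   \item `periodic_pulse`: iterations with `(t - start) %% period == 0`;
#'   \item `periodic_sustained`: iterations with
#'     `(t - start) %% period < pulse_duration`.
#' }
#'
#' @param mode one of `"none"`, `"pulse"`, `"continuous"`,
#'   `"periodic_pulse"`, `"periodic_sustained"`.
#' @param start first active iteration.
#' @param end last active iteration (`Inf` = unbounded).
#' @param period cycle length in iterations for the periodic modes.
#' @param pulse_duration active iterations per cycle (periodic_sustained).
#' @param kill_prob per-DCC kill probability per application.
#' @param threshold_fraction DCC-count gate as a fraction of grid size.
#' @param exact if TRUE, kill exactly `floor(kill_prob * n_dcc)` uniformly
#'   chosen DCCs instead of independent per-cell Bernoulli draws.
#' @return an object of class `treatment_plan`.
#' @examples
#' treatment_plan("continuous", start = 5000, end = 6000, kill_prob = 0.01)
#' @export
treatment_plan <- function(mode = plan_modes, start = 1, end = Inf,
                           period = 100, pulse_duration = period,
                           kill_prob = 0, threshold_fraction = 0,
                           exact = FALSE) {
  mode <- match.arg(mode)
  if (!is.numeric(kill_prob) || kill_prob < 0 || kill_prob > 1)
    stop("`kill_prob` must be in [0, 1]")
  if (start > end) stop("`start` must be <= `end`")
  if (period < 1) stop("`period` must be >= 1")
  if (pulse_duration < 1 || pulse_duration > period)
    stop("`pulse_duration` must be in [1, period]")
  if (threshold_fraction < 0) stop("`threshold_fraction` must be >= 0")
  structure(list(mode = mode, start = as.integer(start), end = end,
                 period = as.integer(period),
                 pulse_duration = as.integer(pulse_duration),
                 kill_prob = kill_prob,
                 threshold_fraction = threshold_fraction,
                 exact = isTRUE(exact)),
            class = "treatment_plan")
}

#' @export
print.treatment_plan <- function(x, ...) {
  cat(sprintf(
    "<treatment_plan> %s start=%d end=%s period=%d duration=%d kill=%g threshold=%g%s\n",
    x$mode, x$start, format(x$end), x$period, x$pulse_duration, x$kill_prob,
    x$threshold_fraction, if (x$exact) " (exact-fraction)" else ""))
  invisible(x)
}

plan_for_engine <- function(plan) {
  stopifnot(inherits(plan, "treatment_plan"))
  list(mode_code = match(plan$mode, plan_modes) - 1L,
       start = plan$start, end = as.numeric(plan$end), period = plan$period,
       pulse_duration = plan$pulse_duration, kill_prob = plan$kill_prob,
       threshold_fraction = plan$threshold_fraction, exact = plan$exact)
}

#' Should a treatment be applied at this iteration?
#'
#' TRUE iff the iteration falls in the plan's active phase and the DCC count
#' is at or above the threshold gate.
#'
#' @param plan a [treatment_plan()].
#' @param t iteration.
#' @param n_dcc current differentiated-cancer-cell count.
#' @param total_sites grid size (`side^3`).
#' @return logical.
#' @export
should_apply <- function(plan, t, n_dcc, total_sites) {
  stopifnot(inherits(plan, "treatment_plan"))
  active <- switch(plan$mode,
    none = FALSE,
    pulse = t == plan$start,
    continuous = t >= plan$start && t <= plan$end,
    periodic_pulse = t >= plan$start && t <= plan$end &&
      (t - plan$start) %% plan$period == 0,
    periodic_sustained = t >= plan$start && t <= plan$end &&
      (t - plan$start) %% plan$period < plan$pulse_duration)
  active && n_dcc >= plan$threshold_fraction * total_sites - 1e-9
}

#' Apply one treatment round to a simulation
#'
#' Kills differentiated cancer cells per the plan's `kill_prob` — as
#' independent Bernoulli draws, or exactly `floor(kill_prob * n_dcc)`
#' uniformly chosen victims in exact mode. Healthy cells and CSCs are never
#' touched; freed sites become empty immediately.
#'
#' @param sim a `tumor_sim`.
#' @param plan a [treatment_plan()], or a bare kill probability.
#' @param exact used only when `plan` is a bare probability.
#' @return the kill count.
#' @export
apply_treatment <- function(sim, plan, exact = FALSE) {
  stopifnot(inherits(sim, "tumor_sim"))
  if (is.numeric(plan)) {
    kill_prob <- plan
  } else {
    stopifnot(inherits(plan, "treatment_plan"))
    kill_prob <- plan$kill_prob
    exact <- plan$exact
  }
  engine_apply_treatment(sim$ptr, kill_prob, isTRUE(exact))
}
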