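# Build a simulation whose every site holds a cell with the given hallmarks.
# Used to isolate single decision-cascade channels for rate measurements.
uniform_population_sim <- function(side, hallmarks, params) {
  sim <- tumor_sim(side, params, fill = FALSE)
  place_cells(sim, 0:(side^3 - 1L), hallmarks = hallmarks)
  sim
}

# Params that disable every stochastic channel except the one under test.
quiet_params <- function(...) {
  args <- utils::modifyList(list(a = Inf, m = Inf, boundary_fraction = 1),
                            list(...))
  do.call(hallmark_params, args)
}

hallmark_names <- c("sg", "igi", "ea", "ei", "gi")
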