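test_that("plan construction validates its fields", {
  expect_error(treatment_plan("continuous", kill_prob = 1.5), "kill_prob")
  expect_error(treatment_plan("continuous", start = 10, end = 5), "start")
  expect_error(treatment_plan("periodic_sustained", period = 50,
                              pulse_duration = 60), "pulse_duration")
})

test_that("should_apply implements the phase logic of every mode", {
  tot <- 125000
  cont <- treatment_plan("continuous", start = 5000, end = 6000,
                         kill_prob = 0.01)
  expect_true(should_apply(cont, 5500, 10, tot))
  expect_true(should_apply(cont, 5000, 10, tot))
  expect_true(should_apply(cont, 6000, 10, tot))
  expect_false(should_apply(cont, 4999, 10, tot))
  expect_false(should_apply(cont, 6001, 10, tot))

  pulse <- treatment_plan("pulse", start = 5000, kill_prob = 1)
  expect_true(should_apply(pulse, 5000, 10, tot))
  expect_false(should_apply(pulse, 5001, 10, tot))

  pp <- treatment_plan("periodic_pulse", start = 1, period = 100,
                       kill_prob = 0.5)
  expect_true(should_apply(pp, 1, 10, tot))
  expect_true(should_apply(pp, 101, 10, tot))
  expect_false(should_apply(pp, 150, 10, tot))

  ps <- treatment_plan("periodic_sustained", start = 1, period = 100,
                       pulse_duration = 60, kill_prob = 0.1)
  offs <- 0:99
  active <- vapply(offs, function(o) should_apply(ps, 1 + o, 10, tot),
                   logical(1))
  expect_true(all(active[offs < 60]))
  expect_false(any(active[offs >= 60]))

  expect_false(should_apply(treatment_plan("none"), 1, 10, tot))
})

test_that("the DCC-count threshold gates application", {
  plan <- treatment_plan("continuous", start = 1, kill_prob = 0.01,
                         threshold_fraction = 0.01)
  expect_false(should_apply(plan, 10, 1249, 125000))
  expect_true(should_apply(plan, 10, 1250, 125000))  # "equal or over"
  expect_true(should_apply(plan, 10, 1251, 125000))
})

test_that("a 100% kill removes every DCC and touches nothing else", {
  sim <- tumor_sim(8, quiet_params(), seed = 31)
  seed_cscs(sim, 0.02)
  remove_cells(sim, 0:99)
  place_cells(sim, 0:99, hallmarks = "igi")   # 100 DCCs
  before <- sim_counts(sim)
  expect_equal(before$n_dcc, 100)
  kills <- apply_treatment(sim, treatment_plan("pulse", start = 1,
                                               kill_prob = 1))
  after <- sim_counts(sim)
  expect_equal(kills, 100)
  expect_equal(after$n_dcc, 0)
  expect_equal(after$n_csc, before$n_csc)       # CSCs resist treatment
  expect_equal(after$n_healthy, before$n_healthy)
  expect_equal(after$n_empty, before$n_empty + 100)  # freed immediately
  expect_true(sim_validate(sim))
})

test_that("kill probabilities are Bernoulli per cell, with an exact mode", {
  build <- function() {
    sim <- tumor_sim(14, quiet_params(), seed = 32, fill = FALSE)
    place_cells(sim, 0:1999, hallmarks = "ea")
    sim
  }
  sim <- build()
  expect_equal(apply_treatment(sim, 0), 0)
  set.seed(33)
  kills <- apply_treatment(sim, 0.5)
  expect_lt(abs(kills - 1000), 3 * sqrt(2000 * 0.25))  # binomial oracle
  # exact-fraction mode kills exactly floor(p * n)
  sim <- build()
  set.seed(34)
  expect_equal(apply_treatment(sim, 0.3, exact = TRUE), floor(0.3 * 2000))
  expect_equal(sim_counts(sim)$n_dcc, 2000 - 600)
})

test_that("a NONE plan is bit-identical to running without a plan", {
  p <- hallmark_params(m = 100, g = 5)
  pipeline <- function(plan) {
    s <- tumor_sim(8, p, seed = 35)
    seed_cscs(s, 0.02)
    sim_run(s, 150, plan = plan)
  }
  expect_identical(pipeline(NULL), pipeline(treatment_plan("none")))
})

test_that("the engine never kills below the threshold gate", {
  p <- hallmark_params(m = 200, a = 500, g = 5)
  sim <- tumor_sim(10, p, seed = 36)
  seed_cscs(sim, 0.01)
  plan <- treatment_plan("continuous", start = 1, kill_prob = 1,
                         threshold_fraction = 0.5)  # unreachable gate
  tr <- sim_run(sim, 200, plan)
  expect_true(all(tr$treatment_kills == 0))
  # and with the gate off, kills do happen in the same world
  sim2 <- tumor_sim(10, p, seed = 36)
  seed_cscs(sim2, 0.01)
  tr2 <- sim_run(sim2, 200, treatment_plan("continuous", start = 1,
                                           kill_prob = 1))
  expect_gt(sum(tr2$treatment_kills), 0)
})

test_that("engine applications agree with should_apply iteration by iteration", {
  plan <- treatment_plan("periodic_sustained", start = 1, period = 20,
                         pulse_duration = 8, kill_prob = 1)
  sim <- tumor_sim(8, hallmark_params(m = 100, a = 300, g = 5), seed = 37)
  seed_cscs(sim, 0.05)
  tr <- sim_run(sim, 200, plan)
  # kills can only be recorded at iterations the phase logic marks active
  inactive <- !vapply(tr$iteration, function(t)
    should_apply(plan, t, Inf, attr(tr, "n_sites")), logical(1))
  expect_true(all(tr$treatment_kills[inactive] == 0))
})
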