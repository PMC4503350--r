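test_that("initialization fills the grid and schedules every cell", {
  sim <- tumor_sim(6, seed = 1)
  ct <- sim_counts(sim)
  expect_equal(ct$n_healthy, 216)
  expect_equal(ct$n_dcc + ct$n_csc + ct$n_empty, 0)
  expect_equal(sim_queue_size(sim), 216)
  q <- sim_queue(sim)
  expect_true(all(q$time >= 5 & q$time <= 10))
  cells <- sim_cells(sim)
  expect_true(all(cells$telomere == 50))
  expect_true(all(cells$mutation_denominator == 1e5))
  expect_true(all(!cells$sg & !cells$igi & !cells$ea & !cells$ei & !cells$gi))
  expect_error(tumor_sim(2), "side")
})

test_that("same seed gives identical initial queues and trajectories", {
  pipeline <- function() {
    s <- tumor_sim(8, hallmark_params(g = 5), seed = 99)
    q <- sim_queue(s)
    seed_cscs(s, 0.02)
    list(queue = q, traj = sim_run(s, 120), cells = sim_cells(s))
  }
  r1 <- pipeline(); r2 <- pipeline()
  expect_identical(r1$queue, r2$queue)
  expect_identical(r1$traj, r2$traj)
  expect_identical(r1$cells, r2$cells)
})

test_that("schedule_mitosis draws uniform integer delays on {5..10}", {
  sim <- tumor_sim(3, quiet_params(), seed = 5, fill = FALSE)
  id <- place_cells(sim, 0L, delay = 1000L)  # park the automatic event far out
  n <- 30000
  for (i in seq_len(n)) schedule_mitosis(sim, id)
  times <- sim_queue(sim)$time
  d <- times[times < 1000]  # drop the parked automatic event
  expect_true(all(d %in% 5:10))
  freq <- tabulate(factor(d, levels = 5:10), nbins = 6) / n
  se <- sqrt((1 / 6) * (5 / 6) / n)
  expect_true(all(abs(freq - 1 / 6) < 4 * se))
  expect_lt(abs(mean(d) - 7.5), 0.05)
})

test_that("stale events are discarded silently", {
  sim <- tumor_sim(4, quiet_params(), fill = FALSE)
  place_cells(sim, 0L, delay = 2L)
  remove_cells(sim, 0L)
  r <- sim_step(sim)
  expect_equal(r$outcome, "stale")
  expect_equal(sim_stats(sim)$events_stale, 1)
  expect_equal(sim_step(sim)$outcome, "empty_queue")
})

test_that("queue pops in time order with FIFO tie-breaking", {
  sim <- tumor_sim(4, quiet_params(), seed = 3, fill = FALSE)
  ids <- c(place_cells(sim, 0L, delay = 7L),
           place_cells(sim, 2L, delay = 5L),
           place_cells(sim, 4L, delay = 7L))
  r1 <- sim_step(sim); r2 <- sim_step(sim); r3 <- sim_step(sim)
  expect_equal(r1$cell, ids[2])               # earliest time first
  expect_equal(c(r2$cell, r3$cell), ids[c(1, 3)])  # tie: insertion order
  expect_true(r1$time <= r2$time && r2$time <= r3$time)
})

test_that("decision cascade outcomes match the event model", {
  # telomere 0 without effective immortality -> death on division attempt
  sim <- tumor_sim(5, quiet_params(), seed = 2, fill = FALSE)
  place_cells(sim, 62L, telomere = 0L, delay = 0L)
  expect_equal(sim_step(sim)$outcome, "died_telomere")
  expect_equal(sim_counts(sim)$n_empty, 125)

  # telomere 0 with EI -> divides
  sim <- tumor_sim(5, quiet_params(), seed = 2, fill = FALSE)
  place_cells(sim, 62L, hallmarks = "ei", telomere = 0L, delay = 0L)
  expect_equal(sim_step(sim)$outcome, "divided")

  # outside the growth region without self-growth -> quiescent requeue
  sim <- tumor_sim(10, hallmark_params(a = Inf, m = Inf), seed = 2,
                   fill = FALSE)
  expect_equal(sim$growth_margin, 1L)
  id <- place_cells(sim, 0L, delay = 0L)  # corner, outside region
  expect_equal(sim_step(sim)$outcome, "quiescent")
  expect_equal(sim_queue_size(sim), 1L)   # requeued
  expect_true(id %in% sim_cells(sim)$id)

  # same site with SG -> divides
  sim <- tumor_sim(10, hallmark_params(a = Inf, m = Inf), seed = 2,
                   fill = FALSE)
  place_cells(sim, 0L, hallmarks = "sg", delay = 0L)
  expect_equal(sim_step(sim)$outcome, "divided")

  # fully surrounded without IGI -> quiescent
  sim <- tumor_sim(4, quiet_params(), seed = 2)
  out <- sim_step(sim)
  expect_equal(out$outcome, "quiescent")
})

test_that("evade apoptosis makes damage death impossible", {
  p <- hallmark_params(a = Inf, m = Inf, e = 1, boundary_fraction = 1)
  sim <- uniform_population_sim(6, hallmark_names, p)  # 5 hallmarks, EA ON
  set.seed(7)
  invisible(sim_run(sim, 150))
  st <- sim_stats(sim)
  expect_gt(st$events_live, 3000)
  expect_equal(st$died_damage, 0)
})

test_that("division copies the genome, decrements telomeres, conserves sites", {
  sim <- tumor_sim(5, quiet_params(), seed = 4, fill = FALSE)
  mother <- place_cells(sim, 62L, hallmarks = c("sg", "gi"), delay = 1000L)
  before <- sim_counts(sim)
  divide_cell(sim, mother, 63L)
  cells <- sim_cells(sim)
  expect_equal(nrow(cells), 2)
  expect_equal(sim_counts(sim)$n_empty, before$n_empty - 1)  # exactly one new
  expect_true(all(cells$telomere == 49))     # decremented in both cells
  expect_true(all(cells$divisions == 1))
  daughter <- cells[cells$id != mother, ]
  expect_true(daughter$sg && daughter$gi)    # pure copy at mutation prob 0
  expect_false(daughter$ea || daughter$ei)
  expect_equal(sim_queue_size(sim), 3L)      # mother's old + two fresh events
  # occupied target without competition is a contract violation
  expect_error(divide_cell(sim, mother, 63L), "occupied")
})

test_that("IGI competition with g = 1 always replaces a neighbor", {
  p <- quiet_params(g = 1)
  sim <- tumor_sim(5, p, seed = 6)
  center <- site_index(5, c(2, 2, 2))
  igi <- place_cells(sim, center, hallmarks = "igi", delay = 1000L)
  before <- sim_counts(sim)
  expect_equal(compete_igi(sim, igi), "divided")
  after <- sim_counts(sim)
  # conservation: one death + one birth
  expect_equal(after$n_healthy, before$n_healthy - 1)
  expect_equal(after$n_dcc, before$n_dcc + 1)
  expect_equal(after$n_empty, 0)
  # contract: competition requires zero empty neighbors
  sim2 <- tumor_sim(5, p, seed = 6)
  igi2 <- place_cells(sim2, center, hallmarks = "igi", delay = 1000L)
  remove_cells(sim2, site_index(5, c(2, 2, 3)))
  expect_error(compete_igi(sim2, igi2), "fully occupied")
})

test_that("competition failure mode is configurable", {
  center <- site_index(5, c(2, 2, 2))
  # requeue mode (default): the loser survives
  sim <- tumor_sim(5, quiet_params(g = Inf), seed = 8)
  igi <- place_cells(sim, center, hallmarks = "igi", delay = 1000L)
  expect_equal(compete_igi(sim, igi), "quiescent")
  expect_true(igi %in% sim_cells(sim)$id)
  # loser-dies mode
  sim <- tumor_sim(5, quiet_params(g = Inf, igi_failure_kills = TRUE), seed = 8)
  igi <- place_cells(sim, center, hallmarks = "igi", delay = 1000L)
  expect_equal(compete_igi(sim, igi), "died_competition")
  expect_false(igi %in% sim_cells(sim)$id)
})

test_that("occupancy is conserved and consistent through a stochastic run", {
  sim <- tumor_sim(10, hallmark_params(m = 100, a = 200, g = 5), seed = 10)
  seed_cscs(sim, 0.01)
  tr <- sim_run(sim, 300)
  expect_true(all(tr$n_healthy + tr$n_dcc + tr$n_csc + tr$n_empty == 1000))
  expect_true(sim_validate(sim))
  expect_true(sim_stats(sim)$event_order_ok)
})

test_that("hallmark flags are monotone along any cell's lifetime", {
  sim <- tumor_sim(8, hallmark_params(m = 50, a = 100, boundary_fraction = 1),
                   seed = 13)
  invisible(sim_run(sim, 150))
  snap1 <- sim_cells(sim)
  invisible(sim_run(sim, 150))
  snap2 <- sim_cells(sim)
  joined <- merge(snap1, snap2, by = "id")
  expect_gt(nrow(joined), 50)
  for (h in c("sg", "igi", "ea", "ei", "gi"))
    expect_true(all(joined[[paste0(h, ".y")]] >= joined[[paste0(h, ".x")]]))
})

test_that("telomere ledger: tl0 - telomere equals lineage divisions", {
  sim <- tumor_sim(8, hallmark_params(a = 100, m = Inf, boundary_fraction = 1),
                   seed = 14)
  invisible(sim_run(sim, 400))
  cells <- sim_cells(sim)
  active <- cells[cells$telomere > 0 & cells$is_csc == 0, ]
  expect_gt(nrow(active), 100)
  expect_true(all(50 - active$telomere == active$divisions))
})

test_that("with all death channels disabled the population is constant", {
  sim <- tumor_sim(8, quiet_params(), seed = 15)
  tr <- sim_run(sim, 120)
  expect_true(all(tr$n_healthy == 512))
  expect_true(all(tr$deaths_random + tr$deaths_damage + tr$deaths_telomere +
                    tr$deaths_competition == 0))
})

test_that("run with zero iterations returns an empty trajectory", {
  sim <- tumor_sim(5, seed = 16)
  tr <- sim_run(sim, 0)
  expect_equal(nrow(tr), 0)
  expect_equal(sim_counts(sim)$n_healthy, 125)
})

test_that("no cancer mechanism means no DCCs ever", {
  sim <- tumor_sim(8, quiet_params(a = 500), seed = 17)  # deaths, no mutation
  tr <- sim_run(sim, 200)
  expect_true(all(tr$n_dcc == 0))
  expect_true(all(tr$n_csc == 0))
})
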