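test_that("record_counts reports exact registry counts and resets tallies", {
  sim <- tumor_sim(10, seed = 41)
  seed_cscs(sim, 0.01)
  row <- record_counts(sim)
  expect_equal(row$n_healthy, 990)
  expect_equal(row$n_dcc, 0)
  expect_equal(row$n_csc, 10)
  expect_equal(row$n_healthy + row$n_dcc + row$n_csc + row$n_empty, 1000)
  # a 100% kill drops n_dcc to zero in the next row
  remove_cells(sim, 0:4); place_cells(sim, 0:4, hallmarks = "sg")
  invisible(apply_treatment(sim, 1))
  row2 <- record_counts(sim)
  expect_equal(row2$n_dcc, 0)
  expect_equal(row2$treatment_kills, 5)
  expect_equal(record_counts(sim)$treatment_kills, 0)  # tally was reset
})

test_that("central_slice classifies the central plane on every axis", {
  sim <- tumor_sim(9, seed = 42)
  s <- central_slice(sim)
  expect_equal(dim(s), c(9, 9))
  expect_true(all(s == 1))                 # all healthy
  expect_equal(attr(s, "index"), 4L)
  # a CSC at the center shows up in the slice of each axis
  place_cells(sim, site_index(9, c(4, 4, 4)), is_csc = TRUE)
  for (ax in c("x", "y", "z")) {
    sl <- central_slice(sim, ax)
    expect_equal(sl[5, 5], 3L)
    expect_equal(sum(sl == 3), 1)
  }
  expect_error(central_slice(sim, index = 9), "bounds")
})

test_that("trajectory CSV round-trips bit-exactly", {
  sim <- tumor_sim(8, hallmark_params(m = 100, a = 300), seed = 43)
  seed_cscs(sim, 0.02)
  tr <- sim_run(sim, 60)
  path <- tempfile(fileext = ".csv")
  write_timeseries(tr, path)
  back <- read_timeseries(path)
  expect_equal(nrow(back), 60)
  for (cn in names(tr)) expect_identical(back[[cn]], tr[[cn]])
})

test_that("slice files are written in CSV and plain PGM formats", {
  sim <- tumor_sim(8, seed = 44)
  place_cells(sim, site_index(8, c(4, 4, 4)), is_csc = TRUE)
  s <- central_slice(sim)
  csv <- tempfile(fileext = ".csv")
  write_slice(s, csv, "csv")
  m <- as.matrix(utils::read.csv(csv, header = FALSE))
  expect_equal(unname(m), matrix(as.integer(s), nrow(s)))
  pgm <- tempfile(fileext = ".pgm")
  write_slice(s, pgm, "pgm")
  lines <- readLines(pgm)
  expect_equal(lines[1], "P2")
  expect_equal(lines[2], "8 8")
  expect_equal(lines[3], "255")
  expect_length(lines, 3 + 8)
  expect_true(any(grepl("255", lines[-(1:3)])))  # the CSC pixel
})

test_that("config JSON round-trips and is strictly validated", {
  cfg <- default_config(side = 12, iterations = 40, seed = 7)
  path <- tempfile(fileext = ".json")
  save_config(cfg, path)
  loaded <- load_config(path)
  expect_s3_class(loaded$params, "ca_params")
  expect_equal(unclass(loaded$params), unclass(hallmark_params()))
  expect_equal(loaded$run, list(side = 12L, iterations = 40L, seed = 7L))
  expect_equal(loaded$treatment$mode, "none")
  expect_true(is.infinite(loaded$treatment$end))

  # unknown keys are rejected
  bad <- jsonlite::read_json(path)
  bad$params$bogus <- 1
  p2 <- tempfile(fileext = ".json")
  jsonlite::write_json(bad, p2, auto_unbox = TRUE)
  expect_error(load_config(p2), "bogus")

  # a missing seed is an error naming the field
  bad2 <- jsonlite::read_json(path)
  bad2$run$seed <- NULL
  p3 <- tempfile(fileext = ".json")
  jsonlite::write_json(bad2, p3, auto_unbox = TRUE)
  expect_error(load_config(p3), "seed")
})

test_that("run_config executes a full configured simulation", {
  cfg <- load_config(save_config(default_config(side = 8, iterations = 25,
                                                seed = 3),
                                 tempfile(fileext = ".json")))
  res <- run_config(cfg)
  expect_equal(nrow(res$trajectory), 25)
  expect_equal(res$trajectory$n_csc[1], round(0.01 * 512))
})

test_that("the CLI runs, writes artifacts, and slices state dumps", {
  dir <- tempfile(); dir.create(dir)
  cfgpath <- file.path(dir, "cfg.json")
  save_config(default_config(side = 8, iterations = 20, seed = 5), cfgpath)
  out <- file.path(dir, "run1")
  suppressMessages(tumor_cli(c("run", "--config", cfgpath, "--out", out)))
  expect_true(file.exists(paste0(out, "_timeseries.csv")))
  expect_true(file.exists(paste0(out, "_final_occupancy.csv")))
  expect_true(file.exists(paste0(out, "_slice.pgm")))
  expect_equal(nrow(read_timeseries(paste0(out, "_timeseries.csv"))), 20)

  suppressMessages(tumor_cli(c("scenario", "--name", "fig2", "--scale", "0.2",
                               "--replicates", "1", "--seed-base", "2",
                               "--iterations", "15", "--out-dir", dir)))
  expect_true(file.exists(file.path(dir, "fig2_seed2_timeseries.csv")))

  sl <- file.path(dir, "slice.pgm")
  suppressMessages(tumor_cli(c("slice", "--state",
                               paste0(out, "_final_occupancy.csv"),
                               "--axis", "z", "--out", sl)))
  expect_equal(readLines(sl)[1:2], c("P2", "8 8"))
  expect_error(tumor_cli(c("explode")), "subcommand")
})
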