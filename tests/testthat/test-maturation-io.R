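test_that("planted-burst fixtures: conservation, ground truth, degenerate cases", {
  fx <- generate_bursty_fixture(n_units = 3, n_bursts = 20,
                                spikes_per_burst = 5, seed = 1)
  expect_equal(sum(lengths(fx$spike_trains$trains)), 3 * 20 * 5)
  expect_equal(nrow(fx$ground_truth), 60)
  # planted gaps respected: intra-burst ISI strictly below the gap
  gaps <- tapply(fx$ground_truth$start_s, fx$ground_truth$unit_id,
                 function(s) min(diff(sort(s))))
  expect_true(all(gaps > 0.01))

  fx0 <- generate_bursty_fixture(n_units = 2, n_bursts = 0,
                                 background_rate_hz = 1 / 60,
                                 duration_s = 120, seed = 2)
  expect_equal(nrow(fx0$ground_truth), 0)
  expect_gte(sum(lengths(fx0$spike_trains$trains)), 0)

  expect_error(generate_bursty_fixture(intra_burst_isi_s = 2, gap_s = 1),
               "smaller")
})

test_that("spike-train CSV round trip is exact and rejects malformed input", {
  sts <- sts_of(c(0, 0.005, 1.25), numeric(0), c(0.5), duration_s = 10)
  path <- tempfile(fileext = ".csv")
  write_spike_trains(sts, path)
  back <- read_spike_trains(path)
  expect_equal(back$trains, sts$trains)
  expect_equal(back$n_units, 3)           # empty unit preserved via sidecar
  expect_equal(back$duration_s, 10)

  # negative time rejected with its line number
  writeLines(c("unit_id,spike_time_s", "0,0.100000", "0,-0.200000"), path2 <- tempfile())
  expect_error(read_spike_trains(path2, duration_s = 1), "line 3")
  writeLines(c("unit_id,spike_time_s", "0,abc"), path3 <- tempfile())
  expect_error(read_spike_trains(path3, duration_s = 1), "line 2")
  # duration required without sidecar
  writeLines(c("unit_id,spike_time_s", "0,0.100000"), path4 <- tempfile())
  expect_error(read_spike_trains(path4), "duration_s")
})

test_that("config round trip rejects unknown keys", {
  p <- tempfile(fileext = ".json")
  write_config(list(duration_s = 60, n_neurons = 100), p)
  cfg <- read_config(p)
  expect_equal(cfg$duration_s, 60)
  write_config(list(duration_s = 60, tpyo = 1), p)
  expect_error(read_config(p), "tpyo")
})

test_that("maturation runs are reproducible and shaped as scheduled", {
  sched <- maturation_schedule(
    connection_probabilities = c(0.02, 0.05),
    bounds = list(parameter_bounds(0.07, 0.3, -0.1),
                  parameter_bounds(0.09, 0.5, -0.1)),
    runs_per_vmtp = 2L, n_neurons = 40L,
    config = simulation_config(duration_s = 30,
                               time_unit_convention = "per_slice"))
  a <- run_maturation(sched, seed = 5, n_units = 9)
  b <- run_maturation(sched, seed = 5, n_units = 9)
  expect_identical(a$summaries, b$summaries)
  expect_identical(a$report, b$report)

  expect_equal(nrow(a$summaries), 2 * 4)      # 2 time points x 4 features
  sr <- a$summaries[a$summaries$feature == "SR", ]
  expect_equal(sr$n, c(18, 18))               # 2 runs x 9 units pooled
  expect_true(all(sr$q1 <= sr$m & sr$m <= sr$q3))

  single <- maturation_schedule(connection_probabilities = 0.05,
                                bounds = list(parameter_bounds(0.09, 0.5, -0.1)),
                                runs_per_vmtp = 1L, n_neurons = 20L,
                                config = simulation_config(duration_s = 20))
  m1 <- run_maturation(single, seed = 1)
  expect_equal(unique(m1$summaries$mtp), 1)

  # schedule validation
  expect_error(maturation_schedule(connection_probabilities = c(0.1, 0.05)),
               "non-decreasing")
})

test_that("maturation report writer emits the summary, comparison and provenance", {
  sched <- maturation_schedule(connection_probabilities = 0.05,
                               bounds = list(parameter_bounds(0.09, 0.5, -0.1)),
                               runs_per_vmtp = 1L, n_neurons = 20L,
                               config = simulation_config(duration_s = 20))
  m <- run_maturation(sched, seed = 2)
  dir <- file.path(tempdir(), "matreport")
  write_maturation_report(m, dir)
  expect_true(file.exists(file.path(dir, "summaries.tsv")))
  expect_true(file.exists(file.path(dir, "report.tsv")))
  prov <- jsonlite::read_json(file.path(dir, "provenance.json"),
                              simplifyVector = TRUE)
  expect_equal(prov$seed, 2)
})

test_that("command-line interface: fixtures -> analyze -> report round trip", {
  csv <- tempfile(fileext = ".csv")
  inex_cli(c("fixtures", "--seed", "3", "--out", csv))
  expect_true(file.exists(csv))

  tsv <- tempfile(fileext = ".tsv")
  inex_cli(c("analyze", "--in", csv, "--out", tsv))
  feats <- read.delim(tsv)
  expect_true(all(c("unit_id", "spike_rate", "burst_rate") %in% names(feats)))
  expect_true(all(feats$n_bursts >= 1))   # planted bursts are found

  rep_tsv <- tempfile(fileext = ".tsv")
  inex_cli(c("report", "--in", tsv, "--out", rep_tsv))
  summ <- read.delim(rep_tsv)
  expect_equal(summ$feature, c("SR", "BR", "BD", "SB"))

  # simulate subcommand with a config file
  cfgp <- tempfile(fileext = ".json")
  write_config(list(n_neurons = 15, duration_s = 10,
                    connection_probability = 0.1,
                    c_upper = 0.09, y_exc_upper = 0.5, y_inh_upper = -0.1,
                    time_unit_convention = "per_slice"), cfgp)
  simcsv <- tempfile(fileext = ".csv")
  inex_cli(c("simulate", "--seed", "4", "--config", cfgp, "--out", simcsv))
  sts <- read_spike_trains(simcsv)
  expect_equal(sts$n_units, 15)
  expect_gt(sum(lengths(sts$trains)), 0)

  expect_error(inex_cli(c("bogus")), "unknown subcommand")
  expect_error(inex_cli(c("analyze", "--in")), "needs a value")
})
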