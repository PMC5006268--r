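test_that("firing rate: clamped sum of active inputs", {
  expect_equal(firing_rate(0.07, numeric(0), numeric(0)), 0.07)
  expect_equal(firing_rate(0.01, -0.5, 1), 0)           # clamped at zero
  expect_equal(firing_rate(0.02, c(0.3, 0.2, -0.1), c(1, 0, 1)), 0.22)
  expect_error(firing_rate(0.1, c(1, 2), 1), "equal length")
  expect_error(firing_rate(0.1, 0.5, 0.5), "0/1")
})

test_that("spike probability: value, maximum, domain errors", {
  expect_equal(spike_probability(0, 0.005), 0)
  expect_equal(spike_probability(200, 0.005), exp(-1))  # lambda*dt = 1
  expect_equal(spike_probability(0.07, 0.005), 3.4988e-4, tolerance = 1e-4)
  expect_error(spike_probability(-1, 0.005), ">= 0")
  expect_error(spike_probability(1, 0), "> 0")
})

test_that("advance_slice applies the threshold and one-slice history rules", {
  # single isolated neuron with c chosen for an exact per-slice probability
  mk_net <- function(c_i) {
    structure(list(neuron_types = "excitatory", basic_activity = c_i,
                   weights = Matrix::sparseMatrix(i = integer(0),
                                                  j = integer(0),
                                                  x = numeric(0),
                                                  dims = c(1, 1)),
                   spec = NULL), class = "inex_network")
  }
  cfg <- simulation_config(duration_s = 1, time_unit_convention = "per_slice")

  c35 <- c_for_slice_probability(0.35)
  expect_identical(advance_slice(0, mk_net(c35), cfg, x = 0.3), 1L)  # 0.3 < 0.35
  expect_identical(advance_slice(0, mk_net(c35), cfg, x = 0.4), 0L)  # 0.4 > 0.35

  # history: x = 0.5 becomes 0.05 after a spike, so P = 0.06 now fires
  c06 <- c_for_slice_probability(0.06)
  expect_identical(advance_slice(0, mk_net(c06), cfg, x = 0.5), 0L)
  expect_identical(advance_slice(1, mk_net(c06), cfg, x = 0.5), 1L)

  # P = 0 silences everything regardless of the draw
  expect_identical(advance_slice(0, mk_net(0), cfg, x = 0), 0L)
})

test_that("silent network stays silent and slice count matches duration/dt", {
  net <- generate_network(network_spec(20, 0.3, parameter_bounds(0, 0, 0),
                                       seed = 1))
  sts <- simulate_network(net, simulation_config(duration_s = 10), seed = 1)
  expect_equal(sum(lengths(sts$trains)), 0)
  expect_equal(sts$provenance$n_slices, 2000)
  expect_equal(simulation_config(300, 0.005)$duration_s / 0.005, 60000)
})

test_that("compiled core is bit-for-bit equivalent to the R reference slice loop", {
  net <- generate_network(network_spec(25, 0.25,
                                       parameter_bounds(0.09, 0.9, -0.9),
                                       seed = 11))
  cfg <- simulation_config(duration_s = 1.5, time_unit_convention = "per_slice")
  sts <- simulate_network(net, cfg, seed = 99)

  set.seed(99)
  n_slices <- floor(cfg$duration_s / cfg$dt)
  prev <- integer(25)
  ref <- rep(list(numeric(0)), 25)
  for (k in seq_len(n_slices) - 1L) {
    cur <- advance_slice(prev, net, cfg)
    for (i in which(cur == 1L)) ref[[i]] <- c(ref[[i]], k * cfg$dt)
    prev <- cur
  }
  expect_gt(sum(lengths(ref)), 50)  # the case actually exercises spiking
  expect_identical(lapply(sts$trains, as.numeric), ref)
})

test_that("simulation is seed-deterministic", {
  net <- generate_network(network_spec(50, 0.1, parameter_bounds(0.09, 0.5, -0.1),
                                       seed = 2))
  cfg <- simulation_config(duration_s = 20)
  a <- simulate_network(net, cfg, seed = 123)
  b <- simulate_network(net, cfg, seed = 123)
  expect_identical(a$trains, b$trains)
  d <- simulate_network(net, cfg, seed = 124)
  expect_false(identical(a$trains, d$trains))
})

test_that("raising the basic-activity bound does not lower the spike rate (paired seeds)", {
  rate <- function(c_upper, seed) {
    net <- generate_network(network_spec(
      100, 0.05, parameter_bounds(c_upper, 0.3, -0.1), seed = seed))
    sts <- simulate_network(net, simulation_config(duration_s = 60),
                            seed = seed)
    stats::median(60 * lengths(sts$trains) / 60)
  }
  lo <- vapply(1:10, function(s) rate(0.02, s), numeric(1))
  hi <- vapply(1:10, function(s) rate(0.09, s), numeric(1))
  expect_gte(stats::median(hi - lo), 0)
  expect_true(mean(hi >= lo) > 0.8)
})

test_that("strong inhibition does not raise the spike rate (paired seeds, dense net)", {
  rate <- function(y_inh, seed) {
    net <- generate_network(network_spec(
      100, 0.3, parameter_bounds(0.09, 0.5, y_inh),
      inhibitory_fraction = 0.2, seed = seed))
    sts <- simulate_network(net, simulation_config(duration_s = 60),
                            seed = seed)
    stats::median(60 * lengths(sts$trains) / 60)
  }
  none <- vapply(1:10, function(s) rate(0, s), numeric(1))
  strong <- vapply(1:10, function(s) rate(-0.9, s), numeric(1))
  expect_lte(stats::median(strong - none), 0)
})

test_that("isolated neurons with constant hazard match the Markov-chain oracle", {
  # reduced version of the acceptance-scale check: 50 neurons, 20000 slices
  p <- 0.002; f <- 0.1
  c_i <- c_for_slice_probability(p)
  net <- generate_network(network_spec(50, 0, parameter_bounds(1, 0, 0),
                                       seed = 1))
  net$basic_activity <- rep(c_i, 50)
  cfg <- simulation_config(duration_s = 100, time_unit_convention = "per_slice",
                           history_factor = f)
  sts <- simulate_network(net, cfg, seed = 8)
  counts <- lengths(sts$trains)
  expected <- 20000 * oracle_markov_rate(p, f)
  se <- stats::sd(counts) / sqrt(50)
  expect_lt(abs(mean(counts) - expected), 4 * se)
})
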