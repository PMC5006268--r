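#' Maturation schedule
#'
#' The six virtual measurement time points of the maturation experiment:
#' connectivity grows from 1% to 10% of all possible directed connections
#' (1, 2, 4, 6, 8, 10%), each time point gets its own parameter bounds, and
#' each is simulated `runs_per_vmtp` times with a freshly redrawn network.
#'
#' @param connection_probabilities non-decreasing vector, one per time point.
#' @param bounds list of [parameter_bounds()], one per time point; default:
#'   the published per-time-point bounds ([reference_bounds()]).
#' @param runs_per_vmtp repeated simulations per time point (default 10).
#' @param n_neurons network size (default 1000, the estimated number of
#'   active cells in a well).
#' @param inhibitory_fraction default 0.2.
#' @param triangular_mode_fraction default 1.
#' @param config shared [simulation_config()] (default: 300 s, 5 ms slices).
#' @return an object of class `maturation_schedule`.
#' @export
maturation_schedule <- function(connection_probabilities =
                                  c(0.01, 0.02, 0.04, 0.06, 0.08, 0.10),
                                bounds = NULL,
                                runs_per_vmtp = 10L,
                                n_neurons = 1000L,
                                inhibitory_fraction = 0.2,
                                triangular_mode_fraction = 1,
                                config = simulation_config()) {
  if (is.unsorted(connection_probabilities))
    stop("`connection_probabilities` must be non-decreasing", call. = FALSE)
  n_vmtp <- length(connection_probabilities)
  if (is.null(bounds)) {
    bt <- reference_bounds()
    if (n_vmtp > nrow(bt))
      stop("no default bounds for this many time points", call. = FALSE)
    bounds <- lapply(seq_len(n_vmtp), function(k)
      parameter_bounds(bt$c_upper[k], bt$y_exc_upper[k], bt$y_inh_upper[k]))
  }
  stopifnot(length(bounds) == n_vmtp)
  structure(list(connection_probabilities = connection_probabilities,
                 bounds = bounds, runs_per_vmtp = as.integer(runs_per_vmtp),
                 n_neurons = as.integer(n_neurons),
                 inhibitory_fraction = inhibitory_fraction,
                 triangular_mode_fraction = triangular_mode_fraction,
                 config = config),
            class = "maturation_schedule")
}

#' Run the maturation experiment
#'
#' For each virtual measurement time point: draw a fresh network at that
#' connectivity and bounds, simulate the configured number of runs, analyse
#' each run with the adaptive burst detector, pool the features of the first
#' `n_units` units across runs and summarise them as quartiles.  Finally the
#' summaries are compared with the experimental reference.  The whole report
#' is reproducible bit-for-bit from the master seed.
#'
#' @param schedule a [maturation_schedule()].
#' @param seed master seed; spawns one network seed and one simulation seed
#'   per (time point, run).
#' @param n_units units pooled per run (default 9, a virtual 6-well-MEA
#'   well: one simulated neuron corresponds to one electrode).
#' @param reference reference summaries for the comparison (default: the
#'   embedded medium-activity MEA table).
#' @return an object of class `maturation_result`: `summaries` (data frame
#'   `mtp`, `feature`, `q1`, `m`, `q3`, `n`), `report` (from
#'   [compare_to_reference()]), `pooled` (per-time-point pooled feature
#'   vectors), `schedule`, `provenance`.
#' @export
run_maturation <- function(schedule, seed = 1L, n_units = 9L,
                           reference = reference_table("MEA")) {
  stopifnot(inherits(schedule, "maturation_schedule"))
  n_vmtp <- length(schedule$connection_probabilities)
  n_runs <- schedule$runs_per_vmtp
  set.seed(seed)
  net_seeds <- matrix(sample.int(.Machine$integer.max, n_vmtp * n_runs),
                      nrow = n_vmtp)
  sim_seeds <- matrix(sample.int(.Machine$integer.max, n_vmtp * n_runs),
                      nrow = n_vmtp)

  feat_code <- c(spike_rate = "SR", burst_rate = "BR",
                 burst_duration_s = "BD", spikes_per_burst = "SB")
  summaries <- list(); pooled_all <- list()
  log_counts <- list()
  for (v in seq_len(n_vmtp)) {
    runs <- lapply(seq_len(n_runs), function(r) {
      spec <- network_spec(schedule$n_neurons,
                           schedule$connection_probabilities[v],
                           schedule$bounds[[v]],
                           inhibitory_fraction = schedule$inhibitory_fraction,
                           triangular_mode_fraction =
                             schedule$triangular_mode_fraction,
                           seed = net_seeds[v, r])
      net <- generate_network(spec)
      sts <- simulate_network(net, schedule$config, seed = sim_seeds[v, r])
      analyze_spike_trains(subset_units(sts, seq_len(n_units) - 1L))
    })
    pooled <- select_units_and_pool(runs, n_units)
    pooled_all[[v]] <- pooled
    summaries[[v]] <- do.call(rbind, lapply(names(feat_code), function(f) {
      q <- summarize_quartiles(pooled[[f]])
      data.frame(mtp = v, feature = feat_code[[f]],
                 q1 = q[["q1"]], m = q[["m"]], q3 = q[["q3"]],
                 n = sum(is.finite(pooled[[f]])))
    }))
    log_counts[[v]] <- data.frame(
      mtp = v, runs = n_runs,
      spikes_analyzed = sum(vapply(runs, function(x)
        sum(x$spike_rate) * schedule$config$duration_s / 60, numeric(1))),
      bursts_found = sum(vapply(runs, function(x) sum(x$n_bursts),
                                numeric(1))))
  }
  summaries <- do.call(rbind, summaries)
  rownames(summaries) <- NULL
  structure(list(
    summaries = summaries,
    report = compare_to_reference(summaries, reference),
    pooled = pooled_all,
    log = do.call(rbind, log_counts),
    schedule = schedule,
    provenance = list(seed = as.integer(seed), n_units = n_units,
                      time_unit_convention =
                        schedule$config$time_unit_convention,
                      triangular_mode_fraction =
                        schedule$triangular_mode_fraction)
  ), class = "maturation_result")
}

#' @export
print.maturation_result <- function(x, ...) {
  cat(sprintf("<maturation_result> %d time points, %d runs each (seed %d)\n",
              length(x$schedule$connection_probabilities),
              x$schedule$runs_per_vmtp, x$provenance$seed))
  sr <- x$summaries[x$summaries$feature == "SR", ]
  br <- x$summaries[x$summaries$feature == "BR", ]
  cat("median spike rate  (spikes/min):",
      paste(sprintf("%.2f", sr$m), collapse = " "), "\n")
  cat("median burst rate  (bursts/min):",
      paste(sprintf("%.2f", br$m), collapse = " "), "\n")
  if (!is.null(x$report)) {
    ok <- x$report$inside[x$report$feature == "SR"]
    cat(sprintf("spike-rate medians inside reference IQR: %d/%d\n",
                sum(ok, na.rm = TRUE), length(ok)))
  }
  invisible(x)
}
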