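#' Grid of parameter upper bounds
#'
#' Default axes are the published search space: basic-activity bound
#' 0.01..0.09 (step 0.01), excitatory bound 0.1..0.9 (step 0.1), inhibitory
#' bound -0.1..-0.9 (step -0.1); 9 x 9 x 9 = 729 candidates.
#'
#' @param c_uppers ordered values of the basic-activity bound.
#' @param y_exc_uppers ordered values of the excitatory bound.
#' @param y_inh_uppers ordered (negative) values of the inhibitory bound.
#' @return an object of class `search_grid`.
#' @export
search_grid <- function(c_uppers = seq(0.01, 0.09, by = 0.01),
                        y_exc_uppers = seq(0.1, 0.9, by = 0.1),
                        y_inh_uppers = seq(-0.1, -0.9, by = -0.1)) {
  if (!length(c_uppers) || !length(y_exc_uppers) || !length(y_inh_uppers))
    stop("all grid axes must be non-empty", call. = FALSE)
  structure(list(c_uppers = c_uppers, y_exc_uppers = y_exc_uppers,
                 y_inh_uppers = y_inh_uppers),
            class = "search_grid")
}

#' Enumerate a search grid
#'
#' Full Cartesian product in deterministic order: the basic-activity bound
#' varies slowest, then the excitatory bound, then the inhibitory bound.
#'
#' @param grid a [search_grid()].
#' @return data frame with columns `c_upper`, `y_exc_upper`, `y_inh_upper`,
#'   one row per candidate.
#' @export
build_grid <- function(grid = search_grid()) {
  stopifnot(inherits(grid, "search_grid"))
  g <- expand.grid(y_inh_upper = grid$y_inh_uppers,
                   y_exc_upper = grid$y_exc_uppers,
                   c_upper = grid$c_uppers,
                   KEEP.OUT.ATTRS = FALSE)
  g <- g[, c("c_upper", "y_exc_upper", "y_inh_upper")]
  rownames(g) <- NULL
  g
}

#' Search objective: distance of spike and burst rate to the reference
#'
#' `loss = |SR_sim - SR_ref| / SR_ref + |BR_sim - BR_ref| / BR_ref`
#' (a term falls back to the absolute deviation when its reference median is
#' zero).  A candidate whose simulated SR and BR medians both lie inside the
#' reference `[Q1, Q3]` is flagged in-range; in-range candidates are
#' preferred over any out-of-range candidate regardless of loss, which
#' implements "approximately in the range of the reference data" before
#' distance minimisation.
#'
#' @param sim_summary list with numeric `sr` and `br`, each named
#'   `c(q1, m, q3)` (e.g. from [summarize_quartiles()]).
#' @param ref_row same layout, the reference time point.
#' @return list with `loss` (non-negative) and `in_range` (logical).
#' @export
objective <- function(sim_summary, ref_row) {
  term <- function(sim_m, ref_m) {
    if (!is.finite(sim_m)) return(Inf)
    if (ref_m == 0) abs(sim_m - ref_m) else abs(sim_m - ref_m) / ref_m
  }
  loss <- term(sim_summary$sr[["m"]], ref_row$sr[["m"]]) +
    term(sim_summary$br[["m"]], ref_row$br[["m"]])
  in_range <- is.finite(sim_summary$sr[["m"]]) &&
    is.finite(sim_summary$br[["m"]]) &&
    sim_summary$sr[["m"]] >= ref_row$sr[["q1"]] &&
    sim_summary$sr[["m"]] <= ref_row$sr[["q3"]] &&
    sim_summary$br[["m"]] >= ref_row$br[["q1"]] &&
    sim_summary$br[["m"]] <= ref_row$br[["q3"]]
  list(loss = loss, in_range = in_range)
}

#' @keywords internal
ref_row_for_mtp <- function(ref_tab, mtp) {
  pick <- function(f) {
    r <- ref_tab[ref_tab$mtp == mtp & ref_tab$feature == f, ]
    c(q1 = r$q1[1], m = r$m[1], q3 = r$q3[1])
  }
  list(sr = pick("SR"), br = pick("BR"))
}

#' @keywords internal
#' Simulate one candidate (several runs with shared seeds) and summarise
#' the pooled SR/BR medians of the first `n_units` units.
simulate_candidate <- function(bounds, vmtp_config, net_seeds, sim_seeds,
                               n_units) {
  runs <- lapply(seq_along(net_seeds), function(r) {
    spec <- network_spec(vmtp_config$n_neurons,
                         vmtp_config$connection_probability,
                         bounds,
                         inhibitory_fraction = vmtp_config$inhibitory_fraction,
                         triangular_mode_fraction =
                           vmtp_config$triangular_mode_fraction,
                         seed = net_seeds[r])
    net <- generate_network(spec)
    sts <- simulate_network(net, vmtp_config$config, seed = sim_seeds[r])
    analyze_spike_trains(subset_units(sts, seq_len(n_units) - 1L))
  })
  pooled <- select_units_and_pool(runs, n_units)
  list(sr = summarize_quartiles(pooled$spike_rate),
       br = summarize_quartiles(pooled$burst_rate),
       bd = summarize_quartiles(pooled$burst_duration_s),
       sb = summarize_quartiles(pooled$spikes_per_burst))
}

#' Default per-time-point network and simulation settings
#'
#' @param connection_probability connectivity of the time point.
#' @param n_neurons network size (default 1000).
#' @param inhibitory_fraction default 0.2.
#' @param triangular_mode_fraction default 1.
#' @param config a [simulation_config()].
#' @return a plain list consumed by [brute_force_search()] and
#'   [run_maturation()].
#' @export
vmtp_config <- function(connection_probability, n_neurons = 1000L,
                        inhibitory_fraction = 0.2,
                        triangular_mode_fraction = 1,
                        config = simulation_config()) {
  list(connection_probability = connection_probability,
       n_neurons = as.integer(n_neurons),
       inhibitory_fraction = inhibitory_fraction,
       triangular_mode_fraction = triangular_mode_fraction,
       config = config)
}

#' Brute-force search over parameter upper bounds
#'
#' Simulates every candidate of the grid with shared per-run seeds (so that
#' candidates differ only in their bounds, not in their noise), summarises
#' the pooled spike- and burst-rate medians of the first `n_units` units and
#' scores them with [objective()] against the reference time point.  The
#' winner is the in-range candidate of minimal loss, or the overall minimal
#' loss when no candidate is in range.  The full per-candidate ledger is
#' returned.
#'
#' @param config a [vmtp_config()] (network size, connectivity, simulation
#'   settings of the time point).
#' @param grid a [search_grid()].
#' @param ref_row reference summaries, a list with `sr` and `br` entries
#'   (each `c(q1, m, q3)`), or an `mtp` number to pick from
#'   [reference_table()].
#' @param runs_per_candidate simulations per candidate (default 1; the
#'   selected bounds can then be re-run more often).
#' @param seed master seed; spawns the shared per-run substream seeds.
#' @param n_units units pooled per run (default 9).
#' @param ref reference table used when `ref_row` is an mtp number.
#' @param simulate_fn optional replacement for the simulation stage, mainly
#'   for testing the search machinery: a function of a [parameter_bounds()]
#'   object returning a list with `sr` and `br` quartile summaries.
#' @return an object of class `search_result`: `best` (parameter_bounds),
#'   `loss`, `in_range`, `ledger` (data frame over all candidates), `seeds`.
#' @export
brute_force_search <- function(config, grid = search_grid(), ref_row,
                               runs_per_candidate = 1L, seed = 1L,
                               n_units = 9L, ref = reference_table("MEA"),
                               simulate_fn = NULL) {
  stopifnot(runs_per_candidate >= 1)
  if (is.numeric(ref_row) && length(ref_row) == 1L)
    ref_row <- ref_row_for_mtp(ref, ref_row)
  cand <- build_grid(grid)
  set.seed(seed)
  net_seeds <- sample.int(.Machine$integer.max, runs_per_candidate)
  sim_seeds <- sample.int(.Machine$integer.max, runs_per_candidate)

  ledger <- vector("list", nrow(cand))
  for (k in seq_len(nrow(cand))) {
    b <- parameter_bounds(cand$c_upper[k], cand$y_exc_upper[k],
                          cand$y_inh_upper[k])
    s <- if (is.null(simulate_fn))
      simulate_candidate(b, config, net_seeds, sim_seeds, n_units)
    else simulate_fn(b)
    o <- objective(s, ref_row)
    ledger[[k]] <- data.frame(c_upper = b$c_upper,
                              y_exc_upper = b$y_exc_upper,
                              y_inh_upper = b$y_inh_upper,
                              sr_median = s$sr[["m"]], br_median = s$br[["m"]],
                              loss = o$loss, in_range = o$in_range)
  }
  ledger <- do.call(rbind, ledger)
  pool <- if (any(ledger$in_range)) which(ledger$in_range) else
    seq_len(nrow(ledger))
  best_k <- pool[which.min(ledger$loss[pool])]
  structure(list(
    best = parameter_bounds(ledger$c_upper[best_k],
                            ledger$y_exc_upper[best_k],
                            ledger$y_inh_upper[best_k]),
    loss = ledger$loss[best_k],
    in_range = ledger$in_range[best_k],
    best_index = best_k,
    ledger = ledger,
    seeds = list(master = seed, network = net_seeds, simulation = sim_seeds)
  ), class = "search_result")
}

#' @export
print.search_result <- function(x, ...) {
  cat(sprintf("<search_result> %d candidates; best: c=%g, y+=%g, y-=%g (loss %.4f%s)\n",
              nrow(x$ledger), x$best$c_upper, x$best$y_exc_upper,
              x$best$y_inh_upper, x$loss,
              if (x$in_range) ", in range" else ""))
  invisible(x)
}

#' Calibrate the model's under-specified conventions
#'
#' The rate equation leaves the unit of `lambda` (hence the effective slice
#' length in `lambda * dt`) open, and the triangular distributions' mode is
#' never stated.  This routine makes the choice explicit: every candidate
#' convention is simulated at the given time points with the published
#' per-time-point bounds and connectivity, scored with [objective()] against
#' the experimental (MEA) reference, and the convention with minimal summed
#' loss is returned together with the full diagnostics.
#'
#' @param conventions data frame with columns `time_unit_convention` and
#'   `triangular_mode_fraction`; default: all three unit conventions crossed
#'   with modes 0, 0.5, 1.
#' @param mtps time points to score (default 1 and 5: one sparse, one busy).
#' @param n_neurons,duration_s scale of the calibration simulations; the
#'   defaults (200 neurons, 60 s) keep the routine desk-scale.
#' @param runs_per_point simulations per convention and time point.
#' @param seed master seed.
#' @param n_units units pooled per run (default 9).
#' @return list with `chosen` (one-row data frame), `diagnostics` (per
#'   convention and mtp: SR/BR medians and loss) and `summed_loss`.
#' @export
calibrate_conventions <- function(conventions = NULL, mtps = c(1L, 5L),
                                  n_neurons = 200L, duration_s = 60,
                                  runs_per_point = 2L, seed = 1L,
                                  n_units = 9L) {
  if (is.null(conventions))
    conventions <- expand.grid(
      time_unit_convention = c("per_second", "per_slice", "per_millisecond"),
      triangular_mode_fraction = c(0, 0.5, 1),
      stringsAsFactors = FALSE)
  stopifnot(nrow(conventions) >= 1)
  ref <- reference_table("MEA")
  bounds_tab <- reference_bounds()
  set.seed(seed)
  net_seeds <- sample.int(.Machine$integer.max, runs_per_point)
  sim_seeds <- sample.int(.Machine$integer.max, runs_per_point)

  diag <- list()
  summed <- numeric(nrow(conventions))
  for (k in seq_len(nrow(conventions))) {
    conv <- conventions[k, ]
    for (mtp in mtps) {
      bt <- bounds_tab[bounds_tab$mtp == mtp, ]
      cfg <- vmtp_config(bt$connection_probability, n_neurons = n_neurons,
                         triangular_mode_fraction =
                           conv$triangular_mode_fraction,
                         config = simulation_config(
                           duration_s = duration_s,
                           time_unit_convention = conv$time_unit_convention))
      b <- parameter_bounds(bt$c_upper, bt$y_exc_upper, bt$y_inh_upper)
      s <- simulate_candidate(b, cfg, net_seeds, sim_seeds, n_units)
      o <- objective(s, ref_row_for_mtp(ref, mtp))
      summed[k] <- summed[k] + o$loss
      diag[[length(diag) + 1L]] <- data.frame(
        time_unit_convention = conv$time_unit_convention,
        triangular_mode_fraction = conv$triangular_mode_fraction,
        mtp = mtp, sr_median = s$sr[["m"]], br_median = s$br[["m"]],
        loss = o$loss)
    }
  }
  best <- which.min(summed)
  list(chosen = conventions[best, , drop = FALSE],
       summed_loss = summed[best],
       all_losses = cbind(conventions, summed_loss = summed),
       diagnostics = do.call(rbind, diag))
}
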