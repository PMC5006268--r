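#' Simulation configuration
#'
#' @param duration_s total simulated time in seconds (default 300, the length
#'   of one recording).
#' @param dt time-slice length in seconds (default 0.005; 5 ms covers an
#'   action potential plus refractory period, so at most one spike per slice).
#' @param history_factor multiplicative spike-history factor `f` in `(0, 1]`
#'   (default 0.1): in the slice immediately after a neuron spiked its
#'   uniform draw is multiplied by `f`, raising the chance of a follow-up
#'   spike and producing bursts.
#' @param time_unit_convention how the product `lambda * dt` in the spike
#'   probability is formed.  The model's rate equation carries no explicit
#'   units, so the effective slice length is a recorded calibration choice:
#'   `"per_second"` treats `lambda` as 1/s (`dt_eff = dt`), `"per_slice"`
#'   treats it as spikes/slice (`dt_eff = 1`), `"per_millisecond"` as 1/ms
#'   (`dt_eff = 1000 * dt`).  See [calibrate_conventions()].
#' @param seed default seed used by [simulate_network()] when none is given.
#' @return an object of class `simulation_config`.
#' @export
simulation_config <- function(duration_s = 300, dt = 0.005,
                              history_factor = 0.1,
                              time_unit_convention = c("per_second",
                                                       "per_slice",
                                                       "per_millisecond"),
                              seed = 1L) {
  stopifnot(duration_s > 0, dt > 0,
            history_factor > 0, history_factor <= 1)
  time_unit_convention <- match.arg(time_unit_convention)
  structure(list(duration_s = duration_s, dt = dt,
                 history_factor = history_factor,
                 time_unit_convention = time_unit_convention,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' @keywords internal
dt_effective <- function(config) {
  switch(config$time_unit_convention,
         per_second = config$dt,
         per_slice = 1,
         per_millisecond = config$dt * 1000)
}

#' Momentary firing rate of one neuron
#'
#' `lambda = max(0, c_i + sum(y_ji * s_j))`: basic activity plus the summed
#' strengths of the presynaptic neurons that spiked in the previous slice,
#' clamped at zero.
#'
#' @param c_i basic activity of the neuron (>= 0).
#' @param incoming_weights numeric vector of synaptic strengths `y_ji`.
#' @param prev_spike_indicators 0/1 vector, same length: which presynaptic
#'   neurons spiked in the previous slice.
#' @return the clamped momentary rate, a single non-negative number.
#' @examples
#' firing_rate(0.02, c(0.3, 0.2, -0.1), c(1, 0, 1))  # 0.22
#' @export
firing_rate <- function(c_i, incoming_weights, prev_spike_indicators) {
  if (length(incoming_weights) != length(prev_spike_indicators))
    stop("`incoming_weights` and `prev_spike_indicators` must have equal length",
         call. = FALSE)
  if (length(prev_spike_indicators) &&
      !all(prev_spike_indicators %in% c(0, 1)))
    stop("`prev_spike_indicators` must be 0/1", call. = FALSE)
  max(0, c_i + sum(incoming_weights * prev_spike_indicators))
}

#' Per-slice spike probability
#'
#' `P = (lambda * dt) * exp(-lambda * dt)`, the probability of exactly one
#' event of a Poisson process with rate `lambda` in a slice of length `dt`.
#' The value is bounded by `exp(-1)` (attained at `lambda * dt = 1`); for
#' larger `lambda * dt` the probability *decreases*, so very strong input
#' self-quenches.
#'
#' @param lambda_i momentary rate(s), >= 0.  Vectorised.
#' @param dt_effective slice length(s) expressed in the rate's time unit.
#' @return probabilities in `[0, exp(-1)]`.
#' @examples
#' spike_probability(0.07, 0.005)        # 3.4988e-4
#' spike_probability(200, 0.005)         # exp(-1), the maximum
#' @export
spike_probability <- function(lambda_i, dt_effective) {
  if (any(lambda_i < 0)) stop("`lambda_i` must be >= 0", call. = FALSE)
  if (any(dt_effective <= 0)) stop("`dt_effective` must be > 0", call. = FALSE)
  x <- lambda_i * dt_effective
  x * exp(-x)
}

#' Advance the network by one time slice
#'
#' Reference (pure-R) implementation of the update rule used by the compiled
#' simulation core; useful for inspection and as an equivalence oracle.  For
#' each neuron a uniform draw `x_i` is taken (in neuron order); neurons that
#' spiked in the previous slice have `x_i` multiplied by the history factor;
#' a spike is emitted iff the adjusted draw is `< P_i`.
#'
#' @param previous_spikes 0/1 vector of length `n_neurons`.
#' @param network an `inex_network`.
#' @param config a [simulation_config()].
#' @param x optional vector of uniform draws, for deterministic testing;
#'   default `runif(n)` from the current RNG state.
#' @return integer 0/1 vector of spikes in the new slice.
#' @export
advance_slice <- function(previous_spikes, network, config, x = NULL) {
  n <- length(network$neuron_types)
  if (length(previous_spikes) != n)
    stop("`previous_spikes` must have one entry per neuron", call. = FALSE)
  lambda <- pmax(0, network$basic_activity +
                   as.vector(Matrix::crossprod(network$weights,
                                               as.numeric(previous_spikes))))
  p <- spike_probability(lambda, dt_effective(config))
  if (is.null(x)) x <- runif(n)
  x_eff <- ifelse(previous_spikes == 1, config$history_factor * x, x)
  as.integer(x_eff < p)
}

#' Simulate spontaneous activity of a network
#'
#' Runs `floor(duration_s / dt)` synchronous slices from an all-silent
#' initial state and returns one spike train per neuron.  Spike times are the
#' slice start times.  The run is deterministic given the seed.
#'
#' @param network an `inex_network`.
#' @param config a [simulation_config()].
#' @param seed integer seed; defaults to `config$seed`.
#' @return a `spike_train_set`: list with `trains` (list of numeric vectors
#'   of spike times in seconds, one per neuron, unit ids `0..n-1`),
#'   `duration_s`, `n_units` and a `provenance` record (seed, conventions).
#' @examples
#' net <- generate_network(network_spec(20, 0.1,
#'   parameter_bounds(0.09, 0.5, -0.1), seed = 7))
#' sts <- simulate_network(net, simulation_config(duration_s = 30), seed = 7)
#' sum(lengths(sts$trains))
#' @export
simulate_network <- function(network, config = simulation_config(),
                             seed = config$seed) {
  stopifnot(inherits(network, "inex_network"),
            inherits(config, "simulation_config"))
  n_slices <- floor(config$duration_s / config$dt)
  # outgoing-edge view: column j holds the targets of presynaptic neuron j
  w_out <- methods::as(Matrix::t(network$weights), "CsparseMatrix")
  set.seed(seed)
  slices <- inex_core(network$basic_activity, w_out@i, w_out@p, w_out@x,
                      dt_effective(config), config$history_factor,
                      as.integer(n_slices))
  trains <- lapply(slices, function(k) k * config$dt)
  spike_train_set(trains, config$duration_s,
                  provenance = list(seed = as.integer(seed),
                                    dt = config$dt,
                                    history_factor = config$history_factor,
                                    time_unit_convention =
                                      config$time_unit_convention,
                                    n_slices = n_slices))
}

#' Construct a spike-train set
#'
#' @param trains list of numeric vectors of spike times (seconds), one per
#'   unit; unit ids are `0..n-1` in list order.
#' @param duration_s recording length; all times must lie in
#'   `[0, duration_s)`.
#' @param provenance optional named list recorded alongside the data.
#' @return an object of class `spike_train_set`.
#' @export
spike_train_set <- function(trains, duration_s, provenance = list()) {
  stopifnot(is.list(trains), duration_s > 0)
  for (tr in trains) {
    if (length(tr) && (is.unsorted(tr, strictly = TRUE) ||
                       tr[1] < 0 || tr[length(tr)] >= duration_s))
      stop("spike times must be strictly increasing within [0, duration_s)",
           call. = FALSE)
  }
  structure(list(trains = trains, duration_s = duration_s,
                 n_units = length(trains), provenance = provenance),
            class = "spike_train_set")
}

#' @export
print.spike_train_set <- function(x, ...) {
  ns <- sum(lengths(x$trains))
  cat(sprintf("<spike_train_set> %d units, %.0f s, %d spikes (%.2f spikes/min/unit)\n",
              x$n_units, x$duration_s, ns,
              if (x$n_units) 60 * ns / x$duration_s / x$n_units else 0))
  invisible(x)
}

#' Keep a subset of units
#'
#' @param x a `spike_train_set`.
#' @param units integer unit ids (0-based) to keep, in the given order.
#' @return a `spike_train_set` with the selected units renumbered `0..k-1`.
#' @export
subset_units <- function(x, units) {
  stopifnot(inherits(x, "spike_train_set"), all(units >= 0),
            all(units < x$n_units))
  spike_train_set(x$trains[units + 1L], x$duration_s, x$provenance)
}
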