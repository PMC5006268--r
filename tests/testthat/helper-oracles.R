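# Independent oracles, deliberately written from scratch (no calls into the
# package's own implementations of the same quantities).

# quartiles by explicit sort-and-interpolate between closest ranks
oracle_quartiles <- function(x) {
  x <- sort(x[is.finite(x)])
  n <- length(x)
  one <- function(p) {
    h <- (n - 1) * p
    lo <- floor(h)
    if (lo + 1 >= n) return(x[n])
    x[lo + 1] + (h - lo) * (x[lo + 2] - x[lo + 1])
  }
  c(one(0.25), one(0.5), one(0.75))
}

# CMA/skewness threshold rule, brute force: explicit histogram loop,
# running-mean loop, moment skewness, linear scan for the closest CMA value
oracle_cma_threshold <- function(isis, bin_width) {
  k_max <- 0L
  for (v in isis) k_max <- max(k_max, as.integer(ceiling(round(v / bin_width, 9))))
  counts <- rep(0L, k_max)
  for (v in isis) {
    k <- max(1L, as.integer(ceiling(round(v / bin_width, 9))))
    counts[k] <- counts[k] + 1L
  }
  if (k_max == 1L) return(bin_width)
  cma <- numeric(k_max)
  s <- 0
  for (k in seq_len(k_max)) { s <- s + counts[k]; cma[k] <- s / k }
  cma_m <- sum(cma) / k_max
  m1 <- sum(isis) / length(isis)
  m2 <- sum((isis - m1)^2) / length(isis)
  m3 <- sum((isis - m1)^3) / length(isis)
  alpha <- if (m2 == 0) 0 else m3 / m2^1.5
  target <- alpha * cma_m
  best <- 1L
  for (k in seq_len(k_max))
    if (abs(cma[k] - target) < abs(cma[best] - target)) best <- k
  best * bin_width
}

# stationary spike rate of an isolated neuron: two-state Markov chain over
# "spiked in previous slice"; p = P(spike | silent), q = min(1, p / f)
oracle_markov_rate <- function(p, f) p / (1 + p - min(1, p / f))

# exhaustive validity scan of a burst set against the threshold / min-count
# rules; returns TRUE when every burst is a maximal qualifying run
bursts_valid <- function(spike_times, bursts, threshold, min_spikes = 3) {
  if (nrow(bursts) == 0) return(TRUE)
  for (b in seq_len(nrow(bursts))) {
    i1 <- match(bursts$start_s[b], spike_times)
    i2 <- match(bursts$end_s[b], spike_times)
    if (is.na(i1) || is.na(i2)) return(FALSE)
    if (i2 - i1 + 1 != bursts$n_spikes[b]) return(FALSE)
    if (bursts$n_spikes[b] < min_spikes) return(FALSE)
    if (any(diff(spike_times[i1:i2]) > threshold)) return(FALSE)
    if (i1 > 1 && spike_times[i1] - spike_times[i1 - 1] <= threshold)
      return(FALSE)
    if (i2 < length(spike_times) &&
        spike_times[i2 + 1] - spike_times[i2] <= threshold)
      return(FALSE)
  }
  TRUE
}

# basic activity giving an exact per-slice spike probability under the
# per-slice unit convention: solves c * exp(-c) = p on (0, 1)
c_for_slice_probability <- function(p) {
  stats::uniroot(function(c) c * exp(-c) - p, c(1e-12, 1))$root
}

# small helper: spike-train set of explicit trains
sts_of <- function(..., duration_s) {
  spike_train_set(list(...), duration_s)
}
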