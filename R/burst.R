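#' Interspike-interval histogram
#'
#' Histogram of successive spike-time differences with fixed-width bins
#' `(0, w], (w, 2w], ...` covering the largest ISI.  The raw ISI sample is
#' retained because the adaptive threshold uses its skewness.
#'
#' @param spike_times sorted spike times in seconds.
#' @param bin_width_s bin width in seconds; default 0.005 (= the simulation
#'   slice, the finest ISI resolution the simulator can produce).
#' @return an object of class `isi_histogram` with fields `bin_width_s`,
#'   `right_edges`, `counts`, `n_isi` and `isis`.  Fewer than two spikes
#'   yield the empty sentinel (`n_isi = 0`), in which case no bursts can be
#'   detected.
#' @export
isi_histogram <- function(spike_times, bin_width_s = 0.005) {
  stopifnot(bin_width_s > 0)
  if (length(spike_times) > 1 && is.unsorted(spike_times))
    stop("`spike_times` must be sorted", call. = FALSE)
  if (length(spike_times) < 2) {
    return(structure(list(bin_width_s = bin_width_s,
                          right_edges = numeric(0), counts = integer(0),
                          n_isi = 0L, isis = numeric(0)),
                     class = "isi_histogram"))
  }
  isis <- diff(spike_times)
  # round before ceiling so an ISI sitting on a bin edge (up to fp error)
  # lands in the bin whose right edge it equals
  idx <- pmax(1L, as.integer(ceiling(round(isis / bin_width_s, 9))))
  counts <- tabulate(idx, nbins = max(idx))
  structure(list(bin_width_s = bin_width_s,
                 right_edges = seq_along(counts) * bin_width_s,
                 counts = as.integer(counts),
                 n_isi = length(isis), isis = isis),
            class = "isi_histogram")
}

#' @export
print.isi_histogram <- function(x, ...) {
  cat(sprintf("<isi_histogram> %d ISIs in %d bins of %g s\n",
              x$n_isi, length(x$counts), x$bin_width_s))
  invisible(x)
}

#' Cumulative moving average of ISI-histogram counts
#'
#' `CMA[k] = mean(counts[1:k])`, the running mean of the bin counts from the
#' shortest-ISI bin up to bin k.
#'
#' @param hist an [isi_histogram()] with at least one ISI.
#' @return numeric vector, one value per bin.
#' @export
cma_curve <- function(hist) {
  stopifnot(inherits(hist, "isi_histogram"))
  if (hist$n_isi == 0L) stop("empty ISI histogram", call. = FALSE)
  cumsum(hist$counts) / seq_along(hist$counts)
}

#' Fisher-Pearson sample skewness
#' @keywords internal
fp_skewness <- function(x) {
  n <- length(x)
  if (n < 2) return(0)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) return(0)
  mean((x - m)^3) / m2^1.5
}

#' Adaptive burst ISI threshold (CMA/skewness rule)
#'
#' The burst threshold adapts to the dynamics of the spike train instead of
#' using a fixed ISI: the cumulative moving average (CMA) of the ISI
#' histogram is computed, summarised by `CMA_m` (its mean by default, its
#' maximum optionally, matching the original formulation of the tool), and
#' the threshold is the ISI of the bin whose CMA value is closest to
#' `alpha * CMA_m`, where `alpha` is the skewness of the ISI sample.  Ties
#' are broken toward the smaller ISI (more conservative bursts); the bin's
#' representative ISI is its right edge.
#'
#' @param hist an [isi_histogram()] with at least one ISI.
#' @param alpha_mode `"raw"` (default) uses the Fisher-Pearson skewness of
#'   the raw ISI sample directly as `alpha`; `"coefficient"` clamps it into
#'   `[0.3, 1]` before use.
#' @param cma_stat `"mean"` (default) or `"max"`: the CMA summary `CMA_m`.
#' @param semantics `"cma_match"` (default) matches `alpha * CMA_m` against
#'   the CMA curve (counts scale) and returns the matching bin's ISI;
#'   `"literal"` reads `alpha * CMA_m` as seconds and snaps it to the nearest
#'   observed ISI.
#' @return the threshold in seconds.  A single-bin histogram returns that
#'   bin's ISI.
#' @export
burst_threshold <- function(hist, alpha_mode = c("raw", "coefficient"),
                            cma_stat = c("mean", "max"),
                            semantics = c("cma_match", "literal")) {
  stopifnot(inherits(hist, "isi_histogram"))
  alpha_mode <- match.arg(alpha_mode)
  cma_stat <- match.arg(cma_stat)
  semantics <- match.arg(semantics)
  if (hist$n_isi == 0L)
    stop("cannot compute a burst threshold without ISIs", call. = FALSE)
  if (length(hist$counts) == 1L) return(hist$right_edges[1L])
  cma <- cma_curve(hist)
  cma_m <- if (cma_stat == "mean") mean(cma) else max(cma)
  alpha <- fp_skewness(hist$isis)
  if (alpha_mode == "coefficient") alpha <- min(max(alpha, 0.3), 1)
  target <- alpha * cma_m
  if (semantics == "cma_match") {
    hist$right_edges[which.min(abs(cma - target))]
  } else {
    iso <- sort(hist$isis)
    iso[which.min(abs(iso - target))]
  }
}

#' Detect bursts in one spike train
#'
#' A burst is a maximal run of consecutive spikes whose successive ISIs are
#' all `<= threshold_s`, kept if it contains at least `min_spikes` spikes.
#' Burst duration is the time between the first and the last spike of the
#' run.
#'
#' @param spike_times sorted spike times in seconds.
#' @param threshold_s burst ISI threshold (> 0), typically from
#'   [burst_threshold()].
#' @param min_spikes minimum spikes per burst (default 3).
#' @return a data frame with columns `start_s`, `end_s`, `n_spikes`; zero
#'   rows when no bursts are found.  Bursts are ordered and non-overlapping
#'   by construction.
#' @examples
#' detect_bursts(c(0, 0.01, 0.02, 1, 1.01, 1.02, 1.03), 0.05)
#' @export
detect_bursts <- function(spike_times, threshold_s, min_spikes = 3L) {
  stopifnot(threshold_s > 0, min_spikes >= 1)
  empty <- data.frame(start_s = numeric(0), end_s = numeric(0),
                      n_spikes = integer(0))
  n <- length(spike_times)
  if (n < min_spikes) return(empty)
  if (is.unsorted(spike_times)) stop("`spike_times` must be sorted",
                                     call. = FALSE)
  ok <- diff(spike_times) <= threshold_s
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & (r$lengths + 1L >= min_spikes)
  if (!any(keep)) return(empty)
  first <- starts[keep]               # index of first ISI in run
  last <- ends[keep] + 1L             # index of last spike in run
  data.frame(start_s = spike_times[first], end_s = spike_times[last],
             n_spikes = last - first + 1L)
}

#' Spike/burst features of one unit
#'
#' The four validation features: spike rate (spikes/min), burst rate
#' (bursts/min), mean burst duration (s) and mean spikes per burst.  When the
#' unit has no bursts the burst rate is 0 and the two burst-structure
#' features are `NA` (a zero-length burst is undefined).
#'
#' @param spike_times sorted spike times in seconds.
#' @param bursts burst data frame from [detect_bursts()].
#' @param duration_s recording duration in seconds (> 0).
#' @return one-row data frame with columns `spike_rate`, `burst_rate`,
#'   `burst_duration_s`, `spikes_per_burst`, `n_bursts`.
#' @export
extract_features <- function(spike_times, bursts, duration_s) {
  stopifnot(duration_s > 0)
  nb <- nrow(bursts)
  data.frame(
    spike_rate = 60 * length(spike_times) / duration_s,
    burst_rate = 60 * nb / duration_s,
    burst_duration_s = if (nb) mean(bursts$end_s - bursts$start_s) else NA_real_,
    spikes_per_burst = if (nb) mean(bursts$n_spikes) else NA_real_,
    n_bursts = nb
  )
}

#' Per-unit burst analysis of a spike-train set
#'
#' Runs the full adaptive pipeline on every unit: ISI histogram, CMA
#' threshold, burst detection, feature extraction.  Units with fewer than 4
#' spikes cannot contain a 3-spike burst with a meaningful adaptive
#' threshold; for them only the spike rate is reported (no burst analysis is
#' attempted, burst rate 0).
#'
#' @param x a `spike_train_set`.
#' @param bin_width_s ISI histogram bin width (default 0.005 s).
#' @param min_spikes minimum spikes per burst (default 3).
#' @inheritParams burst_threshold
#' @return data frame with one row per unit: `unit_id` (0-based),
#'   `spike_rate`, `burst_rate`, `burst_duration_s`, `spikes_per_burst`,
#'   `n_bursts`.
#' @export
analyze_spike_trains <- function(x, bin_width_s = 0.005,
                                 alpha_mode = "raw", cma_stat = "mean",
                                 semantics = "cma_match", min_spikes = 3L) {
  stopifnot(inherits(x, "spike_train_set"))
  rows <- lapply(seq_along(x$trains), function(u) {
    st <- x$trains[[u]]
    if (length(st) < 4) {
      f <- extract_features(st, detect_bursts(numeric(0), 1), x$duration_s)
    } else {
      h <- isi_histogram(st, bin_width_s)
      thr <- burst_threshold(h, alpha_mode = alpha_mode, cma_stat = cma_stat,
                             semantics = semantics)
      b <- if (thr > 0) detect_bursts(st, thr, min_spikes) else
        detect_bursts(numeric(0), 1)
      f <- extract_features(st, b, x$duration_s)
    }
    cbind(unit_id = u - 1L, f)
  })
  do.call(rbind, rows)
}
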