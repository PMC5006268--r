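#' Synthetic spike trains with planted bursts
#'
#' Ground-truth fixture generator for the burst pipeline: each unit carries
#' `n_bursts` planted bursts (regular intra-burst ISI) separated by gaps of
#' at least `gap_s`, plus optional homogeneous-Poisson background spikes.
#' The intra-burst ISI must be shorter than the gap so the planted structure
#' is well defined.
#'
#' @param n_units number of units.
#' @param n_bursts planted bursts per unit.
#' @param spikes_per_burst spikes per planted burst (>= 3).
#' @param intra_burst_isi_s ISI inside a burst (default 0.01 s).
#' @param gap_s minimum silent gap between bursts (default 1 s).
#' @param background_rate_hz homogeneous background spike rate per unit
#'   (default 0).
#' @param duration_s total duration; default: just enough to hold the bursts
#'   with their gaps.
#' @param seed integer seed.
#' @return list with `spike_trains` (a `spike_train_set`) and `ground_truth`
#'   (data frame `unit_id`, `start_s`, `end_s`, `n_spikes`).
#' @export
generate_bursty_fixture <- function(n_units = 5L, n_bursts = 20L,
                                    spikes_per_burst = 5L,
                                    intra_burst_isi_s = 0.01,
                                    gap_s = 1, background_rate_hz = 0,
                                    duration_s = NULL, seed = 1L) {
  stopifnot(spikes_per_burst >= 3 || n_bursts == 0, gap_s > 0)
  if (n_bursts > 0 && intra_burst_isi_s >= gap_s)
    stop("`intra_burst_isi_s` must be smaller than `gap_s`", call. = FALSE)
  burst_len <- (spikes_per_burst - 1) * intra_burst_isi_s
  slot <- burst_len + gap_s
  if (is.null(duration_s)) duration_s <- max(n_bursts * slot + gap_s, 1)
  if (n_bursts > 0 && duration_s < n_bursts * slot)
    stop("`duration_s` too short for the requested bursts", call. = FALSE)
  set.seed(seed)
  trains <- vector("list", n_units)
  gt <- list()
  for (u in seq_len(n_units)) {
    st <- numeric(0)
    if (n_bursts > 0) {
      jitter <- runif(n_bursts, 0, min(gap_s / 4, (duration_s - n_bursts * slot)
                                       / max(n_bursts, 1)))
      starts <- (seq_len(n_bursts) - 1L) * slot + gap_s / 4 + jitter
      spikes <- rep(starts, each = spikes_per_burst) +
        rep(seq_len(spikes_per_burst) - 1L, n_bursts) * intra_burst_isi_s
      st <- spikes
      gt[[u]] <- data.frame(unit_id = u - 1L, start_s = starts,
                            end_s = starts + burst_len,
                            n_spikes = spikes_per_burst)
    } else {
      gt[[u]] <- data.frame(unit_id = integer(0), start_s = numeric(0),
                            end_s = numeric(0), n_spikes = integer(0))
    }
    if (background_rate_hz > 0) {
      nb <- rpois(1, background_rate_hz * duration_s)
      st <- c(st, runif(nb, 0, duration_s))
    }
    st <- sort(st)
    st <- st[!duplicated(st)]
    trains[[u]] <- st[st < duration_s]
  }
  list(spike_trains = spike_train_set(trains, duration_s,
                                      provenance = list(seed = seed,
                                                        fixture = "planted_bursts")),
       ground_truth = do.call(rbind, gt))
}

#' Recovery of planted bursts
#'
#' Matches detected against planted bursts: a planted burst counts as
#' recovered when some detected burst overlaps it, and a detected burst
#' spans a planted gap when it overlaps two different planted bursts of the
#' same unit.
#'
#' @param detected data frame `unit_id`, `start_s`, `end_s` (detected).
#' @param truth ground-truth data frame from [generate_bursty_fixture()].
#' @return list with `recovered` (fraction of planted bursts overlapped by a
#'   detection), `spanning` (number of detections bridging two planted
#'   bursts).
#' @export
burst_recovery <- function(detected, truth) {
  if (nrow(truth) == 0)
    return(list(recovered = NA_real_, spanning = 0L))
  hit <- logical(nrow(truth)); spanning <- 0L
  for (u in unique(truth$unit_id)) {
    tu <- which(truth$unit_id == u)
    du <- detected[detected$unit_id == u, , drop = FALSE]
    for (d in seq_len(nrow(du))) {
      ov <- truth$start_s[tu] <= du$end_s[d] & truth$end_s[tu] >= du$start_s[d]
      hit[tu[ov]] <- TRUE
      if (sum(ov) >= 2) spanning <- spanning + 1L
    }
  }
  list(recovered = mean(hit), spanning = spanning)
}
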