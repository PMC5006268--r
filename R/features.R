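#' Quartile summary of a feature vector
#'
#' Q1, median and Q3 by linear interpolation between closest ranks (the
#' default quantile definition of mainstream numeric stacks, R type 7).
#' `NA` values (absent burst features of burst-less units) are dropped.
#'
#' @param values numeric vector.
#' @return named numeric vector `c(q1, m, q3)`; all-`NA` input yields `NA`s.
#' @examples
#' summarize_quartiles(1:9)  # 3 5 7
#' @export
summarize_quartiles <- function(values) {
  v <- values[is.finite(values)]
  if (!length(v)) return(c(q1 = NA_real_, m = NA_real_, q3 = NA_real_))
  q <- quantile(v, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  c(q1 = q[1], m = q[2], q3 = q[3])
}

#' Pool the first units of several runs
#'
#' Takes units `0..n_units-1` from each run's feature table and pools their
#' values per feature across runs, mirroring the analysis of the first nine
#' electrodes of a well over ten repeated simulations (10 x 9 = 90 values
#' per feature).
#'
#' @param runs list of per-unit feature tables as returned by
#'   [analyze_spike_trains()].
#' @param n_units number of leading units to take from each run (default 9,
#'   one virtual well of a 6-well MEA).
#' @return named list of numeric vectors: `spike_rate`, `burst_rate`,
#'   `burst_duration_s`, `spikes_per_burst`, each of length
#'   `length(runs) * n_units` (burst-structure entries may be `NA`).
#' @export
select_units_and_pool <- function(runs, n_units = 9L) {
  stopifnot(is.list(runs), length(runs) >= 1, n_units >= 1)
  feats <- c("spike_rate", "burst_rate", "burst_duration_s",
             "spikes_per_burst")
  picked <- lapply(runs, function(tab) {
    if (nrow(tab) < n_units)
      stop(sprintf("run has %d units, %d requested", nrow(tab), n_units),
           call. = FALSE)
    tab[order(tab$unit_id)[seq_len(n_units)], , drop = FALSE]
  })
  stats::setNames(lapply(feats, function(f)
    unlist(lapply(picked, `[[`, f), use.names = FALSE)), feats)
}

#' Mark inactive channels and drop sparse wells
#'
#' A channel is inactive when its spike rate at its last available
#' measurement time point is strictly below `rate_threshold` (default
#' 20 spikes/min).  Wells with fewer than `min_active_channels` active
#' channels (default 2) are removed entirely.
#'
#' @param channel_features data frame with columns `well`, `channel`, `mtp`,
#'   `spike_rate` (one row per channel and measurement time point).
#' @param rate_threshold spikes/min; strictly-below is inactive.
#' @param min_active_channels minimum active channels for a well to be kept.
#' @return list with `table` (input rows of retained wells plus a logical
#'   `active` column) and `exclusions` (data frame of dropped wells and
#'   inactive channels).
#' @export
filter_inactive <- function(channel_features, rate_threshold = 20,
                            min_active_channels = 2L) {
  stopifnot(all(c("well", "channel", "mtp", "spike_rate") %in%
                  names(channel_features)))
  key <- interaction(channel_features$well, channel_features$channel,
                     drop = TRUE)
  last_rate <- vapply(split(channel_features, key), function(d) {
    d$spike_rate[which.max(d$mtp)]
  }, numeric(1))
  active_key <- names(last_rate)[last_rate >= rate_threshold]
  channel_features$active <- as.character(key) %in% active_key

  # count distinct active channels per well
  act <- unique(channel_features[channel_features$active,
                                 c("well", "channel")])
  n_active <- table(factor(act$well, levels = unique(channel_features$well)))
  bad_wells <- names(n_active)[n_active < min_active_channels]

  exclusions <- rbind(
    data.frame(kind = "inactive_channel",
               well = channel_features$well[!channel_features$active &
                                              !duplicated(key)],
               channel = channel_features$channel[!channel_features$active &
                                                    !duplicated(key)]),
    data.frame(kind = "excluded_well", well = bad_wells,
               channel = NA_character_)
  )
  keep <- !(channel_features$well %in% bad_wells)
  list(table = channel_features[keep, , drop = FALSE],
       exclusions = exclusions)
}

#' Activity class of a well
#'
#' Wells are grouped by their mean spike rate at measurement time point 5:
#' low (< 50 spikes/min), medium (50 to 250, both ends included), high
#' (> 250).  Only medium-activity wells enter the reference table.
#'
#' @param mean_spike_rate spikes/min, >= 0.  Vectorised.
#' @return character vector: `"low"`, `"medium"` or `"high"`.
#' @export
classify_activity <- function(mean_spike_rate) {
  if (any(mean_spike_rate < 0)) stop("spike rate must be >= 0", call. = FALSE)
  ifelse(mean_spike_rate < 50, "low",
         ifelse(mean_spike_rate <= 250, "medium", "high"))
}

#' Embedded reference table of feature quartiles
#'
#' Q1/median/Q3 of the four features (SR spikes/min, BR bursts/min, BD s,
#' SB count) at measurement time points 1-6, for the medium-activity
#' experimental recordings (`source = "MEA"`) and the published simulation
#' (`source = "INEX"`).
#'
#' @param source `"MEA"` (default), `"INEX"`, or `"both"`.
#' @return data frame with columns `mtp`, `source`, `feature`, `q1`, `m`,
#'   `q3`.
#' @export
reference_table <- function(source = c("MEA", "INEX", "both")) {
  source <- match.arg(source)
  path <- system.file("extdata", "mea_inex_reference.tsv",
                      package = "inexsim", mustWork = TRUE)
  tab <- read.delim(path, stringsAsFactors = FALSE)
  if (source != "both") tab <- tab[tab$source == source, , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Published per-time-point parameter bounds and connectivity schedule
#'
#' The connection probability and the (c, y+, y-) upper bounds selected by
#' the parameter-space search for each measurement time point.
#'
#' @return data frame with columns `mtp`, `connection_probability`,
#'   `c_upper`, `y_exc_upper`, `y_inh_upper`.
#' @export
reference_bounds <- function() {
  path <- system.file("extdata", "inex_parameter_bounds.tsv",
                      package = "inexsim", mustWork = TRUE)
  read.delim(path, stringsAsFactors = FALSE)
}

#' Compare simulated quartile summaries to a reference
#'
#' For each time point and feature, checks whether the simulated median lies
#' within the closed reference interquartile interval `[Q1, Q3]` and reports
#' the signed deviation of medians, normalised by the reference median
#' (absolute deviation when the reference median is zero).
#'
#' @param sim data frame with columns `mtp`, `feature`, `q1`, `m`, `q3`
#'   (simulated summaries).
#' @param ref reference in the same layout, e.g. [reference_table()].
#' @return data frame with one row per reference (mtp, feature): simulated
#'   and reference quartiles, `inside` (logical, `NA` when the time point is
#'   missing from `sim`) and `deviation`.
#' @export
compare_to_reference <- function(sim, ref = reference_table("MEA")) {
  stopifnot(all(c("mtp", "feature", "m") %in% names(sim)))
  out <- lapply(seq_len(nrow(ref)), function(r) {
    rr <- ref[r, ]
    sr <- sim[sim$mtp == rr$mtp & sim$feature == rr$feature, , drop = FALSE]
    if (nrow(sr) == 0 || !is.finite(sr$m[1])) {
      data.frame(mtp = rr$mtp, feature = rr$feature, sim_m = NA_real_,
                 ref_q1 = rr$q1, ref_m = rr$m, ref_q3 = rr$q3,
                 inside = NA, deviation = NA_real_)
    } else {
      m <- sr$m[1]
      dev <- if (rr$m == 0) m - rr$m else (m - rr$m) / rr$m
      data.frame(mtp = rr$mtp, feature = rr$feature, sim_m = m,
                 ref_q1 = rr$q1, ref_m = rr$m, ref_q3 = rr$q3,
                 inside = m >= rr$q1 & m <= rr$q3, deviation = dev)
    }
  })
  do.call(rbind, out)
}
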