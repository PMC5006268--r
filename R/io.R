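#' Write / read spike trains as CSV
#'
#' Plain CSV with header `unit_id,spike_time_s`, times in seconds with six
#' decimal places, units numbered from 0, rows sorted by unit then time.  A
#' JSON sidecar (`<path>.json`) stores the unit count, duration and
#' provenance so that empty units survive a round trip.
#'
#' @param x a `spike_train_set`.
#' @param path CSV file path.
#' @return `write_spike_trains()` returns `path` invisibly;
#'   `read_spike_trains()` returns the `spike_train_set`.
#' @export
write_spike_trains <- function(x, path) {
  stopifnot(inherits(x, "spike_train_set"))
  df <- data.frame(
    unit_id = rep(seq_along(x$trains) - 1L, lengths(x$trains)),
    spike_time_s = sprintf("%.6f", unlist(x$trains, use.names = FALSE)))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(n_units = x$n_units, duration_s = x$duration_s,
                            provenance = x$provenance),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @param duration_s recording duration; required when no sidecar is found.
#' @param n_units unit count override when no sidecar is found (default:
#'   `max(unit_id) + 1`).
#' @rdname write_spike_trains
#' @export
read_spike_trains <- function(path, duration_s = NULL, n_units = NULL) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!identical(names(df), c("unit_id", "spike_time_s")))
    stop("expected CSV header `unit_id,spike_time_s`", call. = FALSE)
  uid <- suppressWarnings(as.integer(df$unit_id))
  tt <- suppressWarnings(as.numeric(df$spike_time_s))
  bad <- which(is.na(uid) | is.na(tt) | uid < 0)
  if (length(bad))
    stop(sprintf("malformed row at line %d of %s", bad[1] + 1L, path),
         call. = FALSE)
  neg <- which(tt < 0)
  if (length(neg))
    stop(sprintf("negative spike time at line %d of %s", neg[1] + 1L, path),
         call. = FALSE)
  sidecar <- paste0(path, ".json")
  prov <- list()
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (is.null(duration_s)) duration_s <- meta$duration_s
    if (is.null(n_units)) n_units <- meta$n_units
    prov <- as.list(meta$provenance)
  }
  if (is.null(n_units)) n_units <- if (length(uid)) max(uid) + 1L else 0L
  if (is.null(duration_s))
    stop("`duration_s` required when no sidecar metadata is present",
         call. = FALSE)
  trains <- lapply(seq_len(n_units) - 1L, function(u) sort(tt[uid == u]))
  spike_train_set(trains, duration_s, provenance = prov)
}

#' Write / read a configuration document
#'
#' JSON mirror of the simulation and network-spec fields.  Unknown keys are
#' rejected on read so that typos do not silently fall back to defaults.
#'
#' @param config named list of configuration values.
#' @param path file path.
#' @return `read_config()` returns the named list; `write_config()` returns
#'   `path` invisibly.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  known <- c("duration_s", "dt", "history_factor", "time_unit_convention",
             "seed", "n_neurons", "inhibitory_fraction",
             "connection_probability", "triangular_mode_fraction",
             "c_upper", "y_exc_upper", "y_inh_upper",
             "connection_probabilities", "runs_per_vmtp", "n_units")
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  unknown <- setdiff(names(doc), known)
  if (length(unknown))
    stop(sprintf("unknown configuration key(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  doc
}

#' Write per-unit features as TSV
#'
#' Layout: `unit_id  spike_rate  burst_rate  burst_duration_s
#' spikes_per_burst  n_bursts`, absent features written as `NA`.
#'
#' @param features data frame from [analyze_spike_trains()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_features <- function(features, path) {
  utils::write.table(features, path, sep = "\t", row.names = FALSE,
                     quote = FALSE, na = "NA")
  invisible(path)
}

#' Write a maturation report to a directory
#'
#' Emits `summaries.tsv` (quartiles per time point and feature),
#' `report.tsv` (comparison against the reference) and `provenance.json`.
#'
#' @param x a `maturation_result`.
#' @param dir output directory, created if missing.
#' @return `dir`, invisibly.
#' @export
write_maturation_report <- function(x, dir) {
  stopifnot(inherits(x, "maturation_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(x$summaries, file.path(dir, "summaries.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(x$report, file.path(dir, "report.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(x$provenance, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
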