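#' Spike-train, conductance-trace and weight-list CSV interchange
#'
#' Plain-text exchange formats:
#' * spike trains — two columns `unit_id, time_s`, times in seconds to 6
#'   decimal places;
#' * conductance traces — two columns `time_ms, conductance_nS` (the
#'   dynamic-clamp waveform format);
#' * weight lists — one column `amplitude_nS`.
#'
#' Round-tripping a trace or train through export/import reproduces it to
#' the written precision. Malformed or unsorted input is rejected with the
#' offending line number.
#'
#' @param trains a [spike_train()] or list of them.
#' @param path file path.
#' @return Readers return the parsed object(s); writers return `path`
#'   invisibly.
#' @export
write_spike_csv <- function(trains, path) {
  if (inherits(trains, "spike_train")) trains <- list(trains)
  df <- do.call(rbind, lapply(trains, function(tr)
    if (length(tr$times))
      data.frame(unit_id = tr$unit_id, time_s = sprintf("%.6f", tr$times))
    else NULL))
  if (is.null(df)) df <- data.frame(unit_id = character(0),
                                    time_s = character(0))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_spike_csv
#' @param duration train duration in seconds; defaults to just past the
#'   last event.
#' @export
read_spike_csv <- function(path, duration = NULL) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("unit_id", "time_s") %in% names(df)))
    stopf("%s: expected columns unit_id, time_s", path)
  tvals <- suppressWarnings(as.numeric(df$time_s))
  bad <- which(!is.finite(tvals) | tvals < 0)
  if (length(bad))
    stopf("%s: invalid spike time on line %d", path, bad[1] + 1L)
  duration <- duration %||% (max(tvals, 0) + 1e-6)
  units <- unique(df$unit_id)
  out <- vector("list", length(units))
  names(out) <- units
  for (u in units) {
    rows <- which(df$unit_id == u)
    tu <- tvals[rows]
    nd <- which(diff(tu) <= 0)
    if (length(nd))
      stopf("%s: spike times for unit '%s' not strictly increasing on line %d",
            path, u, rows[nd[1] + 1L] + 1L)
    out[[u]] <- spike_train(tu, duration, u)
  }
  out
}

#' @rdname write_spike_csv
#' @param trace a [conductance_trace()].
#' @export
write_trace_csv <- function(trace, path) {
  stopifnot(inherits(trace, "conductance_trace"))
  n <- length(trace$values)
  df <- data.frame(
    time_ms = sprintf("%.6f", trace$t0 + (seq_len(n) - 1L) * trace$dt),
    conductance_nS = sprintf("%.6f", trace$values))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_spike_csv
#' @export
read_trace_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("time_ms", "conductance_nS") %in% names(df)))
    stopf("%s: expected columns time_ms, conductance_nS", path)
  tv <- suppressWarnings(as.numeric(df$time_ms))
  gv <- suppressWarnings(as.numeric(df$conductance_nS))
  bad <- which(!is.finite(tv) | !is.finite(gv))
  if (length(bad)) stopf("%s: malformed row on line %d", path, bad[1] + 1L)
  if (length(tv) < 2L) stopf("%s: need at least two samples", path)
  steps <- diff(tv)
  if (any(abs(steps - steps[1]) > 1e-6))
    stopf("%s: sample grid not uniform near line %d", path,
          which(abs(steps - steps[1]) > 1e-6)[1] + 2L)
  conductance_trace(gv, dt = steps[1], t0 = tv[1])
}

#' @rdname write_spike_csv
#' @param weights numeric amplitudes in nS.
#' @export
write_weights_csv <- function(weights, path) {
  write.csv(data.frame(amplitude_nS = weights), path, row.names = FALSE,
            quote = FALSE)
  invisible(path)
}

#' @rdname write_spike_csv
#' @export
read_weights_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!"amplitude_nS" %in% names(df))
    stopf("%s: expected column amplitude_nS", path)
  w <- suppressWarnings(as.numeric(df$amplitude_nS))
  bad <- which(!is.finite(w) | w < 0)
  if (length(bad)) stopf("%s: invalid amplitude on line %d", path, bad[1] + 1L)
  w
}
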