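spike_times_of <- function(x) {
  if (inherits(x, "sim_result")) x$spikes$times
  else if (inherits(x, "spike_train")) x$times
  else if (is.numeric(x)) as.numeric(x)
  else stopf("expected a spike_train, sim_result or numeric times")
}

#' Spike cross- and auto-correlograms
#'
#' For every spike of the reference train, spikes of the target train
#' within a +/-`window` ms lag are accumulated into a lag histogram; counts
#' are divided by the number of reference spikes and the bin width, giving
#' conditional target rate in spikes/s. For an autocorrelogram (reference
#' and target identical) the zero-lag self-pairs are excluded.
#'
#' Reference inputs may be a [spike_train()], a `sim_result`, or a plain
#' sorted numeric vector of times in seconds (e.g. several inputs' spikes
#' pooled into one reference set).
#'
#' @param ref reference spike times (must be nonempty).
#' @param target target spike times.
#' @param bin_width histogram bin width in ms; must divide the window
#'   evenly.
#' @param window half-window in ms (lags span `-window` to `+window`).
#' @param exclude_self drop zero-lag self pairs; defaults to `TRUE` when
#'   reference and target times are identical.
#' @return An object of class `correlogram`: `lags` (bin centers, ms),
#'   `values` (spikes/s, or dimensionless once normalized), `bin_width`,
#'   `n_ref`, `normalized`.
#' @examples
#' set.seed(1)
#' a <- generate_poisson_train(50, 20)
#' b <- generate_poisson_train(50, 20)
#' mean(correlogram(a, b)$values)   # ~50 spikes/s, flat
#' @export
correlogram <- function(ref, target, bin_width = 0.1, window = 10,
                        exclude_self = NULL) {
  rt <- spike_times_of(ref)
  tt <- spike_times_of(target)
  if (!length(rt)) stopf("reference train is empty; normalization undefined")
  nb <- 2 * window / bin_width
  if (abs(nb - round(nb)) > 1e-9)
    stopf("bin_width must divide the %g ms window evenly", 2 * window)
  if (is.null(exclude_self))
    exclude_self <- length(rt) == length(tt) && isTRUE(all(rt == tt))
  counts <- corr_counts_cpp(rt, tt, window / 1000, bin_width / 1000,
                            exclude_self)
  nbins <- as.integer(round(nb))
  structure(list(
    lags = -window + (seq_len(nbins) - 0.5) * bin_width,
    values = counts / (length(rt) * bin_width / 1000),
    bin_width = bin_width, n_ref = length(rt), normalized = FALSE
  ), class = "correlogram")
}

#' @rdname correlogram
#' @param train spike train for the autocorrelogram.
#' @export
autocorrelogram <- function(train, bin_width = 0.1, window = 10) {
  correlogram(train, train, bin_width, window, exclude_self = TRUE)
}

#' @export
print.correlogram <- function(x, ...) {
  cat(sprintf("Correlogram: %d bins of %g ms, n_ref = %d%s\n",
              length(x$lags), x$bin_width, x$n_ref,
              if (x$normalized) " (normalized)" else ""))
  invisible(x)
}

#' Normalize a correlogram by the baseline firing rate
#'
#' Divides the raw conditional rate by the target's mean rate over the
#' analysis window, so independent trains hover at 1 away from lag zero.
#'
#' @param x a raw [correlogram()].
#' @param baseline_rate mean target firing rate in spikes/s (> 0).
#' @return The correlogram with dimensionless values and `normalized = TRUE`.
#' @export
normalize_correlogram <- function(x, baseline_rate) {
  stopifnot(inherits(x, "correlogram"))
  if (!is.numeric(baseline_rate) || baseline_rate <= 0)
    stopf("baseline_rate must be positive")
  x$values <- x$values / baseline_rate
  x$normalized <- TRUE
  x$baseline_rate <- baseline_rate
  x
}

#' Spike-triggered average of a conductance trace
#'
#' Averages trace segments centered on each trigger spike. Triggers whose
#' window would extend beyond the trace are dropped; at least 90% of the
#' triggers must survive.
#'
#' @param trigger trigger spike times (nonempty).
#' @param trace a [conductance_trace()].
#' @param window half-window in ms.
#' @return An object of class `sta`: `lags` (ms), `values` (nS), `n_used`.
#' @export
spike_triggered_average <- function(trigger, trace, window = 10) {
  tt <- spike_times_of(trigger)
  if (!length(tt)) stopf("trigger train is empty")
  stopifnot(inherits(trace, "conductance_trace"))
  half <- as.integer(round(window / trace$dt))
  idx <- as.integer(round(tt * 1000 / trace$dt))
  res <- sta_cpp(idx, trace$values, half)
  if (res$n_used < 0.9 * length(tt))
    stopf("only %d of %d triggers fit inside the trace (need >= 90%%)",
          res$n_used, length(tt))
  structure(list(lags = seq(-half, half) * trace$dt,
                 values = res$sum / res$n_used, n_used = res$n_used),
            class = "sta")
}

#' Excitation, inhibition and half-decay of a normalized correlogram
#'
#' Summarizes the stereotyped input-output cross-correlogram of an
#' inhibitory input: a brief excess of output spikes just before the input
#' fires (disinhibition, `e`), a suppression trough just after (`i`), and
#' the time for the suppression to recover halfway back to baseline
#' (`t_half`).
#'
#' * `e` = max(value - 1) over lags in `e_window` (default \[-4, 0\] ms),
#'   floored at 0.
#' * `i` = 1 - min(value) over lags in `i_window` (default \[0, +6\] ms),
#'   clamped to \[0, 1\].
#' * `t_half` = first lag at or after the trough where the value recovers
#'   to `1 - i/2`, minus the trough lag. The trough lag is the last lag
#'   attaining the window minimum, so for a flat silenced period the
#'   half-decay clock starts when suppression begins to release.
#'
#' The correlogram must be normalized with a credible baseline: the mean
#' value over `baseline_window` must lie within `1 +/- baseline_tol`.
#'
#' @param nc a [normalize_correlogram()] output.
#' @param e_window,i_window lag windows in ms for the excess and trough.
#' @param baseline_window lag window used for the baseline sanity check.
#' @param baseline_tol allowed deviation of the baseline from 1.
#' @return List with `e`, `i` (dimensionless) and `t_half` (ms; `NA` if the
#'   trough never recovers halfway within the correlogram window).
#' @examples
#' flat <- structure(list(lags = seq(-9.95, 9.95, 0.1),
#'                        values = rep(1, 200), bin_width = 0.1,
#'                        n_ref = 1000L, normalized = TRUE),
#'                   class = "correlogram")
#' extract_eit(flat)   # e = 0, i = 0, t_half = 0
#' @export
extract_eit <- function(nc, e_window = c(-4, 0), i_window = c(0, 6),
                        baseline_window = c(-10, -8), baseline_tol = 0.1) {
  stopifnot(inherits(nc, "correlogram"))
  if (!isTRUE(nc$normalized))
    stopf("extract_eit needs a normalized correlogram")
  base <- nc$values[nc$lags >= baseline_window[1] & nc$lags <= baseline_window[2]]
  if (!length(base) || abs(mean(base) - 1) > baseline_tol)
    stopf("baseline over [%g, %g] ms is %.3f, outside 1 +/- %.2f",
          baseline_window[1], baseline_window[2],
          if (length(base)) mean(base) else NA_real_, baseline_tol)
  in_e <- nc$lags >= e_window[1] & nc$lags <= e_window[2]
  in_i <- nc$lags >= i_window[1] & nc$lags <= i_window[2]
  if (!any(in_e) || !any(in_i)) stopf("metric windows contain no bins")
  e <- max(0, max(nc$values[in_e]) - 1)
  vmin <- min(nc$values[in_i])
  i <- min(1, max(0, 1 - vmin))
  if (i == 0) return(list(e = e, i = 0, t_half = 0))
  trough_lag <- max(nc$lags[in_i][nc$values[in_i] == vmin])
  after <- nc$lags >= trough_lag
  rec <- after & nc$values >= 1 - i / 2
  t_half <- if (any(rec)) min(nc$lags[rec]) - trough_lag else NA_real_
  list(e = e, i = i, t_half = t_half)
}

#' Mean firing rate after a burn-in
#'
#' Spike count after the burn-in divided by the remaining duration. The
#' burn-in discards the transient from the arbitrary initial condition.
#'
#' @param x a `sim_result` or [spike_train()].
#' @param burn_in initial period to discard, in seconds.
#' @return Rate in spikes/s.
#' @export
firing_rate <- function(x, burn_in = 1) {
  tr <- if (inherits(x, "sim_result")) x$spikes else x
  stopifnot(inherits(tr, "spike_train"))
  if (tr$duration <= burn_in)
    stopf("duration (%.4g s) must exceed the burn-in (%.4g s)",
          tr$duration, burn_in)
  sum(tr$times >= burn_in) / (tr$duration - burn_in)
}

#' Interspike-interval statistics
#'
#' Sample mean, sd, coefficient of variation and histogram of the ISIs of a
#' spike train.
#'
#' @param train a [spike_train()] (or `sim_result`) with at least 2 spikes.
#' @param bin_width histogram bin width in ms.
#' @return List with `mean` (s), `sd` (s), `cv`, and `histogram`
#'   (data.frame of bin midpoints in ms and counts).
#' @export
isi_stats <- function(train, bin_width = 0.5) {
  tt <- spike_times_of(train)
  if (length(tt) < 2L) stopf("need at least 2 spikes for ISI statistics")
  isis <- diff(tt)
  m <- mean(isis)
  s <- if (length(isis) > 1L) sd(isis) else 0
  isis_ms <- isis * 1000
  breaks <- seq(0, max(isis_ms) + bin_width, by = bin_width)
  h <- hist(isis_ms, breaks = breaks, plot = FALSE)
  list(mean = m, sd = s, cv = s / m,
       histogram = data.frame(mid = h$mids, count = h$counts))
}
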