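#' Unitary synaptic conductance kernels
#'
#' A unitary synaptic event is modelled as a peak-normalized difference of
#' exponentials, `k(t) = A * (exp(-t/tau_decay) - exp(-t/tau_rise)) / N`
#' for `t >= 0`, where `N` is the bracket's maximum so the waveform peaks
#' at exactly `A`. The closed-form peak time is
#' `t* = tau_rise*tau_decay/(tau_decay - tau_rise) * log(tau_decay/tau_rise)`
#' and the time integral is `A*(tau_decay - tau_rise)/N`.
#'
#' `ipsg_kernel()` is the inhibitory Purkinje-cell unitary conductance
#' (rise 0.1 ms, decay 2.5 ms, reversal -75 mV); `epsg_kernel()` is the
#' mossy-fiber AMPA excitatory unitary conductance (0.4 nS, rise 0.28 ms,
#' decay 1.06 ms, reversal 0 mV).
#'
#' @param amplitude peak conductance A in nS (`>= 0`).
#' @param tau_rise,tau_decay exponential time constants in ms,
#'   `0 < tau_rise < tau_decay`.
#' @param reversal synaptic reversal potential in mV.
#' @return An object of class `unitary_kernel` with the parameters plus the
#'   derived `norm` (N), `peak_time` (ms) and `integral` (nS*ms).
#' @examples
#' k <- ipsg_kernel(1)
#' c(k$peak_time, k$integral)   # 0.33530 ms, 2.85885 nS*ms
#' @export
make_kernel <- function(amplitude, tau_rise, tau_decay, reversal) {
  if (!is.numeric(amplitude) || amplitude < 0)
    stopf("amplitude must be >= 0 nS")
  if (!(tau_rise > 0 && tau_decay > tau_rise))
    stopf("need 0 < tau_rise < tau_decay (got %.4g, %.4g ms)",
          tau_rise, tau_decay)
  tpeak <- tau_rise * tau_decay / (tau_decay - tau_rise) *
    log(tau_decay / tau_rise)
  norm <- exp(-tpeak / tau_decay) - exp(-tpeak / tau_rise)
  structure(list(
    amplitude = amplitude, tau_rise = tau_rise, tau_decay = tau_decay,
    reversal = reversal, norm = norm, peak_time = tpeak,
    integral = amplitude * (tau_decay - tau_rise) / norm
  ), class = "unitary_kernel")
}

#' @rdname make_kernel
#' @export
ipsg_kernel <- function(amplitude = 1) {
  make_kernel(amplitude, tau_rise = 0.1, tau_decay = 2.5, reversal = -75)
}

#' @rdname make_kernel
#' @export
epsg_kernel <- function(amplitude = 0.4) {
  make_kernel(amplitude, tau_rise = 0.28, tau_decay = 1.06, reversal = 0)
}

#' @rdname make_kernel
#' @param kernel a `unitary_kernel`.
#' @param t times in ms at which to evaluate the waveform.
#' @export
kernel_eval <- function(kernel, t) {
  ifelse(t < 0, 0, kernel$amplitude *
           (exp(-t / kernel$tau_decay) - exp(-t / kernel$tau_rise)) /
           kernel$norm)
}

#' @export
print.unitary_kernel <- function(x, ...) {
  cat(sprintf(
    "Unitary kernel: %.4g nS, rise %.3g ms, decay %.3g ms, reversal %g mV\n",
    x$amplitude, x$tau_rise, x$tau_decay, x$reversal))
  invisible(x)
}

#' Uniformly sampled conductance traces
#'
#' A `conductance_trace` holds nonnegative conductance samples (nS) on a
#' uniform grid of step `dt` milliseconds starting at `t0` ms.
#'
#' @param values conductance samples in nS.
#' @param dt sample step in ms.
#' @param t0 time of the first sample in ms.
#' @return An object of class `conductance_trace`.
#' @export
conductance_trace <- function(values, dt, t0 = 0) {
  if (!is.numeric(dt) || dt <= 0) stopf("dt must be positive (ms)")
  structure(list(values = as.numeric(values), dt = dt, t0 = t0),
            class = "conductance_trace")
}

#' @export
print.conductance_trace <- function(x, ...) {
  cat(sprintf("Conductance trace: %d samples at dt = %g ms (%.6g s)",
              length(x$values), x$dt, length(x$values) * x$dt / 1000))
  if (length(x$values))
    cat(sprintf(", mean %.4g nS", mean(x$values)))
  cat("\n")
  invisible(x)
}

n_samples_for <- function(duration_s, dt_ms) {
  as.integer(round(duration_s * 1000 / dt_ms))
}

check_dt <- function(dt, kernel) {
  if (dt > kernel$tau_rise / 2)
    stopf("dt = %g ms is too coarse to resolve the %g ms rise; need dt <= %g ms",
          dt, kernel$tau_rise, kernel$tau_rise / 2)
}

# Shared filtering core: weighted impulses -> sampled conductance.
# Exact grid evaluation of the biexponential kernel via two one-pole
# recursions; state can be carried across chunks.
filter_impulses <- function(impulses, dt, kernel, state = NULL) {
  biexp_filter_cpp(
    impulses,
    a_decay = exp(-dt / kernel$tau_decay),
    a_rise = exp(-dt / kernel$tau_rise),
    scale = kernel$amplitude / kernel$norm,
    y_decay0 = state$y_decay %||% 0,
    y_rise0 = state$y_rise %||% 0
  )
}

#' Convolve a spike train with a unitary kernel
#'
#' Linear superposition of one kernel waveform per spike, evaluated exactly
#' on the sample grid by recursive filtering (no tail truncation). Spike
#' times are quantized to the grid (bias under `dt/2`).
#'
#' @param train a [spike_train()].
#' @param kernel a [make_kernel()] waveform.
#' @param dt sample step in ms; must satisfy `dt <= tau_rise/2` to resolve
#'   the rising phase.
#' @param duration trace duration in seconds (defaults to the train's).
#' @return A [conductance_trace()].
#' @examples
#' tr <- spike_train(0, duration = 0.05)
#' g <- convolve_train(tr, ipsg_kernel(1), dt = 0.02)
#' max(g$values)   # ~1 nS, at ~0.335 ms
#' @export
convolve_train <- function(train, kernel, dt = 0.02, duration = train$duration) {
  stopifnot(inherits(train, "spike_train"), inherits(kernel, "unitary_kernel"))
  check_dt(dt, kernel)
  n <- n_samples_for(duration, dt)
  imp <- bin_events_cpp(train$times, 1.0, 0, dt / 1000, n)
  conductance_trace(filter_impulses(imp, dt, kernel)$values, dt)
}

#' Synaptic input-size distributions
#'
#' Describes how unitary inhibitory amplitudes (nS) are drawn when building
#' a convergent input set.
#'
#' * `size_triplet()` — the simplified fixed set: 16 small (3 nS), 10
#'   medium (10 nS) and 2 large (30 nS) inputs, nominal total 200 nS
#'   (exact sum 208 nS).
#' * `size_uniform(size)` — all inputs share one amplitude.
#' * `size_categorical(values, probs)` — i.i.d. categorical draws; the
#'   default reduces the corrected empirical input-size distribution to the
#'   same three amplitudes and proportions as the triplet.
#' * `size_empirical()` — a synthetic continuous surrogate for the
#'   corrected empirical distribution: truncated lognormal amplitudes
#'   calibrated so the small/medium/large class probabilities match the
#'   triplet's 16:10:2 proportions (see the source for the closed-form
#'   calibration); an alternative to the categorical surrogate when a
#'   continuous size spectrum matters.
#' * `size_pool(sizes)` — i.i.d. draws from a user-supplied amplitude list.
#'
#' @param size,values,probs,sizes amplitudes in nS and draw probabilities.
#' @return An object of class `size_distribution`.
#' @export
size_triplet <- function() {
  structure(list(kind = "simplified_triplet",
                 sizes = c(rep(3, 16), rep(10, 10), rep(30, 2))),
            class = "size_distribution")
}

#' @rdname size_triplet
#' @export
size_uniform <- function(size) {
  if (size <= 0) stopf("size must be positive (nS)")
  structure(list(kind = "uniform", sizes = size), class = "size_distribution")
}

#' @rdname size_triplet
#' @export
size_categorical <- function(values = c(3, 10, 30),
                             probs = c(16, 10, 2) / 28) {
  if (length(values) != length(probs) || any(values <= 0) || any(probs < 0))
    stopf("values must be positive and match probs in length")
  if (abs(sum(probs) - 1) > 1e-9) stopf("probs must sum to 1")
  structure(list(kind = "categorical_empirical", sizes = values, probs = probs),
            class = "size_distribution")
}

#' @rdname size_triplet
#' @param meanlog,sdlog,lower,upper truncated-lognormal parameters of the
#'   synthetic empirical surrogate (nS scale).
#' @export
size_empirical <- function(meanlog = 1.6231, sdlog = 0.9368, lower = 1,
                           upper = 45) {
  # Synthetic surrogate for the corrected empirical input-size
  # distribution, which is continuous and strongly right-skewed (the
  # largest corrected inputs approach ~40 nS). Skewed synaptic weight
  # distributions are conventionally modelled as lognormal; the defaults
  # are calibrated so the small (<6 nS) / medium (6-20 nS) / large
  # (>20 nS) class probabilities match the 16:10:2 proportions of the
  # simplified triplet: P(<6) = 16/28 and P(>20) = 2/28 give
  # sdlog = log(20/6)/(qnorm(26/28) - qnorm(16/28)) and
  # meanlog = log(6) - qnorm(16/28)*sdlog. Draws outside [lower, upper]
  # are rejected.
  if (!(lower > 0 && upper > lower)) stopf("need 0 < lower < upper")
  structure(list(kind = "lognormal_surrogate", meanlog = meanlog,
                 sdlog = sdlog, lower = lower, upper = upper,
                 sizes = lower),  # minimum attainable size
            class = "size_distribution")
}

#' @rdname size_triplet
#' @export
size_pool <- function(sizes) {
  if (!length(sizes) || any(sizes <= 0)) stopf("sizes must be positive (nS)")
  structure(list(kind = "user_list", sizes = as.numeric(sizes)),
            class = "size_distribution")
}

#' Draw unitary amplitudes to a target total conductance
#'
#' Amplitudes are drawn i.i.d. from the distribution until their cumulative
#' sum reaches `total_target`; a draw whose final total deviates from the
#' target by more than 5% is rejected and restarted. The fixed triplet set
#' is returned as-is. Draws use the current R random stream.
#'
#' @param dist a [size_triplet()]-style distribution.
#' @param total_target target summed amplitude in nS.
#' @param tol relative overshoot tolerance before restarting (default 0.05).
#' @param max_tries restart budget before giving up.
#' @return Numeric vector of amplitudes (nS), in draw order.
#' @examples
#' sample_sizes(size_uniform(5), 200)   # exactly 40 x 5 nS
#' @export
sample_sizes <- function(dist, total_target, tol = 0.05, max_tries = 10000L) {
  stopifnot(inherits(dist, "size_distribution"))
  if (total_target <= 0) stopf("total_target must be positive (nS)")
  if (dist$kind == "simplified_triplet") return(dist$sizes)
  if (min(dist$sizes) > total_target)
    stopf("smallest available size (%.4g nS) exceeds the %.4g nS target",
          min(dist$sizes), total_target)
  draw_one <- switch(dist$kind,
    uniform = function() dist$sizes,
    categorical_empirical = function()
      sample(dist$sizes, 1L, prob = dist$probs, replace = TRUE),
    user_list = function() sample(dist$sizes, 1L, replace = TRUE),
    lognormal_surrogate = function() {
      repeat {
        s <- rlnorm(1L, dist$meanlog, dist$sdlog)
        if (s >= dist$lower && s <= dist$upper) return(s)
      }
    },
    stopf("unknown size distribution kind '%s'", dist$kind))
  for (try in seq_len(max_tries)) {
    sizes <- numeric(0)
    total <- 0
    while (total < total_target) {
      s <- draw_one()
      sizes <- c(sizes, s)
      total <- total + s
    }
    if (abs(total - total_target) <= tol * total_target) return(sizes)
  }
  stopf("could not reach %.4g nS within %.0f%% in %d attempts",
        total_target, 100 * tol, max_tries)
}

#' Correct raw amplitudes for depression and recording conditions
#'
#' Voltage-clamp amplitudes measured with a high-chloride internal solution
#' overestimate the physiological unitary conductance; amplitudes are
#' multiplied by a synaptic depression factor (default 0.4) and divided by
#' a chloride correction factor (default 2.3).
#'
#' @param raw raw amplitudes in nS.
#' @param depression_factor multiplicative depression scaling (> 0).
#' @param chloride_factor divisive recording correction (> 0).
#' @return Corrected amplitudes in nS.
#' @examples
#' correct_amplitudes(172.5)   # 30 nS
#' @export
correct_amplitudes <- function(raw, depression_factor = 0.4,
                               chloride_factor = 2.3) {
  if (depression_factor <= 0 || chloride_factor <= 0)
    stopf("correction factors must be positive")
  raw * depression_factor / chloride_factor
}

#' Assemble the total inhibitory conductance from weighted spike trains
#'
#' Each input's spike train is convolved with the unit-amplitude inhibitory
#' kernel scaled by its weight, and contributions are summed. The total is
#' computed from amplitude-weighted impulses in a single filter pass, so
#' additivity is exact to rounding.
#'
#' @param weights unitary amplitudes in nS, one per train.
#' @param trains list of [spike_train()] objects matching `weights`.
#' @param dt sample step in ms.
#' @param duration trace duration in seconds (defaults to the trains').
#' @param kernel kernel shape; its amplitude is ignored (weights set the
#'   per-input peaks).
#' @param per_input if `TRUE`, also return each input's own trace.
#' @return A [conductance_trace()]; with `per_input = TRUE`, a list with
#'   elements `total` and `per_input`.
#' @export
assemble_inhibition <- function(weights, trains, dt = 0.02,
                                duration = NULL, kernel = ipsg_kernel(1),
                                per_input = FALSE) {
  if (length(weights) != length(trains))
    stopf("need one spike train per weight (%d weights, %d trains)",
          length(weights), length(trains))
  check_dt(dt, kernel)
  duration <- duration %||% if (length(trains)) trains[[1]]$duration else 0
  n <- n_samples_for(duration, dt)
  unit <- make_kernel(1, kernel$tau_rise, kernel$tau_decay, kernel$reversal)
  imp <- numeric(n)
  for (i in seq_along(trains)) {
    tt <- trains[[i]]$times
    imp <- imp + bin_events_cpp(tt, weights[i], 0, dt / 1000, n)
  }
  total <- conductance_trace(filter_impulses(imp, dt, unit)$values, dt)
  if (!per_input) return(total)
  per <- lapply(seq_along(trains), function(i) {
    ki <- make_kernel(weights[i], kernel$tau_rise, kernel$tau_decay,
                      kernel$reversal)
    convolve_train(trains[[i]], ki, dt, duration)
  })
  list(total = total, per_input = per)
}

#' Generate the excitatory conductance from a Poisson event stream
#'
#' A homogeneous Poisson stream of unitary excitatory events is convolved
#' with the excitatory kernel. Event counts are drawn per sample bin
#' (Poisson with mean `rate * dt`), which is the grid-quantized equivalent
#' of drawing and binning individual event times.
#'
#' @param event_rate events per second (`>= 0`).
#' @param duration trace duration in seconds.
#' @param dt sample step in ms.
#' @param kernel unitary excitatory kernel (default [epsg_kernel()]).
#' @return A [conductance_trace()].
#' @export
generate_excitation <- function(event_rate, duration, dt = 0.02,
                                kernel = epsg_kernel()) {
  if (!is.numeric(event_rate) || length(event_rate) != 1L || event_rate < 0)
    stopf("event_rate must be a single nonnegative number")
  check_dt(dt, kernel)
  n <- n_samples_for(duration, dt)
  if (event_rate == 0)
    return(conductance_trace(numeric(n), dt))
  imp <- as.numeric(rpois(n, event_rate * dt / 1000))
  conductance_trace(filter_impulses(imp, dt, kernel)$values, dt)
}

#' Conductance trace summary statistics
#'
#' Sample mean, standard deviation and coefficient of variation (sd/mean)
#' of a conductance trace, after discarding an initial burn-in.
#'
#' @param trace a [conductance_trace()].
#' @param burn_in initial period to discard, in seconds.
#' @return List with `mean` (nS), `sd` (nS) and `cv`.
#' @export
trace_stats <- function(trace, burn_in = 0) {
  stopifnot(inherits(trace, "conductance_trace"))
  skip <- n_samples_for(burn_in, trace$dt)
  v <- trace$values[seq_len(length(trace$values)) > skip]
  if (!length(v)) stopf("no samples left after burn-in")
  m <- mean(v)
  s <- if (length(v) > 1L) sd(v) else 0
  if (m == 0) stopf("cv undefined for a zero-mean trace")
  list(mean = m, sd = s, cv = s / m)
}
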