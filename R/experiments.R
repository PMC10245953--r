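with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  old_kind <- RNGkind()
  on.exit({
    RNGkind(old_kind[1L], old_kind[2L], old_kind[3L])
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, globalenv())
  })
  # kind pinned so draws do not depend on the session's generator state
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  expr
}

window_events <- function(tt, t0, t1) {
  i0 <- findInterval(t0, tt, left.open = TRUE)
  i1 <- findInterval(t1, tt, left.open = TRUE)
  if (i1 > i0) tt[seq.int(i0 + 1L, i1)] else numeric(0)
}

#' Run a full convergent-inhibition experiment
#'
#' Streams the whole pipeline — weighted inhibitory impulses from the input
#' spike trains, Poisson excitatory events, biexponential conductance
#' filtering, and the integrate-and-fire update — through fixed-length
#' chunks, carrying the filter and membrane state across chunk boundaries.
#' This keeps memory flat in the simulated duration, so multi-thousand-
#' second runs are practical; the result is equivalent to building the
#' full-length conductance traces and calling [simulate_neuron()] once.
#'
#' Excitatory event draws use the current R random stream; seed it (the
#' scenario runners reserve a dedicated substream) or supply a
#' pre-generated `exc_train` for exact reproducibility across chunkings.
#'
#' @param neuron a [neuron_params()] object.
#' @param weights unitary inhibitory amplitudes in nS, one per train.
#' @param trains list of input [spike_train()] objects.
#' @param exc_rate excitatory event rate in events/s.
#' @param duration simulated seconds (defaults to the trains' duration).
#' @param dt integration step in ms.
#' @param burn_in seconds discarded from rate and conductance statistics.
#' @param chunk chunk length in seconds.
#' @param exc_train optional explicit excitatory event train (overrides
#'   `exc_rate` draws).
#' @param kernel_i,kernel_e inhibitory / excitatory kernel shapes.
#' @return List with `spikes` (output [spike_train()]), `rate` (spikes/s
#'   after burn-in), `gi_mean`, `gi_sd`, `gi_cv` (total inhibitory
#'   conductance statistics after burn-in), `duration`, `burn_in`, `dt`.
#' @export
run_lif_experiment <- function(neuron, weights, trains, exc_rate,
                               duration = NULL, dt = 0.02, burn_in = 1,
                               chunk = 20, exc_train = NULL,
                               kernel_i = ipsg_kernel(1),
                               kernel_e = epsg_kernel()) {
  stopifnot(inherits(neuron, "neuron_params"))
  if (length(weights) != length(trains))
    stopf("need one spike train per weight")
  duration <- duration %||% if (length(trains)) trains[[1]]$duration else
    stopf("duration is required without input trains")
  if (duration <= burn_in)
    stopf("duration must exceed the burn-in")
  check_dt(dt, kernel_i)
  check_dt(dt, kernel_e)
  unit_i <- make_kernel(1, kernel_i$tau_rise, kernel_i$tau_decay,
                        kernel_i$reversal)
  n_total <- n_samples_for(duration, dt)
  n_chunk <- max(1L, n_samples_for(chunk, dt))
  skip <- n_samples_for(burn_in, dt)
  dt_s <- dt / 1000
  state_i <- state_e <- NULL
  mstate <- NULL
  spikes_ms <- vector("list", 0L)
  s1 <- 0; s2 <- 0; nstat <- 0
  ref_steps <- as.integer(round(neuron$t_ref / dt))
  start <- 0L
  while (start < n_total) {
    n <- min(n_chunk, n_total - start)
    t0 <- start * dt_s
    t1 <- (start + n) * dt_s
    imp <- numeric(n)
    for (i in seq_along(trains)) {
      tt <- window_events(trains[[i]]$times, t0, t1)
      if (length(tt))
        imp <- imp + bin_events_cpp(tt, weights[i], t0, dt_s, n)
    }
    state_i <- filter_impulses(imp, dt, unit_i, state_i)
    gI <- state_i$values
    impE <- if (!is.null(exc_train)) {
      bin_events_cpp(window_events(exc_train$times, t0, t1), 1.0, t0, dt_s, n)
    } else if (exc_rate > 0) {
      as.numeric(rpois(n, exc_rate * dt_s))
    } else numeric(n)
    state_e <- filter_impulses(impE, dt, kernel_e, state_e)
    gE <- state_e$values
    res <- lif_cpp(gE, gI, dt, neuron$Cm, neuron$gL, neuron$VL, neuron$VE,
                   neuron$VI, neuron$theta, neuron$Vr, ref_steps,
                   V0 = mstate$V %||% neuron$Vr,
                   ref_left0 = mstate$ref_left %||% 0L,
                   t0_ms = t0 * 1000, record_v = FALSE)
    mstate <- list(V = res$V, ref_left = res$ref_left)
    if (length(res$spike_ms))
      spikes_ms[[length(spikes_ms) + 1L]] <- res$spike_ms
    if (start + n > skip) {
      keep <- max(skip - start, 0L)
      v <- if (keep > 0L) gI[seq.int(keep + 1L, n)] else gI
      s1 <- s1 + sum(v); s2 <- s2 + sum(v * v); nstat <- nstat + length(v)
    }
    start <- start + n
  }
  times <- unlist(spikes_ms) / 1000
  dur_end <- duration
  if (length(times) && times[length(times)] >= dur_end)
    dur_end <- times[length(times)] + 1e-9
  sp <- spike_train(times, dur_end, "output")
  gmean <- s1 / nstat
  gsd <- sqrt(max((s2 - nstat * gmean^2) / (nstat - 1), 0))
  list(spikes = sp, rate = firing_rate(sp, burn_in),
       gi_mean = gmean, gi_sd = gsd,
       gi_cv = if (gmean > 0) gsd / gmean else NA_real_,
       duration = duration, burn_in = burn_in, dt = dt)
}

lognormal_specs <- function(rates, ids = sprintf("pc%02d", seq_along(rates))) {
  specs <- lapply(rates, function(r) if (r > 0) isi_lognormal(r) else NULL)
  names(specs) <- ids
  specs
}

# one substream per input (matching assign_synchrony) plus a trailing
# stream reserved for the excitatory event draws
exc_stream <- function(seed, n_inputs) {
  rng_substreams(seed, n_inputs + 1L)[[n_inputs + 1L]]
}

pooled_input_correlogram <- function(times_list, out_times, bin_width,
                                     window, burn_in) {
  ref <- sort(unlist(times_list))
  ref <- ref[ref >= burn_in]
  correlogram(ref, out_times, bin_width = bin_width, window = window,
              exclude_self = FALSE)
}

#' Input-size cross-correlogram experiment
#'
#' Simulates a convergent inhibitory input set on the `"timing"` preset,
#' then computes, per distinct input amplitude, the normalized
#' cross-correlogram between that class's pooled input spikes and the
#' output train, and its excitation / inhibition / half-decay summary
#' ([extract_eit()]). Shows how input size governs the depth and duration
#' of the spike-timing imprint each input leaves on the output.
#'
#' @param weights unitary amplitudes in nS (default: the simplified
#'   triplet set, 16x3 + 10x10 + 2x30 nS).
#' @param inh_rate inhibitory input firing rate, spikes/s (lognormal ISIs).
#' @param duration simulated seconds.
#' @param seed master seed (trains and excitation derive substreams).
#' @param bin_width,window correlogram resolution, ms.
#' @param neuron,exc_rate neuron preset and excitatory event rate.
#' @param dt,burn_in,chunk integration controls (see
#'   [run_lif_experiment()]).
#' @return List: `run` (driver output), `rate`, `metrics` (data.frame with
#'   one row per amplitude class: `size`, `n_inputs`, `n_ref`, `e`, `i`,
#'   `t_half`), `correlograms` (named list of normalized correlograms).
#' @export
run_size_crosscorr <- function(weights = size_triplet()$sizes, inh_rate = 83,
                               duration = 1000, seed = 1, bin_width = 0.1,
                               window = 10, neuron = neuron_params("timing"),
                               exc_rate = preset_exc_rate("timing"),
                               dt = 0.02, burn_in = 1, chunk = 20) {
  specs <- lognormal_specs(rep(inh_rate, length(weights)))
  trains <- assign_synchrony(specs, list(), duration, seed)
  run <- with_rng_stream(exc_stream(seed, length(specs)),
    run_lif_experiment(neuron, weights, trains, exc_rate, duration, dt,
                       burn_in, chunk))
  out_t <- run$spikes$times[run$spikes$times >= burn_in]
  base <- run$rate
  classes <- sort(unique(weights))
  mets <- vector("list", length(classes))
  ccs <- vector("list", length(classes))
  for (ci in seq_along(classes)) {
    sel <- which(weights == classes[ci])
    cc <- pooled_input_correlogram(lapply(trains[sel], `[[`, "times"),
                                   out_t, bin_width, window, burn_in)
    ncc <- normalize_correlogram(cc, base)
    eit <- extract_eit(ncc)
    mets[[ci]] <- data.frame(size = classes[ci], n_inputs = length(sel),
                             n_ref = cc$n_ref, e = eit$e, i = eit$i,
                             t_half = eit$t_half)
    ccs[[ci]] <- ncc
  }
  names(ccs) <- paste0(classes, "nS")
  list(run = run, rate = base, metrics = do.call(rbind, mets),
       correlograms = ccs)
}

#' Refractory-structure comparison experiment
#'
#' Compares input configurations that share (approximately) the same total
#' inhibition but differ in input firing statistics: lognormal-ISI inputs
#' at 49, 83 and 122 spikes/s (12, 9 and 6 inputs of 20 nS) versus Poisson
#' inputs at 80 spikes/s (9 x 20 nS). Refractory-like (lognormal) inputs
#' produce a dip in the spike-triggered average inhibitory conductance just
#' before their spikes — and hence effective excitation of the output
#' before suppression — which Poisson inputs lack.
#'
#' @param cases data.frame with columns `label`, `family` (`"lognormal"` or
#'   `"poisson"`), `rate` (spikes/s), `n` (input count), `amp` (nS).
#' @param duration simulated seconds per case (correlograms).
#' @param sta_duration seconds of reassembled conductance used for the
#'   spike-triggered average.
#' @inheritParams run_size_crosscorr
#' @return Named list per case: `rate`, `eit`, `correlogram` (normalized),
#'   `sta` ([spike_triggered_average()] of the total inhibitory conductance
#'   on one input's spikes), `total_weight`.
#' @export
run_refractory_comparison <- function(
    cases = data.frame(
      label = c("ln49", "ln83", "ln122", "poisson80"),
      family = c("lognormal", "lognormal", "lognormal", "poisson"),
      rate = c(49, 83, 122, 80), n = c(12, 9, 6, 9), amp = 20),
    duration = 500, sta_duration = 50, seed = 1, bin_width = 0.1,
    window = 10, neuron = neuron_params("timing"),
    exc_rate = preset_exc_rate("timing"), dt = 0.02, burn_in = 1,
    chunk = 20) {
  out <- vector("list", nrow(cases))
  names(out) <- cases$label
  for (k in seq_len(nrow(cases))) {
    cs <- cases[k, ]
    mk <- if (cs$family == "poisson") isi_poisson else isi_lognormal
    specs <- setNames(rep(list(mk(cs$rate)), cs$n),
                      sprintf("pc%02d", seq_len(cs$n)))
    trains <- assign_synchrony(specs, list(), duration, seed + k)
    weights <- rep(cs$amp, cs$n)
    run <- with_rng_stream(exc_stream(seed + k, cs$n),
      run_lif_experiment(neuron, weights, trains, exc_rate, duration, dt,
                         burn_in, chunk))
    out_t <- run$spikes$times[run$spikes$times >= burn_in]
    cc <- pooled_input_correlogram(lapply(trains, `[[`, "times"), out_t,
                                   bin_width, window, burn_in)
    ncc <- normalize_correlogram(cc, run$rate)
    short <- lapply(trains, function(tr)
      spike_train(tr$times[tr$times < sta_duration], sta_duration,
                  tr$unit_id))
    gi <- assemble_inhibition(weights, short, dt, sta_duration)
    trig <- short[[1]]$times
    trig <- trig[trig > window / 1000 & trig < sta_duration - window / 1000]
    out[[k]] <- list(rate = run$rate, eit = extract_eit(ncc),
                     correlogram = ncc,
                     sta = spike_triggered_average(trig, gi, window),
                     total_weight = sum(weights))
  }
  out
}

#' Conductance-variability / firing-rate scan
#'
#' Holds the total inhibitory conductance fixed while varying how it is
#' split across inputs — few large versus many small, plus optional
#' nonuniform draws from the empirical surrogate distribution — and
#' records the coefficient of variation of the summed conductance together
#' with the output firing rate. At fixed mean inhibition, fewer/larger
#' inputs make the conductance more variable and the cell fires faster.
#'
#' @param uniform_sizes uniform input amplitudes to scan (nS); input counts
#'   are `total/size`.
#' @param n_nonuniform number of nonuniform weight draws from `dist`.
#' @param total target summed amplitude, nS.
#' @param uniform_rate,nonuniform_rate input firing rates (spikes/s) for
#'   the uniform and nonuniform configurations.
#' @param dist size distribution for nonuniform draws.
#' @param duration simulated seconds per configuration.
#' @inheritParams run_size_crosscorr
#' @return data.frame with one row per configuration: `config`, `n_inputs`,
#'   `size` (nS; NA for nonuniform), `total_weight`, `gi_mean`, `gi_cv`,
#'   `rate`.
#' @export
run_cv_rate_scan <- function(uniform_sizes = c(2.5, 5, 10, 20, 40),
                             n_nonuniform = 0, total = 200,
                             uniform_rate = 100, nonuniform_rate = 83,
                             dist = size_categorical(), duration = 10,
                             seed = 1, neuron = neuron_params("rate"),
                             exc_rate = preset_exc_rate("rate"), dt = 0.02,
                             burn_in = 1, chunk = 20) {
  run_one <- function(weights, rate, config, size, run_seed) {
    specs <- lognormal_specs(rep(rate, length(weights)))
    trains <- assign_synchrony(specs, list(), duration, run_seed)
    run <- with_rng_stream(exc_stream(run_seed, length(weights)),
      run_lif_experiment(neuron, weights, trains, exc_rate, duration, dt,
                         burn_in, chunk))
    data.frame(config = config, n_inputs = length(weights), size = size,
               total_weight = sum(weights), gi_mean = run$gi_mean,
               gi_cv = run$gi_cv, rate = run$rate)
  }
  rows <- vector("list", 0L)
  for (k in seq_along(uniform_sizes)) {
    sz <- uniform_sizes[k]
    weights <- sample_sizes(size_uniform(sz), total)
    rows[[length(rows) + 1L]] <- run_one(
      weights, uniform_rate, sprintf("uniform_%gnS", sz), sz, seed + k)
  }
  for (d in seq_len(n_nonuniform)) {
    weights <- with_seed(seed + 1000L + d, sample_sizes(dist, total))
    rows[[length(rows) + 1L]] <- run_one(
      weights, nonuniform_rate, sprintf("nonuniform_%02d", d), NA_real_,
      seed + 1000L + d)
  }
  do.call(rbind, rows)
}

#' Rate-code transfer experiment
#'
#' Varies the firing rate of one probe input of a nonuniform 200 nS weight
#' set while the remaining inputs fire at a fixed base rate, and records
#' the output firing rate. The output rate falls approximately linearly
#' with the probe rate, with a slope proportional to the probe amplitude —
#' each input transmits a rate code weighted by its synaptic size.
#'
#' @param probe_size probe input amplitude, nS; the rest of the set is
#'   drawn from `dist` to make up `total`.
#' @param probe_rates probe firing rates to scan, spikes/s (0 = silent).
#' @param base_rate firing rate of the other inputs, spikes/s.
#' @param total target summed amplitude including the probe, nS.
#' @param dist size distribution for the non-probe weights.
#' @param duration simulated seconds per rate point.
#' @inheritParams run_cv_rate_scan
#' @return data.frame with `probe_rate`, `rate`, `gi_mean`, `gi_cv`,
#'   `probe_size`, plus attribute `"weights"` (the drawn set, probe first).
#' @export
run_rate_code_scan <- function(probe_size = 37,
                               probe_rates = seq(0, 160, by = 40),
                               base_rate = 80, total = 200,
                               dist = size_categorical(), duration = 100,
                               seed = 1, neuron = neuron_params("rate"),
                               exc_rate = preset_exc_rate("rate"), dt = 0.02,
                               burn_in = 1, chunk = 20) {
  if (probe_size >= total) stopf("probe_size must be below the total")
  weights <- c(probe_size,
               with_seed(seed, sample_sizes(dist, total - probe_size)))
  n <- length(weights)
  rows <- vector("list", length(probe_rates))
  for (k in seq_along(probe_rates)) {
    rates <- c(probe_rates[k], rep(base_rate, n - 1L))
    trains <- assign_synchrony(lognormal_specs(rates), list(), duration, seed)
    run <- with_rng_stream(exc_stream(seed, n),
      run_lif_experiment(neuron, weights, trains, exc_rate, duration, dt,
                         burn_in, chunk))
    rows[[k]] <- data.frame(probe_rate = probe_rates[k], rate = run$rate,
                            gi_mean = run$gi_mean, gi_cv = run$gi_cv,
                            probe_size = probe_size)
  }
  out <- do.call(rbind, rows)
  attr(out, "weights") <- weights
  out
}

#' Synchrony experiments
#'
#' Measures how perfectly synchronizing subsets of inputs (shared spike
#' times) changes the output firing rate, at fixed total inhibition.
#'
#' `run_synchrony_uniform()` synchronizes `k` of 40 uniform 5 nS inputs for
#' each `k` in `sync_counts`. `run_synchrony_draws()` draws nonuniform
#' weight sets and simulates each asynchronously and with a chosen subset
#' synchronized (`"largest2"`, `"smallest2"`, or an integer index vector).
#' Rate changes are governed by the total synchronized amplitude, not the
#' number of inputs synchronized.
#'
#' @param sync_counts numbers of inputs to synchronize (0 or 1 = none).
#' @param size,n_inputs uniform amplitude (nS) and input count.
#' @param inh_rate input firing rate, spikes/s (lognormal ISIs).
#' @param duration simulated seconds per condition.
#' @inheritParams run_cv_rate_scan
#' @return `run_synchrony_uniform()`: data.frame with `n_sync`,
#'   `sync_amp`, `rate`, `gi_cv`. `run_synchrony_draws()`: data.frame with
#'   one row per draw: `draw`, `n_inputs`, `sync_amp`, `rate_async`,
#'   `rate_sync`, `pct_change`, `gi_cv_async`, `gi_cv_sync`.
#' @export
run_synchrony_uniform <- function(sync_counts = c(0, 5, 10, 20), size = 5,
                                  n_inputs = 40, inh_rate = 80,
                                  duration = 200, seed = 1,
                                  neuron = neuron_params("rate"),
                                  exc_rate = preset_exc_rate("rate"),
                                  dt = 0.02, burn_in = 1, chunk = 20) {
  weights <- rep(size, n_inputs)
  specs <- lognormal_specs(rep(inh_rate, n_inputs))
  ids <- names(specs)
  rows <- vector("list", length(sync_counts))
  for (k in seq_along(sync_counts)) {
    m <- sync_counts[k]
    groups <- if (m >= 2) list(ids[seq_len(m)]) else list()
    trains <- assign_synchrony(specs, groups, duration, seed)
    run <- with_rng_stream(exc_stream(seed, n_inputs),
      run_lif_experiment(neuron, weights, trains, exc_rate, duration, dt,
                         burn_in, chunk))
    rows[[k]] <- data.frame(n_sync = m, sync_amp = if (m >= 2) m * size else 0,
                            rate = run$rate, gi_cv = run$gi_cv)
  }
  do.call(rbind, rows)
}

#' @rdname run_synchrony_uniform
#' @param n_draws number of nonuniform weight-set draws.
#' @param subset which inputs to synchronize per draw: `"largest2"`,
#'   `"smallest2"`, or an integer vector of input indices (draw order).
#' @param total target summed amplitude, nS.
#' @param dist size distribution for the draws.
#' @export
run_synchrony_draws <- function(n_draws = 10, subset = "largest2",
                                total = 200, dist = size_categorical(),
                                inh_rate = 80, duration = 200, seed = 1,
                                neuron = neuron_params("rate"),
                                exc_rate = preset_exc_rate("rate"),
                                dt = 0.02, burn_in = 1, chunk = 20) {
  rows <- vector("list", n_draws)
  for (d in seq_len(n_draws)) {
    dseed <- seed + d
    weights <- with_seed(dseed, sample_sizes(dist, total))
    n <- length(weights)
    sel <- if (identical(subset, "largest2")) {
      order(weights, decreasing = TRUE)[1:2]
    } else if (identical(subset, "smallest2")) {
      order(weights)[1:2]
    } else as.integer(subset)
    specs <- lognormal_specs(rep(inh_rate, n))
    ids <- names(specs)
    run_cond <- function(groups) {
      trains <- assign_synchrony(specs, groups, duration, dseed)
      with_rng_stream(exc_stream(dseed, n),
        run_lif_experiment(neuron, weights, trains, exc_rate, duration, dt,
                           burn_in, chunk))
    }
    async <- run_cond(list())
    sync <- run_cond(list(ids[sel]))
    rows[[d]] <- data.frame(
      draw = d, n_inputs = n, sync_amp = sum(weights[sel]),
      rate_async = async$rate, rate_sync = sync$rate,
      pct_change = 100 * (sync$rate - async$rate) / async$rate,
      gi_cv_async = async$gi_cv, gi_cv_sync = sync$gi_cv)
  }
  do.call(rbind, rows)
}
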