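#' Point-conductance integrate-and-fire neuron parameters
#'
#' The cerebellar-nuclei neuron is a single-compartment leaky
#' integrate-and-fire cell obeying
#' `Cm dV/dt = gE(t)(VE - V) + gI(t)(VI - V) + gL(VL - V)`.
#' A spike is registered when `V` reaches the threshold `theta`; the cell
#' is then refractory for `t_ref` ms and resumes from the reset `Vr`.
#'
#' Two presets cover the experiments in this package:
#' * `"timing"` — `Cm = 50 pF`, `gL = 8.8 nS`, `VL = -40 mV`; paired with
#'   20000 excitatory events/s. Used for cross-correlogram and
#'   spike-timing experiments.
#' * `"rate"` — `Cm = 200 pF`, `gL = 5 nS`, `VL = -10 mV`; paired with
#'   23650 excitatory events/s. Used for firing-rate, conductance-CV and
#'   synchrony experiments.
#'
#' Both share `VE = 0`, `VI = -75`, `theta = -50`, `Vr = -60` mV and
#' `t_ref = 2` ms. Any field can be overridden explicitly.
#'
#' @param preset `"rate"` or `"timing"`, or `NULL` to require all fields.
#' @param Cm membrane capacitance, pF.
#' @param gL leak conductance, nS.
#' @param VL leak reversal potential, mV.
#' @param VE,VI excitatory / inhibitory reversal potentials, mV.
#' @param theta spike threshold, mV.
#' @param Vr reset potential, mV (must be below `theta`).
#' @param t_ref absolute refractory period, ms.
#' @return An object of class `neuron_params`.
#' @export
neuron_params <- function(preset = c("rate", "timing"), Cm = NULL, gL = NULL,
                          VL = NULL, VE = 0, VI = -75, theta = -50, Vr = -60,
                          t_ref = 2) {
  if (!is.null(preset)) {
    preset <- match.arg(preset)
    base <- switch(preset,
      rate   = list(Cm = 200, gL = 5, VL = -10),
      timing = list(Cm = 50, gL = 8.8, VL = -40))
    Cm <- Cm %||% base$Cm
    gL <- gL %||% base$gL
    VL <- VL %||% base$VL
  }
  if (is.null(Cm) || is.null(gL) || is.null(VL))
    stopf("Cm, gL and VL must be given when no preset is used")
  if (Cm <= 0 || gL <= 0) stopf("Cm and gL must be positive")
  if (!(Vr < theta)) stopf("reset Vr must lie below threshold theta")
  if (t_ref < 0) stopf("t_ref must be >= 0 ms")
  structure(list(preset = if (is.null(preset)) NA_character_ else preset,
                 Cm = Cm, gL = gL, VL = VL, VE = VE, VI = VI,
                 theta = theta, Vr = Vr, t_ref = t_ref),
            class = "neuron_params")
}

#' @export
print.neuron_params <- function(x, ...) {
  cat(sprintf(
    "LIF neuron [%s]: Cm=%g pF, gL=%g nS, VL=%g mV, theta=%g, Vr=%g, t_ref=%g ms\n",
    x$preset, x$Cm, x$gL, x$VL, x$theta, x$Vr, x$t_ref))
  invisible(x)
}

#' Excitatory event rate paired with a neuron preset
#'
#' @param preset `"rate"` (23650 events/s) or `"timing"` (20000 events/s).
#' @return Events per second.
#' @export
preset_exc_rate <- function(preset = c("rate", "timing")) {
  switch(match.arg(preset), rate = 23650, timing = 20000)
}

as_g_trace <- function(g, dt, n) {
  if (inherits(g, "conductance_trace")) {
    if (abs(g$dt - dt) > 1e-12)
      stopf("conductance sampled at dt = %g ms, expected %g ms", g$dt, dt)
    if (length(g$values) < n)
      stopf("conductance trace shorter than the simulation")
    g$values[seq_len(n)]
  } else if (is.numeric(g) && length(g) == 1L) {
    rep(as.numeric(g), n)
  } else stopf("conductances must be conductance_trace objects or scalars")
}

#' Simulate the integrate-and-fire neuron
#'
#' Integrates the membrane equation by exponential Euler with conductances
#' held constant within each step — exact in the constant-conductance
#' limit, unconditionally stable otherwise. Threshold crossings are
#' registered at the end of the step in which `V >= theta`; during the
#' refractory period `V` is clamped at `Vr` while the conductances continue
#' to evolve. Integration starts from `V = Vr` (or a carried state).
#'
#' @param params a [neuron_params()] object.
#' @param gE,gI excitatory / inhibitory conductances: [conductance_trace()]
#'   objects on a shared grid, or scalars (nS) for constant conductance.
#' @param duration simulated time in seconds; defaults to the trace length,
#'   and is required when both conductances are scalars.
#' @param dt integration step in ms (must match trace sampling).
#' @param record_v if `TRUE`, keep the membrane-potential trace.
#' @param state carried state from a previous call (chunked integration),
#'   as returned in `$state`.
#' @param t0 start time in seconds of this segment (spike times are global).
#' @return An object of class `sim_result`: `spikes` (a [spike_train()]),
#'   `params`, `dt`, `state`, and optionally `v` (mV samples).
#' @examples
#' p <- neuron_params("rate")
#' r <- simulate_neuron(p, gE = 0, gI = 0, duration = 1)
#' firing_rate(r, burn_in = 0.2)   # ~91.5 spikes/s
#' @export
simulate_neuron <- function(params, gE, gI, duration = NULL, dt = 0.02,
                            record_v = FALSE, state = NULL, t0 = 0) {
  stopifnot(inherits(params, "neuron_params"))
  if (inherits(gE, "conductance_trace")) dt <- gE$dt
  else if (inherits(gI, "conductance_trace")) dt <- gI$dt
  if (is.null(duration)) {
    len <- function(g) if (inherits(g, "conductance_trace"))
      length(g$values) * g$dt / 1000 else Inf
    duration <- min(len(gE), len(gI))
    if (!is.finite(duration))
      stopf("duration is required when both conductances are constant")
  }
  n <- n_samples_for(duration, dt)
  res <- lif_cpp(as_g_trace(gE, dt, n), as_g_trace(gI, dt, n), dt,
                 params$Cm, params$gL, params$VL, params$VE, params$VI,
                 params$theta, params$Vr,
                 ref_steps = as.integer(round(params$t_ref / dt)),
                 V0 = state$V %||% params$Vr,
                 ref_left0 = state$ref_left %||% 0L,
                 t0_ms = t0 * 1000, record_v = record_v)
  times <- res$spike_ms / 1000
  dur_end <- t0 + duration
  # a crossing in the very last step is stamped at the segment end
  if (length(times) && times[length(times)] >= dur_end)
    dur_end <- times[length(times)] + 1e-9
  out <- list(
    spikes = spike_train(times, dur_end, unit_id = "output"),
    params = params, dt = dt,
    state = list(V = res$V, ref_left = res$ref_left))
  if (record_v) out$v <- res$v_trace
  structure(out, class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf("LIF simulation: %d spikes over %.6g s (%.4g /s)\n",
              length(x$spikes$times), x$spikes$duration,
              length(x$spikes$times) / max(x$spikes$duration, 1e-12)))
  invisible(x)
}

#' Closed-form interspike interval for constant conductances
#'
#' With constant `gE` and `gI` the membrane equation is linear with
#' steady state `Vinf = (gE*VE + gI*VI + gL*VL) / (gE + gI + gL)` and time
#' constant `tau = Cm / (gE + gI + gL)`. If `Vinf > theta` the cell fires
#' periodically with interval
#' `t_ref + tau * log((Vinf - Vr) / (Vinf - theta))`; otherwise it never
#' fires (`Inf`). This is the analytic oracle against which the numerical
#' integrator is validated.
#'
#' @param params a [neuron_params()] object.
#' @param gE_const,gI_const constant conductances in nS (`>= 0`).
#' @return Interspike interval in ms, or `Inf`.
#' @examples
#' closed_form_isi(neuron_params("rate"), 0, 0)     # 10.926 ms
#' closed_form_isi(neuron_params("rate"), 15, 30)   # 7.011 ms
#' @export
closed_form_isi <- function(params, gE_const, gI_const) {
  stopifnot(inherits(params, "neuron_params"))
  if (gE_const < 0 || gI_const < 0) stopf("conductances must be >= 0")
  gtot <- gE_const + gI_const + params$gL
  vinf <- (gE_const * params$VE + gI_const * params$VI +
             params$gL * params$VL) / gtot
  if (vinf <= params$theta) return(Inf)
  params$t_ref + params$Cm / gtot *
    log((vinf - params$Vr) / (vinf - params$theta))
}
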