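---
title: "Modeling convergent Purkinje-cell inhibition of cerebellar nuclei neurons"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling convergent Purkinje-cell inhibition of cerebellar nuclei neurons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cbnsim)
```

## The scientific problem

Each glutamatergic projection neuron of the cerebellar nuclei (CbN) receives
convergent inhibition from tens of Purkinje cells (PCs), which fire
spontaneously at 40–160 spikes/s. Unitary PC→CbN synaptic conductances are
strongly nonuniform: most inputs are small (a few nS) but a few are an order
of magnitude larger. `cbnsim` implements a complete in-silico version of the
dynamic-clamp paradigm used to study this system: synthetic PC spike trains
drive biexponential synaptic conductances that are summed and injected into
a point-conductance integrate-and-fire CbN neuron, whose output is analyzed
with firing-rate, interspike-interval, cross-correlogram, spike-triggered
average, and synchrony statistics.

Two questions organize the experiments: how does the *division* of a fixed
total inhibitory conductance among inputs of different sizes set the CbN
baseline rate (a variance effect — the coefficient of variation of the
summed conductance), and how faithfully does each individual input transmit
a *rate code* and a *temporal code* to the output, as a function of its
size?

## The model

### Input spike trains

PC firing is regular in a refractory-like way. We model each PC's
interspike intervals (ISIs) as i.i.d. lognormal draws. Across PCs recorded
in vivo, the ISI standard deviation tracks the ISI mean linearly,

$$\mathrm{sd} = -0.00154 + 0.583\,\mathrm{mean} \quad(\text{seconds}),$$

so one number — the target rate — fixes the whole distribution
(`isi_lognormal()`). The natural-log parameters come from moment inversion:
$\sigma^2 = \ln(1 + (\mathrm{sd}/\mathrm{mean})^2)$,
$\mu = \ln(\mathrm{mean}) - \sigma^2/2$. The relation has positive sd only
for rates below $0.583/0.00154 \approx 378.6$ spikes/s, which covers the
physiological range. A Poisson family (`isi_poisson()`) provides the
memoryless control, and `isi_resampled()` draws from a user-supplied ISI
pool when real recordings are available.

Trains start at a uniform random fraction of one drawn ISI — an
approximately stationary phase — because the initialization convention of
the original experiments is not determined by anything we model. No hard
refractory floor is imposed beyond the lognormal shape itself; the
near-zero density at short ISIs already produces the autocorrelogram
trough that drives the timing results.

Each unit owns an independent L'Ecuyer-CMRG substream derived from one
master seed, so adding or regrouping inputs never perturbs the other
units' spike times. Synchrony is modelled as its experimental definition:
units in a synchrony group share one spike train verbatim
(`assign_synchrony()`), which makes $k$ synchronized equal inputs *exactly*
equivalent to a single input of $k$-fold amplitude — a property the test
suite checks bitwise.

### Synaptic conductances

A unitary synaptic event is a peak-normalized difference of exponentials,

$$k(t) = A\,\frac{e^{-t/\tau_d} - e^{-t/\tau_r}}{N},$$

with $N$ chosen so the peak equals $A$ exactly. Inhibition uses
$\tau_r = 0.1$ ms, $\tau_d = 2.5$ ms, reversal $-75$ mV; excitation uses
$A = 0.4$ nS, $\tau_r = 0.28$ ms, $\tau_d = 1.06$ ms, reversal 0 mV. The
nominal "rise time" and "decay time" are interpreted as the two exponential
time constants (not 10–90% times): this is the standard biexponential
synapse and is consistent with the stated peak-amplitude semantics. The
closed-form peak time and integral (`make_kernel()`) serve as oracles in
the tests.

Convolution is implemented as two one-pole recursive filters (one per
exponential), which evaluates the superposed kernels *exactly* on the
sample grid with no tail truncation and costs O(samples) regardless of
event rate. Spike times are quantized to the grid, a bias of at most
$dt/2 = 0.01$ ms against a 0.1 ms rise. The excitatory drive is a
homogeneous Poisson stream (20000 or 23650 events/s depending on preset)
drawn as per-bin Poisson counts, the grid-quantized equivalent of drawing
event times.

Input amplitude sets are built by `sample_sizes()`: i.i.d. draws from a
size distribution until the running total reaches the target (200 nS),
rejecting and restarting if the final total overshoots by more than 5% —
the overshoot rule is our choice, as only the target total is specified.
Raw voltage-clamp amplitudes can be corrected for synaptic depression
(×0.4) and the high-chloride recording bias (÷2.3) with
`correct_amplitudes()`. Three empirically motivated distributions are
provided: the fixed simplified triplet (16×3 + 10×10 + 2×30 nS, nominal
200 nS, exact sum 208 nS), a categorical reduction of the corrected
empirical size distribution over {3, 10, 30} nS with weights 16:10:2, and
`size_empirical()`, a synthetic continuous surrogate (truncated lognormal,
calibrated in closed form so its small/medium/large class probabilities
match 16:10:2; skewed synaptic weight distributions are conventionally
described as lognormal). The categorical surrogate is the default in the
scenario runners; the published numeric size list itself is not available.

### The neuron

The CbN cell is a single-compartment conductance-based leaky
integrate-and-fire neuron,

$$C_m \frac{dV}{dt} = g_E(t)(V_E - V) + g_I(t)(V_I - V) + g_L(V_L - V),$$

with threshold $\theta = -50$ mV, reset $V_r = -60$ mV and a 2 ms absolute
refractory period. Two presets are used: `"timing"`
($C_m = 50$ pF, $g_L = 8.8$ nS, $V_L = -40$ mV, 20000 excitatory
events/s), used for the cross-correlogram experiments, and `"rate"`
($C_m = 200$ pF, $g_L = 5$ nS, $V_L = -10$ mV, 23650 events/s), used for
the firing-rate, CV and synchrony experiments.

Integration is exponential Euler with conductances held constant within
each $dt = 0.02$ ms step — exact in the constant-conductance limit and
unconditionally stable. A crossing is registered at the end of the step in
which $V \ge \theta$ (no sub-step interpolation); during refractoriness
$V$ is clamped at $V_r$ while the conductances continue to evolve, since
the behavior of $V$ during the "inactive" period is not otherwise
specified. Integration starts at $V_r$ and a 1 s burn-in is discarded from
all statistics, replacing the slow conductance ramp-in that protected the
biological cells at trial onset. With constant conductances the model has
the closed form
$$\mathrm{ISI} = t_{ref} + \tau \ln\frac{V_\infty - V_r}{V_\infty - \theta},
\qquad \tau = \frac{C_m}{g_E + g_I + g_L},$$
(`closed_form_isi()`), the oracle against which the integrator is verified
to within one time step across both presets; halving $dt$ changes
experiment firing rates by under 1%.

### Analyses

Cross- and auto-correlograms follow the accumulative-histogram definition:
for every reference spike, target spikes within ±10 ms are binned by lag
(0.1 ms default bins — our choice, as the original bin width is not
stated) and counts are divided by the reference spike count and the bin
width, giving conditional rate in spikes/s; dividing further by the mean
output rate gives the normalized, dimensionless form that hovers at 1 for
independent trains. Zero-lag self pairs are excluded from
autocorrelograms.

The stereotyped input–output correlogram of an inhibitory input is
summarized by three numbers (`extract_eit()`): `e`, the peak normalized
excess over baseline in the window [−4, 0] ms before the input spike
(disinhibition caused by the input's own refractory period); `i`, one
minus the trough minimum in [0, +6] ms (suppression depth); and `t_half`,
the lag from the trough to half-recovery toward baseline. The windows are
our choice, bracketing where the features occur. The trough lag is defined
as the *last* bin attaining the minimum, so that for an input that
silences the cell completely the half-decay clock starts when the silence
ends; extraction requires the baseline (mean over [−10, −8] ms) to lie
within 1 ± 0.1. Peak and trough are read from the binned values directly,
without smoothing — counting noise is controlled by simulation duration
rather than by filtering.

Spike-triggered averages of conductance traces drop triggers whose ±10 ms
window leaves the trace and require at least 90% of triggers to survive.

## Scenario runners and problem sizes

`run_lif_experiment()` streams spike binning, filtering and integration
through 20 s chunks, carrying filter and membrane state across boundaries,
so memory stays flat however long the run; a test verifies the chunked
path reproduces the one-shot convolve-then-simulate path exactly on shared
inputs. The runners wire this into the experiments:

* `run_size_crosscorr()` — triplet inputs at 83 spikes/s on the timing
  preset; per-size-class pooled correlograms and e/i/t½.
* `run_refractory_comparison()` — 12×20 nS at 49 Hz, 9×20 nS at 83 Hz,
  6×20 nS at 122 Hz lognormal, and 9×20 nS Poisson at 80 Hz; STAs and
  correlograms.
* `run_cv_rate_scan()` — 200 nS split as 80×2.5 … 5×40 nS uniform (at
  100 spikes/s) plus optional nonuniform draws (at 83 spikes/s).
* `run_rate_code_scan()` — one probe input (default 37 nS) scanned over
  0–160 spikes/s while the rest of a 200 nS set fires at 80 spikes/s.
* `run_synchrony_uniform()` / `run_synchrony_draws()` — synchronizing k of
  40×5 nS inputs, or chosen subsets (largest two, smallest two) of
  nonuniform draws.

The reference experiments behind the timing metrics ran for 160,000 s per
cell; that precision is unnecessary for the quantities we extract. The
package's acceptance runs use 5,000 s for the correlogram metrics
(counting error per 0.1 ms bin ≈ 1–2% for the large-input class), 100 s
per rate point averaged over 20 weight draws for the rate-code endpoints,
and 20 draws × 200 s per condition for the synchrony contrast; the test
suite uses further-scaled versions of the same configurations with
tolerances that respect the implied counting error.

## What the generator does and does not emulate

The synthetic trains reproduce the first-order ISI statistics (lognormal
shape, the sd–mean relation, hence rate-dependent refractoriness) and
stationary firing at a fixed rate per run. They do not model complex
spikes, bursting, rate modulation within a train, or cross-PC correlations
other than the imposed all-or-none synchrony; short-term depression enters
only as the static ×0.4 amplitude correction. Passing tests therefore
demonstrate the model's behavior under stationary, independently firing
inputs with realistic ISI dispersion — not under the full richness of in
vivo PC dynamics.

## Numerical choices and degenerate inputs

* `dt = 0.02` ms resolves the 0.1 ms synaptic rise with five samples; the
  convolution precondition `dt ≤ τ_r/2` is enforced with an informative
  error.
* Empty spike trains, zero-rate inputs and zero-amplitude kernels are
  valid and produce zero conductance; an empty reference train is an error
  for correlograms (the normalization is undefined), as is a zero-mean
  trace for a CV.
* Ties in the correlogram trough are broken toward the latest minimal bin
  (see above); `t_half` is `NA` if the trough never recovers halfway
  within the window.
* The 5% overshoot rule in `sample_sizes()` restarts the draw rather than
  trimming, keeping draws i.i.d. conditional on acceptance.

## Known limitations

* The corrected empirical input-size list is not published; both provided
  surrogates (categorical and truncated lognormal) match its coarse class
  structure but not its exact tail. The rate-code endpoint rates of the
  fluctuation-driven regime are sensitive to the large-input mass of the
  weight distribution, and pooled-over-draw values can sit 15–25% below
  the single example configuration reported for the reference experiment;
  the timing metrics and synchrony contrasts are robust to this choice.
* The integrate-and-fire cell is passive: no adaptation, rebound or
  voltage-gated currents, so dynamic-clamp measurements in biological
  neurons (whose effective parameters differ) are matched qualitatively,
  not numerically.
* Threshold crossing is resolved only to the integration step; with
  `dt = 0.02` ms this biases rates by well under 1%.

## A worked example

```{r example, eval = FALSE}
# Rate transmitted by one large input (scaled-down illustration)
df <- run_rate_code_scan(probe_size = 37, probe_rates = c(0, 80, 160),
                         duration = 20, seed = 1)
df
# slope of the rate code carried by this input, spikes/s per spikes/s
coef(lm(rate ~ probe_rate, df))[2]
```
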