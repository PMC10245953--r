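#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Difference-of-exponentials synaptic filter, evaluated as two first-order
// recursions y[n] = a*y[n-1] + x[n]. For an impulse of weight w in bin n0
// the output is w*scale*(exp(-(n-n0)dt/tau_d) - exp(-(n-n0)dt/tau_r)):
// the kernel sampled exactly on the grid, with no tail truncation.
// State (the two accumulators) is carried so long runs can be chunked.
// [[Rcpp::export]]
List biexp_filter_cpp(NumericVector impulses, double a_decay, double a_rise,
                      double scale, double y_decay0, double y_rise0) {
  R_xlen_t n = impulses.size();
  NumericVector out(n);
  double yd = y_decay0, yr = y_rise0;
  for (R_xlen_t i = 0; i < n; ++i) {
    yd = a_decay * yd + impulses[i];
    yr = a_rise * yr + impulses[i];
    out[i] = scale * (yd - yr);
  }
  return List::create(_["values"] = out, _["y_decay"] = yd, _["y_rise"] = yr);
}

// Accumulate weighted event impulses onto a sample grid covering
// [t0, t0 + n*dt_s). weights is either length 1 (shared) or one per event.
// Events outside the window are ignored.
// [[Rcpp::export]]
NumericVector bin_events_cpp(NumericVector times, NumericVector weights,
                             double t0, double dt_s, int n) {
  NumericVector out(n);
  bool shared = weights.size() == 1;
  for (R_xlen_t i = 0; i < times.size(); ++i) {
    double rel = times[i] - t0;
    if (rel < 0) continue;
    int k = (int)std::floor(rel / dt_s);
    if (k >= n) continue;
    out[k] += shared ? weights[0] : weights[i];
  }
  return out;
}

// Conductance-based LIF, exponential-Euler update with conductances held
// constant within each step (exact in the constant-conductance limit).
// A spike is registered at the end of the step in which V >= theta; V is
// then clamped at Vr for ref_steps steps while conductances evolve.
// Membrane state (V, remaining refractory steps) is carried across calls.
// [[Rcpp::export]]
List lif_cpp(NumericVector gE, NumericVector gI, double dt_ms,
             double Cm, double gL, double VL, double VE, double VI,
             double theta, double Vr, int ref_steps,
             double V0, int ref_left0, double t0_ms, bool record_v) {
  R_xlen_t n = gE.size();
  if (gI.size() != n) stop("gE and gI must share one sample grid");
  std::vector<double> spikes;
  NumericVector vtrace(record_v ? n : 0);
  double V = V0;
  int ref_left = ref_left0;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (ref_left > 0) {
      V = Vr;
      --ref_left;
    } else {
      double ge = gE[i], gi = gI[i];
      double gtot = ge + gi + gL;
      double vinf = (ge * VE + gi * VI + gL * VL) / gtot;
      V = vinf + (V - vinf) * std::exp(-dt_ms * gtot / Cm);
      if (V >= theta) {
        spikes.push_back(t0_ms + (i + 1) * dt_ms);
        V = Vr;
        ref_left = ref_steps;
      }
    }
    if (record_v) vtrace[i] = V;
  }
  return List::create(_["spike_ms"] = wrap(spikes), _["V"] = V,
                      _["ref_left"] = ref_left, _["v_trace"] = vtrace);
}

// Pair counts for the cross-correlogram: for every reference event, target
// events with lag in [-half_win, half_win) are binned by lag. Both inputs
// must be sorted ascending. When exclude_self is true, pairs at exactly
// zero lag are dropped once per reference event (autocorrelogram).
// [[Rcpp::export]]
NumericVector corr_counts_cpp(NumericVector ref, NumericVector target,
                              double half_win_s, double bin_s,
                              bool exclude_self) {
  int nbins = (int)std::lround(2.0 * half_win_s / bin_s);
  NumericVector counts(nbins);
  R_xlen_t lo = 0, nt = target.size();
  for (R_xlen_t i = 0; i < ref.size(); ++i) {
    double r = ref[i];
    while (lo < nt && target[lo] < r - half_win_s) ++lo;
    bool self_seen = false;
    for (R_xlen_t j = lo; j < nt && target[j] < r + half_win_s; ++j) {
      double lag = target[j] - r;
      if (exclude_self && !self_seen && lag == 0.0) {
        self_seen = true;
        continue;
      }
      int b = (int)std::floor((lag + half_win_s) / bin_s);
      if (b >= 0 && b < nbins) counts[b] += 1.0;
    }
  }
  return counts;
}

// Sum of trace segments centered on trigger sample indices (0-based);
// triggers whose window extends beyond the trace are skipped.
// [[Rcpp::export]]
List sta_cpp(IntegerVector trig_idx, NumericVector trace, int half_steps) {
  int w = 2 * half_steps + 1;
  NumericVector acc(w);
  R_xlen_t n = trace.size();
  int used = 0;
  for (R_xlen_t i = 0; i < trig_idx.size(); ++i) {
    int c = trig_idx[i];
    if (c < half_steps || c + half_steps >= n) continue;
    for (int k = 0; k < w; ++k) acc[k] += trace[c - half_steps + k];
    ++used;
  }
  return List::create(_["sum"] = acc, _["n_used"] = used,
                      _["n_total"] = (int)trig_idx.size());
}
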