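# Shared fixture builders for the test suite. Everything is generated in
# code under fixed seeds; no data files are read.

# A correlogram object with chosen lags/values, for exercising the metric
# extraction logic directly.
manual_correlogram <- function(lags, values, normalized = TRUE) {
  structure(list(lags = lags, values = values,
                 bin_width = diff(lags[1:2]), n_ref = 1000L,
                 normalized = normalized),
            class = "correlogram")
}

# Population of independent lognormal-ISI trains plus matching weights.
make_population <- function(n, rate, duration, seed) {
  specs <- setNames(rep(list(isi_lognormal(rate)), n),
                    sprintf("pc%02d", seq_len(n)))
  assign_synchrony(specs, list(), duration, seed)
}

# Closed-form shot-noise moments (Campbell's theorem) for a kernel driven
# by a Poisson train of the given rate: mean = r * int k dt,
# var = r * int k^2 dt. Integrals evaluated by adaptive quadrature, so the
# oracle is independent of the package's closed forms and filters.
campbell_moments <- function(kernel, rate_per_s) {
  r_ms <- rate_per_s / 1000
  k <- function(t) kernel_eval(kernel, t)
  m <- r_ms * integrate(k, 0, Inf)$value
  v <- r_ms * integrate(function(t) k(t)^2, 0, Inf)$value
  list(mean = m, var = v)
}
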