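test_that("correlogram normalization gives conditional rate in spikes/s", {
  set.seed(101)
  a <- generate_poisson_train(80, 600)
  b <- generate_poisson_train(80, 600)
  cc <- correlogram(a, b, bin_width = 0.5, window = 10)
  expect_length(cc$values, 40)
  # independent trains: every bin at the target rate within 3 counting sd
  per_bin <- cc$n_ref * 80 * 0.5e-3
  expect_true(all(abs(cc$values - 80) <= 3.5 * sqrt(per_bin) / per_bin * 80))

  empty <- spike_train(numeric(0), 600)
  expect_true(all(correlogram(a, empty)$values == 0))
  expect_error(correlogram(empty, a), "empty")
  expect_error(correlogram(a, b, bin_width = 0.3), "evenly")
})

test_that("correlogram is symmetric after reference-count rescaling", {
  set.seed(103)
  a <- generate_poisson_train(60, 300)
  b <- generate_train(isi_lognormal(90), 300)
  ab <- correlogram(a, b, bin_width = 1)
  ba <- correlogram(b, a, bin_width = 1)
  expect_equal(ab$values, rev(ba$values) * ba$n_ref / ab$n_ref,
               tolerance = 1e-12)
})

test_that("autocorrelogram shows the refractory trough of lognormal trains", {
  set.seed(107)
  fast <- generate_train(isi_lognormal(122), 300)
  ac <- autocorrelogram(fast, bin_width = 0.5)
  inner <- abs(ac$lags) < 1.25
  outer <- abs(ac$lags) > 7.5
  expect_lt(mean(ac$values[inner]), 0.05 * mean(ac$values[outer]))

  # Poisson autocorrelogram is flat at the rate for all nonzero lags
  po <- generate_poisson_train(80, 600)
  acp <- autocorrelogram(po, bin_width = 0.5)
  per_bin <- acp$n_ref * 80 * 0.5e-3
  expect_true(all(abs(acp$values - 80) <= 3.5 * sqrt(per_bin) / per_bin * 80))
})

test_that("normalization divides by baseline and round-trips", {
  flat <- manual_correlogram(seq(-9.75, 9.75, 0.5), rep(72, 40),
                             normalized = FALSE)
  ncc <- normalize_correlogram(flat, 72)
  expect_true(all(ncc$values == 1))
  expect_equal(ncc$values * 72, flat$values)
  expect_error(normalize_correlogram(flat, 0), "positive")
})

test_that("spike-triggered averages recover the kernel and the pre-spike dip", {
  cst <- conductance_trace(rep(4, 5000), dt = 0.1)
  st <- spike_triggered_average(spike_train(c(0.1, 0.2, 0.3), 0.5), cst)
  expect_true(all(st$values == 4))
  expect_error(spike_triggered_average(spike_train(numeric(0), 1), cst),
               "empty")

  # own-spike STA of a Poisson input: flat baseline before lag 0, kernel
  # shape riding on the mean after it
  set.seed(109)
  trains <- lapply(1:8, function(i) generate_poisson_train(80, 60,
                                                           paste0("p", i)))
  gi <- assemble_inhibition(rep(10, 8), trains, dt = 0.05, duration = 60)
  trig <- trains[[1]]$times
  trig <- trig[trig > 0.011 & trig < 60 - 0.011]
  st <- spike_triggered_average(trig, gi, window = 10)
  base <- mean(st$values[st$lags < -2])
  post <- st$values[st$lags >= 0]
  peak_lag <- st$lags[st$lags >= 0][which.max(post)]
  expect_equal(peak_lag, 0.35, tolerance = 0.3)
  expect_equal(max(post) - base, 10, tolerance = 0.1)
  pre <- st$values[st$lags < -1]
  expect_lt(max(abs(pre - base)) / base, 0.05)

  # refractory (lognormal) input: STA dips below baseline just before lag 0
  set.seed(110)
  ltr <- lapply(1:8, function(i) generate_train(isi_lognormal(83), 60,
                                                paste0("l", i)))
  gil <- assemble_inhibition(rep(10, 8), ltr, dt = 0.05, duration = 60)
  trig <- ltr[[1]]$times
  trig <- trig[trig > 0.011 & trig < 60 - 0.011]
  stl <- spike_triggered_average(trig, gil, window = 10)
  basel <- mean(stl$values[stl$lags < -8])
  dip <- min(stl$values[stl$lags > -4 & stl$lags < 0])
  expect_lt(dip, basel - 0.5)
})

test_that("e/i/t_half extraction matches hand-constructed correlograms", {
  lags <- seq(-10, 10, by = 0.5)
  flat <- manual_correlogram(lags, rep(1, length(lags)))
  expect_equal(extract_eit(flat), list(e = 0, i = 0, t_half = 0))

  v <- rep(1, length(lags))
  v[lags == -1] <- 1.3
  v[lags >= 0 & lags <= 2] <- 0.2
  ramp <- lags > 2 & lags < 4
  v[ramp] <- 0.2 + 0.8 * (lags[ramp] - 2) / 2
  eit <- extract_eit(manual_correlogram(lags, v))
  expect_equal(eit$e, 0.3)
  expect_equal(eit$i, 0.8)
  expect_equal(eit$t_half, 1.0)

  bad <- manual_correlogram(lags, rep(1.5, length(lags)))
  expect_error(extract_eit(bad), "baseline")
  raw <- manual_correlogram(lags, rep(1, length(lags)), normalized = FALSE)
  expect_error(extract_eit(raw), "normalized")
})

test_that("firing rate discards the burn-in exactly", {
  tr <- spike_train(seq(0.05, 9.95, length.out = 100), 10)
  expect_equal(firing_rate(tr, burn_in = 1), (100 - 10) / 9)
  expect_equal(firing_rate(spike_train(numeric(0), 10), 1), 0)
  expect_error(firing_rate(tr, burn_in = 10), "exceed")
})

test_that("ISI statistics recover the generating moments", {
  per <- spike_train(seq(0, 0.99, by = 0.01), 1)
  st <- isi_stats(per)
  expect_equal(c(st$mean, st$sd, st$cv), c(0.01, 0, 0))
  expect_error(isi_stats(spike_train(0.5, 1)), "2 spikes")

  set.seed(113)
  stp <- isi_stats(generate_poisson_train(80, 500))
  expect_equal(stp$cv, 1, tolerance = 0.03)
  ltr <- generate_train(isi_lognormal(80), 500)
  stl <- isi_stats(ltr)
  expect_equal(stl$mean, 0.0125, tolerance = 0.01)
  expect_equal(stl$sd, isi_lognormal(80)$sd_isi, tolerance = 0.05)
  expect_equal(sum(stl$histogram$count), length(ltr$times) - 1L)
})
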