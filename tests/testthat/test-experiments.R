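test_that("chunked streaming equals one-shot convolve-and-simulate", {
  trains <- make_population(6, 80, 10, seed = 5)
  set.seed(9)
  exc <- generate_poisson_train(2000, 10)
  w <- c(3, 3, 10, 10, 30, 30)
  p <- neuron_params("rate")
  run <- run_lif_experiment(p, w, trains, exc_rate = 0, duration = 10,
                            exc_train = exc, chunk = 3)
  gi <- assemble_inhibition(w, trains, dt = 0.02, duration = 10)
  ge <- convolve_train(exc, epsg_kernel(), dt = 0.02, duration = 10)
  sim <- simulate_neuron(p, ge, gi)
  expect_equal(run$spikes$times, sim$spikes$times, tolerance = 1e-12)
  st <- trace_stats(gi, burn_in = 1)
  expect_equal(run$gi_mean, st$mean, tolerance = 1e-9)
  expect_equal(run$gi_sd, st$sd, tolerance = 1e-9)
})

test_that("runners are bitwise reproducible from (config, seed)", {
  a <- run_rate_code_scan(probe_rates = c(0, 160), duration = 5, seed = 3)
  b <- run_rate_code_scan(probe_rates = c(0, 160), duration = 5, seed = 3)
  expect_identical(a, b)
})

test_that("synchronizing k equal inputs equals one k-fold input exactly", {
  p <- neuron_params("rate")
  specs <- setNames(rep(list(isi_lognormal(80)), 10), sprintf("s%02d", 1:10))
  sync <- assign_synchrony(specs, list(names(specs)), 8, seed = 23)
  lone <- assign_synchrony(specs[1], list(), 8, seed = 23)
  set.seed(31); exc <- generate_poisson_train(5000, 8)
  r1 <- run_lif_experiment(p, rep(5, 10), sync, exc_rate = 0, duration = 8,
                           exc_train = exc)
  r2 <- run_lif_experiment(p, 50, lone, exc_rate = 0, duration = 8,
                           exc_train = exc)
  expect_identical(r1$spikes$times, r2$spikes$times)
  expect_identical(r1$gi_mean, r2$gi_mean)
})

test_that("input-size experiment orders e and i by synaptic size", {
  res <- run_size_crosscorr(duration = 120, seed = 17)
  m <- res$metrics[order(res$metrics$size), ]
  expect_identical(m$size, c(3, 10, 30))
  expect_true(all(diff(m$e) > 0))
  expect_true(all(diff(m$i) > 0))
  expect_true(all(m$i >= 0 & m$i <= 1))
})

test_that("refractory inputs give disinhibition before inhibition; Poisson do not", {
  rc <- run_refractory_comparison(duration = 150, sta_duration = 120, seed = 2)
  e <- vapply(rc, function(x) x$eit$e, numeric(1))
  # effective excitation ordered by input rate; Poisson near zero
  expect_true(e[["ln122"]] > e[["ln83"]])
  expect_true(e[["ln83"]] > e[["ln49"]])
  expect_gt(e[["ln49"]], e[["poisson80"]] + 0.02)
  expect_lt(e[["poisson80"]], 0.1)
  # STA: pre-spike dip for lognormal, flat for Poisson (dip measured as a
  # window mean so counting noise does not bias it upward)
  dip_of <- function(x) {
    s <- x$sta
    base <- mean(s$values[s$lags < -8])
    (base - mean(s$values[s$lags > -2.5 & s$lags < -0.5])) / base
  }
  expect_gt(dip_of(rc$ln83), 0.05)
  expect_lt(dip_of(rc$poisson80), 0.025)
  expect_gt(dip_of(rc$ln83), 2 * abs(dip_of(rc$poisson80)))
})

test_that("firing rate rises with conductance CV at fixed mean inhibition", {
  df <- run_cv_rate_scan(duration = 20, seed = 7)
  expect_equal(nrow(df), 5)
  # uniform 40 x 5 nS has the lowest CV of the 200 nS configurations
  expect_true(all(df$gi_cv[df$size == 2.5] < df$gi_cv[df$size != 2.5]))
  expect_lt(df$gi_cv[df$size == 5], min(df$gi_cv[df$size >= 10]))
  # mean conductance is the same across the scan; rate tracks CV
  expect_lt(diff(range(df$gi_mean)) / mean(df$gi_mean), 0.1)
  expect_gt(cor(df$gi_cv, df$rate, method = "spearman"), 0.9)
})

test_that("rate-code scan: output falls with probe rate, scaled by probe size", {
  big <- run_rate_code_scan(probe_size = 30, probe_rates = c(0, 80, 160),
                            duration = 40, seed = 5)
  small <- run_rate_code_scan(probe_size = 3, probe_rates = c(0, 80, 160),
                              duration = 40, seed = 5)
  slope <- function(df) unname(coef(lm(rate ~ probe_rate, df))[2])
  expect_lt(slope(big), 0)
  expect_lt(abs(slope(small)), abs(slope(big)))
  # output rate decreases with the probe's contribution to inhibition
  expect_true(all(diff(big$rate) < 0))
})

test_that("synchrony gains grow with the synchronized amplitude", {
  df <- run_synchrony_uniform(sync_counts = c(0, 10, 20), duration = 60,
                              seed = 3)
  expect_true(all(diff(df$rate) > 0))
  expect_true(all(diff(df$gi_cv) > 0))

  dl <- run_synchrony_draws(n_draws = 3, subset = "largest2", duration = 60,
                            seed = 11)
  ds <- run_synchrony_draws(n_draws = 3, subset = "smallest2", duration = 60,
                            seed = 11)
  expect_true(all(dl$sync_amp >= 20))
  expect_true(all(ds$sync_amp <= 12))
  expect_gt(mean(dl$pct_change), mean(ds$pct_change))
})

test_that("CSV interchange round-trips and rejects malformed input", {
  tdir <- withr::local_tempdir()
  set.seed(3)
  trains <- make_population(3, 80, 2, seed = 3)
  sp_path <- file.path(tdir, "spikes.csv")
  write_spike_csv(trains, sp_path)
  back <- read_spike_csv(sp_path, duration = 2)
  for (u in names(trains))
    expect_equal(back[[u]]$times, trains[[u]]$times, tolerance = 1e-6)

  bad <- file.path(tdir, "bad.csv")
  writeLines(c("unit_id,time_s", "a,0.5", "a,0.2"), bad)
  expect_error(read_spike_csv(bad), "line 3")

  tr_path <- file.path(tdir, "trace.csv")
  g <- convolve_train(trains[[1]], ipsg_kernel(5), dt = 0.05, duration = 0.5)
  write_trace_csv(g, tr_path)
  g2 <- read_trace_csv(tr_path)
  expect_equal(g2$values, g$values, tolerance = 1e-6)
  expect_equal(g2$dt, g$dt, tolerance = 1e-6)

  cst <- conductance_trace(rep(56, 100), dt = 0.1)
  write_trace_csv(cst, tr_path)
  expect_true(all(read_trace_csv(tr_path)$values == 56))

  w_path <- file.path(tdir, "w.csv")
  write_weights_csv(c(3, 10, 30), w_path)
  expect_identical(read_weights_csv(w_path), c(3, 10, 30))
})
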