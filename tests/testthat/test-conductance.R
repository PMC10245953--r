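test_that("kernel peak time, peak value and integral match quadrature", {
  k <- ipsg_kernel(1)
  # independent oracle: numeric optimization / quadrature of the waveform
  opt <- optimize(function(t) kernel_eval(k, t), c(0, 5), maximum = TRUE)
  expect_equal(k$peak_time, opt$maximum, tolerance = 1e-5)
  expect_equal(opt$objective, 1, tolerance = 1e-9)  # peak-normalized
  expect_equal(k$integral, integrate(function(t) kernel_eval(k, t),
                                     0, Inf)$value, tolerance = 1e-6)
  expect_equal(k$peak_time, 0.33530, tolerance = 1e-4)
  expect_equal(k$integral, 2.8589, tolerance = 1e-4)

  ke <- epsg_kernel()
  expect_equal(ke$integral, integrate(function(t) kernel_eval(ke, t),
                                      0, Inf)$value, tolerance = 1e-6)
  expect_equal(ke$integral, 0.6836, tolerance = 3e-4)

  expect_identical(kernel_eval(make_kernel(0, 0.1, 2.5, -75), 0:10),
                   rep(0, 11))
  expect_error(make_kernel(1, 2.5, 0.1, -75), "tau_rise < tau_decay")
})

test_that("convolution superposes sampled kernels exactly", {
  expect_true(all(convolve_train(spike_train(numeric(0), 1),
                                 ipsg_kernel(1))$values == 0))
  expect_error(convolve_train(spike_train(0.1, 1), ipsg_kernel(1), dt = 0.2),
               "dt")

  g <- convolve_train(spike_train(0, 0.05), ipsg_kernel(1), dt = 0.02)
  expect_equal(max(g$values), 1, tolerance = 1e-3)
  expect_equal((which.max(g$values) - 1) * 0.02, 0.34, tolerance = 1e-9)
  # grid samples equal the closed-form waveform (spike lands in bin 0)
  tt <- (seq_along(g$values) - 1) * 0.02
  expect_equal(g$values, kernel_eval(ipsg_kernel(1), tt), tolerance = 1e-12)

  # Campbell's theorem: mean of a Poisson-driven trace = rate * integral
  set.seed(8)
  tr <- generate_poisson_train(80, 300)
  g <- convolve_train(tr, ipsg_kernel(1), dt = 0.05)
  cm <- campbell_moments(ipsg_kernel(1), 80)
  expect_equal(mean(g$values), cm$mean, tolerance = 0.02)
})

test_that("trace statistics match shot-noise moments and exact identities", {
  cst <- conductance_trace(rep(3.5, 100), dt = 0.1)
  st <- trace_stats(cst)
  expect_equal(c(st$mean, st$sd, st$cv), c(3.5, 0, 0))
  expect_error(trace_stats(conductance_trace(rep(0, 10), 0.1)), "zero-mean")

  set.seed(12)
  tr <- generate_poisson_train(200, 200)
  g <- convolve_train(tr, ipsg_kernel(2), dt = 0.05)
  st <- trace_stats(g, burn_in = 0.5)
  cm <- campbell_moments(ipsg_kernel(2), 200)
  expect_equal(st$mean, cm$mean, tolerance = 0.02)
  expect_equal(st$sd^2, cm$var, tolerance = 0.05)
})

test_that("size draws hit the target total under the stated rules", {
  expect_identical(sample_sizes(size_uniform(5), 200), rep(5, 40))
  trip <- sample_sizes(size_triplet(), 200)
  expect_identical(trip, c(rep(3, 16), rep(10, 10), rep(30, 2)))
  expect_equal(sum(trip), 208)

  set.seed(2)
  draws <- replicate(300, {
    s <- sample_sizes(size_categorical(), 200)
    c(mean(s), sum(s))
  })
  expect_equal(mean(draws[1, ]), 208 / 28, tolerance = 0.05)
  expect_true(all(abs(draws[2, ] - 200) <= 0.05 * 200))

  expect_error(sample_sizes(size_pool(c(250, 300)), 200), "exceeds")

  # continuous surrogate: draws bounded, class proportions near 16:10:2
  set.seed(4)
  s <- unlist(replicate(150, sample_sizes(size_empirical(), 200),
                        simplify = FALSE))
  expect_true(all(s >= 1 & s <= 45))
  expect_equal(mean(s < 6), 16 / 28, tolerance = 0.1)
  expect_equal(mean(s > 20), 2 / 28, tolerance = 0.4)
})

test_that("amplitude corrections rescale as depression/chloride", {
  expect_equal(correct_amplitudes(172.5), 30)
  expect_equal(correct_amplitudes(0), 0)
  expect_equal(correct_amplitudes(c(1, 7, 42), 1, 1), c(1, 7, 42))
  expect_error(correct_amplitudes(5, 0, 2.3), "positive")
})

test_that("assembled inhibition is additive and scale-equivariant", {
  trains <- make_population(6, 80, 5, seed = 31)
  w <- c(3, 3, 10, 10, 30, 30)
  total <- assemble_inhibition(w, trains, dt = 0.02, duration = 5)
  g1 <- assemble_inhibition(w[1:3], trains[1:3], dt = 0.02, duration = 5)
  g2 <- assemble_inhibition(w[4:6], trains[4:6], dt = 0.02, duration = 5)
  expect_equal(total$values, g1$values + g2$values, tolerance = 1e-12)

  both <- assemble_inhibition(w, trains, dt = 0.02, duration = 5,
                              per_input = TRUE)
  expect_equal(Reduce(`+`, lapply(both$per_input, `[[`, "values")),
               total$values, tolerance = 1e-12)

  scaled <- assemble_inhibition(2 * w, trains, dt = 0.02, duration = 5)
  s1 <- trace_stats(total, 0.5); s2 <- trace_stats(scaled, 0.5)
  expect_equal(s2$mean, 2 * s1$mean, tolerance = 1e-12)
  expect_equal(s2$sd, 2 * s1$sd, tolerance = 1e-12)
  expect_equal(s2$cv, s1$cv, tolerance = 1e-12)

  expect_error(assemble_inhibition(c(1, 2), trains[1], dt = 0.02), "per weight")
})

test_that("fewer, larger inputs raise the conductance CV at fixed total", {
  cvs <- vapply(c(2.5, 5, 10, 20, 40), function(sz) {
    n <- 200 / sz
    trains <- make_population(n, 100, 20, seed = 77 + sz)
    trace_stats(assemble_inhibition(rep(sz, n), trains, dt = 0.05,
                                    duration = 20), 1)$cv
  }, numeric(1))
  expect_true(all(diff(cvs) > 0))
})

test_that("synchronized equal inputs equal one scaled input, bitwise", {
  specs <- setNames(rep(list(isi_lognormal(80)), 5), paste0("u", 1:5))
  sync <- assign_synchrony(specs, list(names(specs)), 5, seed = 13)
  lone <- assign_synchrony(specs[1], list(), 5, seed = 13)
  g_sync <- assemble_inhibition(rep(5, 5), sync, dt = 0.02, duration = 5)
  g_lone <- assemble_inhibition(25, lone, dt = 0.02, duration = 5)
  expect_identical(g_sync$values, g_lone$values)
  s1 <- trace_stats(g_sync, 0.5); s2 <- trace_stats(g_lone, 0.5)
  expect_identical(s1$cv, s2$cv)
})

test_that("excitation trace realizes the Poisson event rate", {
  expect_true(all(generate_excitation(0, 1)$values == 0))
  expect_error(generate_excitation(-10, 1), "nonnegative")
  set.seed(19)
  g <- generate_excitation(23650, 30)
  cm <- campbell_moments(epsg_kernel(), 23650)
  expect_equal(trace_stats(g, 0.5)$mean, cm$mean, tolerance = 0.02)
})
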