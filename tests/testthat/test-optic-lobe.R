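test_that("sigmoid activation matches its closed form", {
  expect_equal(sigmoid_activation(0.5), 0.5)
  expect_equal(sigmoid_activation(0), 1 / (1 + exp(0.5)))
  expect_equal(sigmoid_activation(1e4), 1, tolerance = 1e-12)
  expect_equal(sigmoid_activation(-1e4), 0, tolerance = 1e-12)
  r <- seq(-3, 9, by = 0.5)
  expect_true(all(diff(sigmoid_activation(r)) > 0))
})

test_that("lamina pools non-overlapping 3x3 blocks through the sigmoid", {
  zero <- matrix(0, 75, 75)
  expect_equal(lamina_response(zero), rep(1 / (1 + exp(0.5)), 625))
  one <- matrix(1, 75, 75)
  expect_equal(lamina_response(one), rep(1 / (1 + exp(-9 + 0.5)), 625))
  # a single bright block elevates exactly one lamina unit
  patch <- zero
  patch[4:6, 7:9] <- 1
  lam <- lamina_response(patch)
  base <- 1 / (1 + exp(0.5))
  expect_equal(sum(lam > base + 1e-9), 1)
  # permuting photoreceptors within a block leaves the response unchanged
  patch2 <- patch
  patch2[4:6, 7:9] <- matrix(sample(as.numeric(patch[4:6, 7:9])), 3, 3)
  expect_equal(lamina_response(patch2), lam)
  expect_error(lamina_response(matrix(0, 10, 10)), "75 x 75")
})

test_that("simulated LIF spiking matches the closed-form ISI", {
  p <- lif_params()
  expect_equal(lif_rate(-1, p)$rate, 0)
  expect_equal(length(lif_rate(0, p)$spikes), 0)
  # I = 16: ISI = 10 log(240/160) ms, about 4.055 ms
  sim <- lif_rate(16, p)
  isi_cf <- p$tau_m * log((p$R * 16 - p$v0) / (p$R * 16 - p$VT))
  expect_equal(isi_cf, 4.054651, tolerance = 1e-6)
  expect_equal(lif_rate_closed(16, p), 1000 / isi_cf)
  expect_lt(abs(diff(sim$spikes)[1] - isi_cf), p$dt)
  # grid of currents: relative ISI error below dt/ISI
  for (I in c(2, 5, 16, 40)) {
    isi <- p$tau_m * log((p$R * I - p$v0) / (p$R * I - p$VT))
    sim_isi <- mean(diff(lif_rate(I, p)$spikes))
    expect_lt(abs(sim_isi - isi) / isi, p$dt / isi)
  }
  # halving the duration halves the spike count (within one spike)
  p2 <- lif_params(duration = 50)
  n1 <- length(lif_rate(16, p)$spikes)
  n2 <- length(lif_rate(16, p2)$spikes)
  expect_lte(abs(n1 - 2 * n2), 1)
  expect_error(lif_rate(NaN, p), "finite")
})

test_that("medulla responses follow the weighted adapted drive", {
  lam <- lamina_response(make_pattern("plus")[101:175, 101:175])
  zero_w <- rep(0, 625)
  expect_equal(medulla_response(lam, zero_w)$rate, 0)
  w <- rep(c(1, -1), length.out = 625) * 0.1
  det <- medulla_response(lam, w, noise_scale = 0)
  expect_equal(det$rate,
               lif_rate_closed(0.5 * sum(w * lam), lif_params()))
  expect_error(medulla_response(lam[1:10], w), "match")
  # Poisson count noise is centred on the deterministic rate
  noisy <- vapply(1:1000, function(s) {
    medulla_response(lam, w, noise_scale = 1, seed = s)$rate
  }, numeric(1))
  se <- stats::sd(noisy) / sqrt(1000)
  expect_lt(abs(mean(noisy) - det$rate), 3 * se + 1e-9)
})

test_that("lobula integrates delay banks and lateral inhibition", {
  lobe <- fixture_template_lobe()
  p <- lif_params()
  scan <- make_moving_bar(90, 15, direction = 1)   # matches the template
  orth <- make_moving_bar(0, 15, direction = 1)
  r_match <- lobula_response(scan, lobe, p, noise_scale = 0)
  r_orth <- lobula_response(orth, lobe, p, noise_scale = 0)
  expect_gt(r_match$rates[1], r_orth$rates[1])
  # with Q = 0 the rate is the LIF response to the summed bank drive
  st <- lobula_response(scan, lobe, p, noise_scale = 0, stages = TRUE)
  expect_equal(st$rates,
               lif_rate_closed(lobe$gain_lo * rowSums(st$medulla), p),
               tolerance = 1e-6)
  expect_true(all(st$rates >= 0))
})

test_that("stronger lateral inhibition suppresses the population response", {
  # Doubling Q always lowers the total population rate. Individual units
  # need not be monotone: with rectified competition, stronger inhibition
  # can reallocate suppression and let a previously silenced unit rise a
  # little, so per-unit changes are only bounded, not sign-constrained.
  p <- lif_params()
  for (s in 1:20) {
    lobe <- init_visual_lobe(8, seed = s, noise_scale = 0)
    img <- make_synthetic_scene(300 + s)
    scan <- make_scan(img, "custom", 15, window_row = 10 + s,
                      start_col = 5 + s)
    r1 <- suppressWarnings(
      lobula_response(scan, lobe, p, tol = 1e-6, max_iter = 2000)$rates)
    lobe2 <- lobe
    lobe2$Q <- pmin(2 * lobe$Q, 1)
    r2 <- suppressWarnings(
      lobula_response(scan, lobe2, p, tol = 1e-6, max_iter = 2000)$rates)
    expect_lt(sum(r2), sum(r1))
    expect_lt(max(r2 - r1), 0.25 * mean(r1))
  }
})

test_that("the forward pass is reproducible at the rate level", {
  lobe <- init_visual_lobe(8, seed = 3)
  scan <- make_scan(make_pattern("plus"), "lower_half", 15)
  a <- suppressWarnings(lobula_response(scan, lobe, seed = 11))
  b <- suppressWarnings(lobula_response(scan, lobe, seed = 11))
  cc <- suppressWarnings(lobula_response(scan, lobe, seed = 12))
  expect_identical(a$rates, b$rates)
  expect_false(identical(a$rates, cc$rates))
})
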