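test_that("the sparseness index matches its closed form and bounds", {
  expect_equal(sparseness_index(rep(3, 10)), 1)
  expect_equal(sparseness_index(c(1, 0, 0, 0)), 0.25)
  expect_equal(sparseness_index(c(1, 1, 0, 0)), 0.5)
  expect_warning(si <- sparseness_index(c(0, 0, 0)), "undefined")
  expect_true(is.na(si))
  set.seed(7)
  for (i in 1:50) {
    n <- sample(2:40, 1)
    r <- abs(rnorm(n)) * rbinom(n, 1, 0.6)
    if (all(r == 0)) r[1] <- 1
    si <- sparseness_index(r)
    expect_gte(si, 1 / n - 1e-12)
    expect_lte(si, 1 + 1e-12)
  }
})

test_that("angular distance is exact, symmetric and scale-invariant", {
  expect_equal(angular_distance(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(angular_distance(c(1, 0), c(0, 1)), 90)
  expect_equal(angular_distance(c(1, 0), c(1, 1)), 45)
  expect_error(angular_distance(c(0, 0), c(1, 1)), "zero")
  set.seed(3)
  for (i in 1:20) {
    a <- rnorm(6); b <- rnorm(6)
    expect_equal(angular_distance(a, b), angular_distance(b, a))
    expect_equal(angular_distance(3.7 * a, b), angular_distance(a, b),
                 tolerance = 1e-9)
  }
})

test_that("response correlations behave like Pearson correlations", {
  set.seed(5)
  X <- matrix(rnorm(1000 * 8), 1000, 8)
  X <- cbind(X, X[, 1])  # duplicated neuron
  rc <- response_correlation(X)
  expect_equal(rc$matrix[1, 9], 1)
  expect_equal(rc$matrix, t(rc$matrix))
  expect_true(all(diag(rc$matrix) == 1))
  # independent columns: mean |off-diagonal| near the sampling floor
  rc0 <- response_correlation(X[, 1:8])
  expect_lt(rc0$mean_abs_offdiag, 0.1)
  # constant neurons are excluded with a note
  Y <- cbind(X[, 1:3], 2)
  rcY <- response_correlation(Y)
  expect_equal(attr(rcY, "excluded"), 4)
  expect_error(response_correlation(X[1, , drop = FALSE]), "two stimulus")
})

test_that("orientation tuning recovers a template unit's preference", {
  tpl <- fixture_template_lobe()
  ot <- orientation_tuning(tpl, 1, n_reps = 3, seed = 2)
  # vertical bar moving horizontally: probe angles 90 or 270
  expect_true(min(abs(ot$preferred - c(90, 270))) <= 30)
  expect_gt(ot$osi, 0.3)
  # a uniform unit has no orientation preference
  flat <- tpl
  flat$W[2, , ] <- 0.02
  ot2 <- orientation_tuning(flat, 2, n_reps = 3, seed = 2)
  expect_lt(ot2$osi, 0.1)
})

test_that("trained units gain contrast without losing orientation selectivity", {
  lobe <- fixture_trained_lobe()
  po <- suppressWarnings(population_osi(lobe, n_reps = 2, seed = 9))
  u <- which.max(po$osi)
  ot <- suppressWarnings(orientation_tuning(lobe, u, n_reps = 2, seed = 4))
  pref <- ot$preferred
  orth <- (pref + 90) %% 360
  # noise-free deterministic measurement at two contrast levels
  rates <- vapply(c(0.25, 1), function(cc) {
    c(lobula_response(make_moving_bar(pref, 15, contrast = cc), lobe,
                      noise_scale = 0)$rates[u],
      lobula_response(make_moving_bar(orth, 15, contrast = cc), lobe,
                      noise_scale = 0)$rates[u])
  }, numeric(2))
  expect_gt(rates[1, 2], rates[1, 1])          # preferred grows with contrast
  expect_lt(abs(rates[2, 2] - rates[2, 1]),
            0.1 * max(rates[1, ]) + 1e-9)      # orthogonal barely changes
})

test_that("velocity tuning is band-passed around the trained speed", {
  lobe <- fixture_trained_lobe()
  po <- suppressWarnings(population_osi(lobe, n_reps = 2, seed = 9))
  u <- which.max(po$osi)
  ot <- suppressWarnings(orientation_tuning(lobe, u, n_reps = 2, seed = 4))
  vt <- suppressWarnings(
    velocity_tuning(lobe, u, angle = ot$preferred,
                    shifts = c(0, 5, 10, 15, 30, 45, 60), n_reps = 4,
                    seed = 6))
  r <- vt$curve$rate
  expect_gt(r[vt$curve$shift == 15], r[vt$curve$shift == 0])
  expect_gt(r[vt$curve$shift == 15], r[vt$curve$shift == 60])
  if (!is.null(vt$fit)) {
    # fitted curve is non-negative and beats a flat fit
    v <- seq(0, 60, by = 1)
    pred <- vt$fit["c"] * v^(vt$fit["k"] - 1) * exp(-v / vt$fit["theta"])
    expect_true(all(pred >= 0))
    sse_fit <- sum((r - vt$fit["c"] * vt$curve$shift^(vt$fit["k"] - 1) *
                      exp(-vt$curve$shift / vt$fit["theta"]))^2)
    sse_flat <- sum((r - mean(r))^2)
    expect_lt(sse_fit, sse_flat)
  }
})
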