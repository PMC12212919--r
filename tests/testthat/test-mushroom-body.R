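test_that("Kenyon-cell activity is sparse by construction", {
  mb <- mushroom_body(16, n_kc = 2000, seed = 1)
  expect_equal(kc_response(rep(0, 16), mb)$active_fraction, 0)
  set.seed(2)
  for (i in 1:20) {
    r <- pmax(rnorm(16, 10, 8), 0)
    kc <- kc_response(r, mb)
    expect_lte(kc$active_fraction, 0.05)
  }
})

test_that("disjoint lobula codes activate weakly overlapping KC sets", {
  jac <- vapply(1:30, function(s) {
    mb <- mushroom_body(16, n_kc = 2000, seed = s)
    r1 <- c(rep(25, 8), rep(0, 8))
    r2 <- c(rep(0, 8), rep(25, 8))
    a <- kc_response(r1, mb)$active
    b <- kc_response(r2, mb)$active
    length(intersect(a, b)) / length(union(a, b))
  }, numeric(1))
  expect_lt(mean(jac), 0.5)
})

test_that("MBON output is monotone in the readout weights", {
  mb <- mushroom_body(16, n_kc = 500, seed = 4)
  kc <- kc_response(pmax(rnorm(16, 10, 8), 0), mb)
  mb0 <- mb; mb0$D[] <- 0
  expect_equal(mbon_response(kc, mb0)$rate, 0)
  rates <- vapply(c(0.5, 1, 2, 4), function(scale) {
    mbs <- mb; mbs$D <- pmin(mb$D * scale, 1)
    mbon_response(kc, mbs)$rate
  }, numeric(1))
  expect_true(all(diff(rates) >= 0))
})

test_that("the untrained MBON responds equally to both patterns", {
  lobe <- fixture_trained_lobe()
  scans <- list(make_scan(make_pattern("plus"), "lower_half", 15),
                make_scan(make_pattern("multiplication"), "lower_half", 15))
  pres <- lapply(scans, lobula_precompute, weights = lobe)
  diffs <- vapply(1:20, function(s) {
    mb <- mushroom_body(16, n_kc = 1000, seed = s)
    out <- choice_test(mb, lobe, seed = s, preA = pres[[1]], preB = pres[[2]])
    c(out$rate_a - out$rate_b, (out$rate_a + out$rate_b) / 2)
  }, numeric(2))
  expect_lt(abs(mean(diffs[1, ])), 0.1 * mean(diffs[2, ]))
})

test_that("STDP kernels match their closed forms", {
  p <- stdp_params()
  expect_equal(stdp_kernel(20, "dopamine", p), 0.01 * exp(-1))
  expect_equal(stdp_kernel(-20, "dopamine", p), -0.01 * exp(-1))
  expect_equal(stdp_kernel(1e-9, "dopamine", p), 0.01, tolerance = 1e-6)
  expect_equal(stdp_kernel(0, "dopamine", p), 0)
  dts <- c(-50, -5, 5, 50)
  oct <- stdp_kernel(dts, "octopamine", p)
  expect_true(all(oct < 0))
  expect_equal(abs(oct[1:2]), abs(oct[4:3]))
  dop <- stdp_kernel(dts, "dopamine", p)
  expect_equal(dop, -rev(dop))
})

test_that("conditioning shifts MBON responses in the reinforced direction", {
  lobe <- fixture_trained_lobe()
  scan <- make_scan(make_pattern("plus"), "lower_half", 15)
  pre <- lobula_precompute(scan, lobe)
  run_trials <- function(valence, n = 40) {
    mb <- mushroom_body(16, n_kc = 1000, seed = 11)
    rates <- numeric(n)
    for (e in seq_len(n)) {
      mb <- conditioning_trial(NULL, valence, lobe, mb,
                               seed = 1000 + e, pre = pre)
      rates[e] <- attr(mb, "mbon_rate")
    }
    list(mb = mb, rates = rates)
  }
  rew <- run_trials("reward")
  pun <- run_trials("punishment")
  expect_lt(mean(rew$rates[31:40]), mean(rew$rates[1:10]))
  expect_gt(mean(pun$rates[31:40]), mean(pun$rates[1:10]))
  expect_true(all(rew$mb$D >= 0 & rew$mb$D <= 1))
  expect_true(all(pun$mb$D >= 0 & pun$mb$D <= 1))
  # octopamine never potentiates and the projection is never touched
  mb0 <- mushroom_body(16, n_kc = 1000, seed = 11)
  expect_true(all(rew$mb$D <= mb0$D + 1e-12))
  expect_identical(rew$mb$S, mb0$S)
  # KCs silent in a trial keep their weight in that trial: replicate the
  # trial's internal draws and check the changed set
  mb1 <- conditioning_trial(NULL, "reward", lobe, mb0, seed = 77, pre = pre)
  lob <- lobula_sample(pre, lobe, seed = beevision:::sub_seed(77, "lob"))
  kc <- kc_response(lob$rates, mb0, seed = beevision:::sub_seed(77, "kc"),
                    spikes = TRUE)
  changed <- which(mb1$D != mb0$D)
  expect_true(all(changed %in% kc$active))
})

test_that("choice tests are plasticity-free and follow the learned preference", {
  lobe <- fixture_trained_lobe()
  scans <- list(make_scan(make_pattern("plus"), "lower_half", 15),
                make_scan(make_pattern("multiplication"), "lower_half", 15))
  pres <- lapply(scans, lobula_precompute, weights = lobe)
  mb <- mushroom_body(16, n_kc = 1000, seed = 2)
  # hand-craft the readout: silence the KCs pattern A recruits (across
  # several noise draws) and saturate those recruited only by pattern B;
  # such a bee must prefer A
  actives <- function(pre) {
    unique(unlist(lapply(1:5, function(s) {
      kc_response(lobula_sample(pre, lobe, seed = s)$rates, mb)$active
    })))
  }
  aA <- actives(pres[[1]])
  aB <- actives(pres[[2]])
  mb$D[aA] <- 0
  mb$D[setdiff(aB, aA)] <- 1
  d_before <- mb$D
  choices <- vapply(1:20, function(t) {
    choice_test(mb, lobe, seed = t, preA = pres[[1]], preB = pres[[2]])$choice
  }, integer(1))
  expect_gt(mean(choices == 1L), 0.8)
  expect_identical(mb$D, d_before)
})

test_that("untrained bees choose at chance over many tests", {
  lobe <- fixture_trained_lobe()
  scans <- list(make_scan(make_pattern("plus"), "lower_half", 15),
                make_scan(make_pattern("multiplication"), "lower_half", 15))
  pres <- lapply(scans, lobula_precompute, weights = lobe)
  n_correct <- 0L
  for (b in 1:10) {
    mb <- mushroom_body(16, n_kc = 1000, seed = 100 + b)
    for (t in 1:20) {
      out <- choice_test(mb, lobe, seed = b * 1000 + t,
                         preA = pres[[1]], preB = pres[[2]])
      if (out$choice == 1L) n_correct <- n_correct + 1L
    }
  }
  ci <- stats::binom.test(n_correct, 200, p = 0.5)$conf.int
  expect_true(ci[1] <= 0.5 && 0.5 <= ci[2])
})
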