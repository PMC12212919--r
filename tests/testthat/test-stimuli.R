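test_that("multiplication pattern is the plus rotated by 45 degrees", {
  pl <- make_pattern("plus")
  mu <- make_pattern("multiplication")
  rot <- rotate_image(pl, 45)
  expect_lt(mean(abs(mu - rot)), 0.02)
  expect_in_unit_interval(pl)
  expect_in_unit_interval(mu)
})

test_that("bars rotate exactly by construction and respect contrast", {
  b0 <- make_pattern("bar", angle = 0, contrast = 1)
  b90 <- make_pattern("bar", angle = 90, contrast = 1)
  # a horizontal bar has nonzero row variance only in the stroke rows
  rv <- apply(b0, 1, stats::var)
  stroke_rows <- which(apply(b0, 1, max) > 0)
  expect_true(all(rv[-stroke_rows] == 0))
  # analytic drawing: transposing flips the angle by 90 degrees exactly
  expect_lt(max(abs(t(b0)[nrow(b0):1, ] - unname(b90))), 1e-8)
  expect_equal(max(make_pattern("bar", contrast = 0.4)), 0.4)
  expect_error(make_pattern("bar", size = 100), "too small")
})

test_that("grating energy is concentrated at the requested orientation", {
  # oracle: dominant orientation of the 2-D FFT power peak
  g <- make_pattern("grating", angle = 45, sf = 3, size = 280)
  P <- Mod(stats::fft(g - mean(g)))^2
  n <- nrow(P)
  fx <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1))
  idx <- arrayInd(which.max(P[-1]) + 1L, dim(P))
  ang <- atan2(-fx[idx[1]], fx[idx[2]]) * 180 / pi
  ang <- ang %% 180
  expect_lt(min(abs(ang - 45), abs(ang - 225 %% 180)), 2)
})

test_that("synthetic scenes are reproducible, correlated and 1/f-like", {
  s1 <- make_synthetic_scene(5)
  s2 <- make_synthetic_scene(5)
  expect_identical(s1, s2)
  lag1 <- function(img) {
    stats::cor(as.numeric(img[, -1]), as.numeric(img[, -ncol(img)]))
  }
  radial_slope <- function(img) {
    n <- nrow(img)
    P <- Mod(stats::fft(img - mean(img)))^2
    fx <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1)) / n
    f <- sqrt(outer(fx^2, fx^2, "+"))
    bins <- cut(f, breaks = seq(0, 0.5, by = 1 / n))
    pm <- tapply(P, bins, mean)
    fm <- tapply(f, bins, mean)
    ok <- !is.na(pm) & fm > 2 / n & fm < 0.35 & pm > 0
    unname(stats::coef(stats::lm(log(pm[ok]) ~ log(fm[ok])))[2])
  }
  for (seed in 1:10) {
    sc <- make_synthetic_scene(seed)
    expect_in_unit_interval(sc)
    expect_gt(lag1(sc), 0.8)
    sh <- shuffle_image(sc, seed + 100)
    expect_lt(abs(lag1(sh)), 0.1)
    sl <- radial_slope(sc)
    expect_gt(sl, -2.5)
    expect_lt(sl, -1.0)
  }
})

test_that("pixel shuffling preserves the intensity histogram exactly", {
  sc <- make_synthetic_scene(3)
  sh <- shuffle_image(sc, 9)
  expect_identical(sort(as.numeric(sh)), sort(as.numeric(sc)))
  expect_equal(mean(sh), mean(sc))
  expect_equal(stats::var(as.numeric(sh)), stats::var(as.numeric(sc)))
  expect_false(identical(sh, sc))
})

test_that("scan extraction follows the shift arithmetic", {
  pl <- make_pattern("plus")
  s0 <- make_scan(pl, "lower_half", 0)
  expect_length(s0$patches, 5)
  for (k in 2:5) expect_identical(s0$patches[[k]], s0$patches[[1]])
  # direct-slicing oracle on a custom window
  s15 <- make_scan(pl, "custom", 15, window_row = 100, start_col = 20)
  for (k in 1:5) {
    expect_identical(s15$patches[[k]],
                     pl[100:174, (20 + 15 * (k - 1)):(94 + 15 * (k - 1))])
  }
  # lower_half places the window directly below the midline
  lh <- make_scan(pl, "lower_half", 15)
  expect_equal(unname(lh$window["row"]), nrow(pl) %/% 2 + 1)
  expect_error(make_scan(pl[1:80, ], "lower_half", 15), "rows")
  expect_error(make_scan(pl[, 1:100], "whole", 15), "narrow")
})

test_that("mirrored right-to-left scans equal reversed left-to-right scans", {
  img <- make_synthetic_scene(8, size = 300)[1:201, 1:281]  # odd width, symmetric fit
  fwd <- make_scan(img, "whole", 15, direction = "left_to_right")
  mir <- img[, ncol(img):1]
  bwd <- make_scan(mir, "whole", 15, direction = "right_to_left")
  # the bee sees the same temporal sequence, each view mirrored
  for (k in 1:5) {
    expect_equal(bwd$patches[[k]],
                 fwd$patches[[k]][, 75:1],
                 tolerance = 1e-12)
  }
})

test_that("moving bars translate orthogonally to their axis", {
  expect_true(all(make_moving_bar(30, 15, contrast = 0)$patches[[1]] == 0))
  mb <- make_moving_bar(90, shift_px = 10)  # vertical bar moving rightwards
  # frames shift by +10 columns: b[i + lag] aligns with a[i] at lag = +10
  # cross-correlation oracle: column displacement between frames
  for (k in 1:4) {
    a <- colSums(mb$patches[[k]])
    b <- colSums(mb$patches[[k + 1]])
    lags <- -20:20
    cc <- vapply(lags, function(l) {
      ia <- seq_len(75)
      ib <- ia + l
      ok <- ib >= 1 & ib <= 75
      sum(a[ia[ok]] * b[ib[ok]])
    }, numeric(1))
    expect_equal(lags[which.max(cc)], 10)
  }
  # a bar at angle + 180 with opposite motion is the identical stimulus
  m1 <- make_moving_bar(30, 15, direction = 1)
  m2 <- make_moving_bar(210, 15, direction = -1)
  for (k in 1:5) expect_equal(m1$patches[[k]], m2$patches[[k]], tolerance = 1e-12)
})

test_that("distal view shrinks the pattern onto a padded canvas", {
  pl <- make_pattern("plus")
  dv <- distal_view(pl, 5)
  expect_equal(dim(dv), dim(pl))
  expect_equal(sum(dv > 0.05), sum(pl > 0.05) / 25, tolerance = 0.3)
  expect_equal(sum(dv) * 25, sum(pl), tolerance = 1e-8)
})
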