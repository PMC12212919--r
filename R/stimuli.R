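# Stimulus generators: behavioural test patterns, synthetic naturalistic
# scenes, pixel-shuffled controls, five-patch scan sequences and moving-bar
# probes.
#
# Conventions: images are numeric matrices with intensities in [0, 1],
# indexed [row, col] with the origin at the top-left. Geometry is computed
# in centred coordinates with x increasing rightwards (columns) and y
# increasing upwards, so an angle of 0 degrees is a horizontal bar and
# 90 degrees a vertical one. The scan axis is always the column axis.

PATCH_SIDE <- 75L   # photoreceptor window is 75 x 75 pixels
SCAN_LEN <- 5L      # a scan is five sequential patches

# soft-edged coverage of a centred bar: 1 inside, 0 outside, `feather`-px
# linear ramp at the stroke boundary
.bar_coverage <- function(x, y, angle, length, width, feather = 1) {
  th <- angle * pi / 180
  along <- x * cos(th) + y * sin(th)
  perp <- -x * sin(th) + y * cos(th)
  clip((width / 2 + feather / 2 - abs(perp)) / feather, 0, 1) *
    clip((length / 2 + feather / 2 - abs(along)) / feather, 0, 1)
}

.centered_xy <- function(nrow, ncol) {
  cx <- (ncol + 1) / 2
  cy <- (nrow + 1) / 2
  list(x = matrix(rep(seq_len(ncol) - cx, each = nrow), nrow = nrow),
       y = matrix(rep(cy - seq_len(nrow), times = ncol), nrow = nrow))
}

#' Generate a behavioural test pattern
#'
#' Draws the achromatic patterns used in bee discrimination experiments on a
#' uniform background: a right-angled `plus`, its 45-degree rotation
#' (`multiplication`), a single `bar` at an arbitrary angle, a sinusoidal
#' `grating`, an Archimedean `spiral` (mirrored by `handedness`), and a
#' `two_bar_quadrant` pattern with one oriented bar in each lower quadrant.
#' Strokes are bright on a dark background and drawn analytically (distance
#' to the stroke axis), so a bar at angle `a + 90` is the exact 90-degree
#' rotation of the bar at angle `a`.
#'
#' @param kind one of `"plus"`, `"multiplication"`, `"bar"`, `"grating"`,
#'   `"spiral"`, `"two_bar_quadrant"`.
#' @param angle stroke (or grating) orientation in degrees.
#' @param contrast stroke-background intensity difference in `[0, 1]`.
#' @param size canvas side in pixels. The default admits a five-patch scan
#'   at up to a 45-pixel shift and a lower-left-quadrant scan at 15 pixels.
#' @param sf grating spatial frequency, cycles per 75-pixel patch.
#' @param handedness +1 or -1, spiral chirality.
#' @param stroke_frac stroke width as a fraction of the canvas side.
#' @param length_frac stroke length as a fraction of the canvas side. The
#'   defaults draw the pattern over a ~150-pixel extent, so the 75-pixel
#'   eye window at the reference viewing distance covers the pattern's
#'   lower half exactly when scanning below the midline.
#' @param angles two bar angles for `two_bar_quadrant` (lower-left,
#'   lower-right).
#' @return An intensity matrix in `[0, 1]` with attributes `kind` and
#'   `params`.
#' @export
#' @examples
#' p <- make_pattern("plus")
#' m <- make_pattern("multiplication")
make_pattern <- function(kind = c("plus", "multiplication", "bar", "grating",
                                  "spiral", "two_bar_quadrant"),
                         angle = 0, contrast = 1, size = 280, sf = 3,
                         handedness = 1, stroke_frac = 0.085,
                         length_frac = 0.535, angles = c(-45, 45)) {
  kind <- match.arg(kind)
  if (size < PATCH_SIDE + (SCAN_LEN - 1) * 15) {
    stop("canvas too small for a five-patch scan", call. = FALSE)
  }
  stopifnot(contrast >= 0, contrast <= 1)
  g <- .centered_xy(size, size)
  w <- stroke_frac * size
  len <- length_frac * size
  cov <- switch(kind,
    plus = pmax(.bar_coverage(g$x, g$y, 0, len, w),
                .bar_coverage(g$x, g$y, 90, len, w)),
    multiplication = pmax(.bar_coverage(g$x, g$y, 45, len, w),
                          .bar_coverage(g$x, g$y, 135, len, w)),
    bar = .bar_coverage(g$x, g$y, angle, len, w),
    grating = {
      th <- angle * pi / 180
      u <- g$x * cos(th) + g$y * sin(th)
      0.5 + 0.5 * sin(2 * pi * sf * u / PATCH_SIDE)
    },
    spiral = {
      r <- sqrt(g$x^2 + g$y^2)
      phi <- atan2(g$y, g$x)
      v <- cos(2 * pi * r / 40 - sign(handedness) * phi)
      clip((v - 0.3) / 0.2, 0, 1) * clip(len / 2 + 0.5 - r, 0, 1)
    },
    two_bar_quadrant = {
      q <- size / 4
      pmax(.bar_coverage(g$x + q, g$y + q, angles[1], 0.35 * size, w),
           .bar_coverage(g$x - q, g$y + q, angles[2], 0.35 * size, w))
    })
  img <- clip(contrast * cov, 0, 1)
  attr(img, "kind") <- kind
  attr(img, "params") <- list(angle = angle, contrast = contrast, sf = sf,
                              handedness = handedness)
  img
}

#' Rotate an image about its centre
#'
#' Inverse-mapped bilinear interpolation; samples falling outside the
#' source take the `background` value and the result is clipped to `[0,1]`.
#'
#' @param img intensity matrix.
#' @param degrees anticlockwise rotation angle.
#' @param background fill value for out-of-canvas samples.
#' @return Rotated intensity matrix of the same dimensions.
#' @export
rotate_image <- function(img, degrees, background = 0) {
  n <- nrow(img); m <- ncol(img)
  g <- .centered_xy(n, m)
  th <- -degrees * pi / 180   # inverse rotation
  xs <- g$x * cos(th) - g$y * sin(th)
  ys <- g$x * sin(th) + g$y * cos(th)
  cc <- xs + (m + 1) / 2      # back to matrix coordinates
  rr <- (n + 1) / 2 - ys
  r0 <- floor(rr); c0 <- floor(cc)
  fr <- rr - r0; fc <- cc - c0
  at <- function(ri, ci) {
    ok <- ri >= 1 & ri <= n & ci >= 1 & ci <= m
    out <- rep(background, length(ri))
    out[ok] <- img[cbind(ri[ok], ci[ok])]
    out
  }
  v <- (1 - fr) * (1 - fc) * at(r0, c0) + (1 - fr) * fc * at(r0, c0 + 1) +
    fr * (1 - fc) * at(r0 + 1, c0) + fr * fc * at(r0 + 1, c0 + 1)
  matrix(clip(v, 0, 1), n, m)
}

#' Generate a synthetic naturalistic scene
#'
#' Stands in for photographs of flowers and natural scenes: a 1/f-type
#' random field (strong spatial correlations, power-law spectrum) with
#' superposed soft-edged strokes at random orientations, emulating the
#' oriented edge structure of natural images. Reproducible given `seed`.
#'
#' @param seed integer seed.
#' @param size scene side in pixels (at least 200).
#' @param edge_density number of superposed oriented strokes.
#' @param correlation_scale correlation length of the background field in
#'   pixels (low-frequency cutoff of the 1/f spectrum).
#' @return An intensity matrix in `[0, 1]` with attribute `seed`.
#' @export
make_synthetic_scene <- function(seed, size = 256, edge_density = 30,
                                 correlation_scale = 20) {
  stopifnot(size >= 200)
  with_seed(seed, {
    # 1/f-type background: shape white Gaussian noise in the Fourier
    # domain; the 1.4 amplitude exponent gives a power-spectrum slope
    # near -2.3 on log-log axes, within the range typical of natural
    # scenes, and lag-1 pixel correlations above 0.8
    fx <- c(0:(size %/% 2), -((size - size %/% 2 - 1):1)) / size
    f <- sqrt(outer(fx^2, fx^2, "+"))
    amp <- 1 / (f + 1 / (2 * correlation_scale))^1.4
    wn <- matrix(stats::rnorm(size^2), size, size)
    field <- Re(stats::fft(stats::fft(wn) * amp, inverse = TRUE)) / size^2
    field <- field / stats::sd(field)
    # oriented strokes
    g <- .centered_xy(size, size)
    edges <- matrix(0, size, size)
    for (i in seq_len(edge_density)) {
      cx <- stats::runif(1, -size / 2, size / 2)
      cy <- stats::runif(1, -size / 2, size / 2)
      a <- stats::runif(1, 0, 180)
      len <- stats::runif(1, 40, 120)
      w <- stats::runif(1, 3, 9)
      s <- sample(c(-1, 1), 1) * stats::runif(1, 0.8, 1.6)
      edges <- edges + s * .bar_coverage(g$x - cx, g$y - cy, a, len, w,
                                         feather = 6)
    }
    img <- field + edges
    # natural photographs vary widely in overall brightness; draw a
    # per-scene mean level rather than fixing all scenes to mid-grey
    # (kept below mid-grey on average: the lamina sigmoid saturates for
    # bright fields, as photoreceptor pooling does in strong light)
    level <- stats::runif(1, 0.3, 0.55)
    img <- clip((img - mean(img)) / (4 * stats::sd(img)) + level, 0, 1)
    attr(img, "seed") <- seed
    img
  })
}

#' Destroy the spatial structure of an image by pixel shuffling
#'
#' Returns an image with exactly the same multiset of pixel values but
#' randomly permuted positions, removing spatial correlations while
#' preserving the intensity histogram.
#'
#' @param img intensity matrix.
#' @param seed integer seed for the permutation.
#' @return Shuffled intensity matrix of the same dimensions.
#' @export
shuffle_image <- function(img, seed = NULL) {
  out <- with_seed(seed, matrix(sample(as.numeric(img)), nrow(img), ncol(img)))
  attributes(out)$dim <- dim(img)
  out
}

#' Extract a five-patch scan sequence from an image
#'
#' Emulates a lateral scanning flight: five sequential 75 x 75 windows
#' displaced by `shift_px` columns between consecutive patches. The shift
#' is the speed proxy (0 px is hovering: all patches identical; 15 px
#' corresponds to 0.1 m/s, 45 px to 0.3 m/s). `region` places the window:
#' `whole` centres it on the image, `lower_half` places the 75-row window
#' directly below the midline (the lower half of a pattern drawn at the
#' default ~150-px extent), `lower_left` additionally confines the
#' traverse to the left half of the columns, and `custom` uses
#' `window_row` / `start_col` directly (1-based top-left corner of the
#' first patch).
#'
#' @param img intensity matrix.
#' @param region `"whole"`, `"lower_half"`, `"lower_left"` or `"custom"`.
#' @param shift_px non-negative integer column shift per patch.
#' @param direction `"left_to_right"` or `"right_to_left"`.
#' @param window_row top row of the window (for `region = "custom"`).
#' @param start_col leftmost column of the traverse (for `"custom"`).
#' @return An object of class `scan_sequence`: a list with `patches`
#'   (five 75 x 75 matrices), `shift_px`, `region` and `direction`.
#' @export
#' @examples
#' sc <- make_scan(make_pattern("plus"), region = "lower_half", shift_px = 15)
#' length(sc$patches)
make_scan <- function(img, region = c("whole", "lower_half", "lower_left",
                                      "custom"),
                      shift_px = 15,
                      direction = c("left_to_right", "right_to_left"),
                      window_row = NULL, start_col = NULL) {
  region <- match.arg(region)
  direction <- match.arg(direction)
  stopifnot(shift_px >= 0, shift_px == round(shift_px))
  H <- nrow(img); W <- ncol(img)
  span <- PATCH_SIDE + (SCAN_LEN - 1) * shift_px
  rows <- switch(region,
    whole = (H - PATCH_SIDE) %/% 2 + 1,
    lower_half = H %/% 2 + 1,   # window starts right below the midline
    lower_left = H %/% 2 + 1,
    custom = window_row)
  cols <- switch(region,
    whole = c(1L, W),
    lower_half = c(1L, W),
    lower_left = c(1L, W %/% 2),
    custom = c(start_col, start_col + span - 1L))
  if (is.null(rows) || rows < 1 || rows + PATCH_SIDE - 1 > H) {
    stop("scan window exceeds image rows", call. = FALSE)
  }
  if (cols[2] - cols[1] + 1 < span || cols[1] < 1 || cols[2] > W) {
    stop("image too narrow for the requested scan", call. = FALSE)
  }
  base <- cols[1] + (cols[2] - cols[1] + 1 - span) %/% 2
  starts <- if (direction == "left_to_right") {
    base + (seq_len(SCAN_LEN) - 1L) * shift_px
  } else {
    base + (SCAN_LEN - seq_len(SCAN_LEN)) * shift_px
  }
  patches <- lapply(starts, function(s) {
    img[rows:(rows + PATCH_SIDE - 1L), s:(s + PATCH_SIDE - 1L), drop = FALSE]
  })
  structure(list(patches = patches, shift_px = as.integer(shift_px),
                 region = region, direction = direction,
                 window = c(row = rows, col = base)),
            class = "scan_sequence")
}

#' @export
print.scan_sequence <- function(x, ...) {
  cat(sprintf("scan_sequence: %d patches of %dx%d, shift %d px, %s, %s\n",
              length(x$patches), nrow(x$patches[[1]]), ncol(x$patches[[1]]),
              x$shift_px, x$region, x$direction))
  invisible(x)
}

#' Moving-bar probe sequence
#'
#' Five frames of a bar translating across the 75 x 75 visual field in the
#' direction orthogonal to its axis (a bar at `angle` moves along
#' `angle - 90` degrees, so a vertical bar with `direction = +1` moves
#' rightwards). Displacement per frame is `shift_px`; the middle frame is
#' centred.
#'
#' @param angle bar orientation in degrees.
#' @param shift_px displacement per frame (pixels).
#' @param contrast bar-background intensity difference in `[0, 1]`.
#' @param direction +1 or -1, sense of motion along the orthogonal axis.
#' @param bar_length bar length in pixels.
#' @param bar_width bar width in pixels.
#' @return A `scan_sequence` of five 75 x 75 frames.
#' @export
make_moving_bar <- function(angle, shift_px = 15, contrast = 1,
                            direction = 1, bar_length = 60, bar_width = 12) {
  stopifnot(contrast >= 0, contrast <= 1, shift_px >= 0)
  g <- .centered_xy(PATCH_SIDE, PATCH_SIDE)
  th <- (angle - 90) * pi / 180  # motion axis
  frames <- lapply(seq_len(SCAN_LEN), function(k) {
    d <- sign(direction) * (k - (SCAN_LEN + 1) / 2) * shift_px
    clip(contrast * .bar_coverage(g$x - d * cos(th), g$y - d * sin(th),
                                  angle, bar_length, bar_width), 0, 1)
  })
  structure(list(patches = frames, shift_px = as.integer(shift_px),
                 region = "custom", direction = if (direction >= 0)
                   "left_to_right" else "right_to_left",
                 window = c(row = 1L, col = 1L)),
            class = "scan_sequence")
}

#' Far-distance (distal) view of a pattern
#'
#' Emulates viewing a pattern from five times the reference distance: the
#' pattern subtends a fifth of the visual angle, implemented by
#' block-averaging the image down by `factor` and padding it centrally
#' with the `background` level to the original canvas size.
#'
#' @param img intensity matrix whose sides are divisible by `factor`.
#' @param factor linear shrink factor.
#' @param background padding intensity.
#' @return Intensity matrix of the original size.
#' @export
distal_view <- function(img, factor = 5, background = 0) {
  H <- nrow(img); W <- ncol(img)
  stopifnot(H %% factor == 0, W %% factor == 0)
  h <- H %/% factor; w <- W %/% factor
  small <- matrix(0, h, w)
  ri <- (seq_len(H) - 1L) %/% factor + 1L
  ci <- (seq_len(W) - 1L) %/% factor + 1L
  small <- rowsum(t(rowsum(img, ri)), ci) / factor^2
  small <- t(small)
  out <- matrix(background, H, W)
  r0 <- (H - h) %/% 2; c0 <- (W - w) %/% 2
  out[r0 + seq_len(h), c0 + seq_len(w)] <- small
  out
}

#' Write an intensity image as an 8-bit grayscale PNG
#'
#' @param img intensity matrix in `[0, 1]`.
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_image_png <- function(img, path) {
  if (!requireNamespace("png", quietly = TRUE)) {
    stop("the 'png' package is required for PNG export", call. = FALSE)
  }
  stopifnot_image(img)
  png::writePNG(img, path)
  invisible(path)
}
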