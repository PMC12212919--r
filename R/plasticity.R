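# Non-associative learning in the visual lobe: Oja's rule on the
# feed-forward tensor W, a symmetric rate-based inhibitory-STDP rule on
# the lateral matrix Q, the scan-driven training loop, and receptive-field
# extraction.

#' Oja update for one feed-forward weight vector
#'
#' Hebbian learning with multiplicative normalisation:
#' `dW = gamma * r_me * (r_la - r_me * W)`. The unique fixed point for
#' stationary activities is `W = r_la / r_me`; for a linear unit driven by
#' zero-mean inputs the rule converges to the leading eigenvector of the
#' input covariance. The returned value is the increment only; callers
#' apply it and clip weights to `[-1, 1]`.
#'
#' @param W_row current weight vector (lamina inputs of one medulla bank).
#' @param r_la presynaptic lamina activity vector (same length).
#' @param r_me scalar postsynaptic medulla rate.
#' @param gamma learning rate.
#' @return The weight increment, same shape as `W_row`.
#' @export
oja_update <- function(W_row, r_la, r_me, gamma) {
  stopifnot(length(W_row) == length(r_la), gamma >= 0)
  gamma * r_me * (r_la - r_me * W_row)
}

#' Symmetric inhibitory-STDP update for the lateral matrix
#'
#' `dQ[i, j] = eta * (r[i] * r[j] - alpha)` for `i != j`, zero on the
#' diagonal. Each lobula unit has a one-to-one inhibitory partner whose
#' activity equals its own, so the rule drives every pairwise co-activity
#' towards the target `alpha`: persistently co-active pairs grow mutual
#' inhibition, silent pairs let it decay. Callers apply the increment and
#' clip `Q` to `[0, 1]`.
#'
#' @param Q square lateral inhibition matrix (zero diagonal).
#' @param r_lo lobula rate vector.
#' @param eta learning rate.
#' @param alpha target co-activity (spikes/s)^2.
#' @return The increment matrix, zero on the diagonal.
#' @export
istdp_update <- function(Q, r_lo, eta, alpha) {
  stopifnot(nrow(Q) == ncol(Q), nrow(Q) == length(r_lo), eta >= 0)
  dQ <- eta * (outer(r_lo, r_lo) - alpha)
  diag(dQ) <- 0
  dQ
}

#' Train the visual lobe by scanning scenes
#'
#' The exposure loop of non-associative learning. Each step samples a
#' scene and a valid 75-row window uniformly at random (scan direction
#' alternates left/right), extracts a five-patch scan at the 15-px shift,
#' and computes the adapted lamina signal of every patch (each lamina
#' unit's activity minus its sweep-average: the phasic lamina reports
#' changes about its adaptation level, so the learning signal carries no
#' sustained-luminance offset).
#'
#' The feed-forward tensor is updated by Oja's Hebbian rule in its
#' multi-unit (principal-subspace) form: writing `x` for the concatenated
#' five-bank contrast signal and `y = W x` for the linear population
#' response, unit `i` receives
#' `dW_i = gamma * y_i * (x - sum_{j <= i} y_j W_j)`.
#' The self-term `j = i` is exactly the single-unit rule implemented by
#' [oja_update()]; the additional `j < i` terms subtract the components
#' already captured by other units, so the population spans the leading
#' principal subspace of the scanned input instead of collapsing onto one
#' direction. Simultaneously the lateral inhibitory matrix follows the
#' symmetric iSTDP rule of [istdp_update()], driven by the rectified
#' co-activities `max(y, 0)`: pairs co-active beyond the target `alpha`
#' grow mutual inhibition, silent pairs let it decay.
#'
#' Weights are clipped to `[-1, 1]` (`W`) and `[0, 1]` (`Q`) after every
#' update; training stops when the largest absolute weight change over a
#' sliding window of `cfg$window` scans falls below `cfg$convergence_eps`,
#' or after `cfg$n_patches` scans.
#'
#' @param scenes a list of scene intensity matrices (e.g. from
#'   [make_synthetic_scene()]).
#' @param cfg a [learning_config()] object.
#' @param lif a [lif_params()] object (kept for interface symmetry; the
#'   learning signal is the analog lamina activity).
#' @param lobe optional initial `visual_lobe_weights`; by default a fresh
#'   initialisation with `n_lobula` units seeded from `cfg$seed`.
#' @param n_lobula lobula population size when `lobe` is not supplied.
#' @return The trained `visual_lobe_weights`, with a `history` data frame
#'   (per-window max `|dW|`, max `|dQ|`, mean linear response, sparseness
#'   index of the rectified response) and `converged` flag attached.
#' @export
train_visual_lobe <- function(scenes, cfg = learning_config(),
                              lif = lif_params(), lobe = NULL,
                              n_lobula = 50) {
  stopifnot(length(scenes) >= 1, inherits(cfg, "learning_config"))
  if (is.null(lobe)) {
    lobe <- init_visual_lobe(n_lobula = n_lobula, seed = cfg$seed)
  }
  n <- lobe$n_lobula
  # flat n x 3125 view of W (banks concatenated) for the subspace update
  W3 <- matrix(aperm(lobe$W, c(1, 3, 2)), nrow = n)
  if (!isTRUE(lobe$trained) && cfg$gamma > 0) {
    # the rule is self-normalising; rescaling the white-noise start to
    # the equilibrium norm skips the long saturated transient it would
    # otherwise spend shrinking the initial weights
    W3 <- W3 / sqrt(rowSums(W3^2))
  }
  Q <- lobe$Q
  Lmask <- lower.tri(matrix(0, n, n), diag = TRUE)
  ycap <- 30  # caps transients while the initial weight norm relaxes
  hist_rows <- list()
  win_dw <- rep(Inf, cfg$window)
  win_dq <- rep(Inf, cfg$window)
  rate_acc <- 0
  si_acc <- 0
  si_n <- 0
  converged <- FALSE
  scans_run <- 0L
  with_seed(cfg$seed, {
    for (step in seq_len(cfg$n_patches)) {
      img <- scenes[[sample.int(length(scenes), 1L)]]
      H <- nrow(img); W_img <- ncol(img)
      span <- PATCH_SIDE + (SCAN_LEN - 1L) * 15L
      row0 <- sample.int(H - PATCH_SIDE + 1L, 1L)
      col0 <- sample.int(W_img - span + 1L, 1L)
      dirn <- if (step %% 2L == 0L) "right_to_left" else "left_to_right"
      scan <- make_scan(img, region = "custom", shift_px = 15,
                        direction = dirn, window_row = row0,
                        start_col = col0)
      lam <- vapply(scan$patches, lamina_response, numeric(LAMINA_N))
      # phasic lamina: banks carry deviations from the sweep average,
      # exactly as in the inference pass
      x <- as.numeric(lam - rowMeans(lam))
      y <- clip(as.numeric(W3 %*% x), -ycap, ycap)
      dW <- cfg$gamma * (outer(y, x) - (Lmask * outer(y, y)) %*% W3)
      Wnew <- clip(W3 + dW, -1, 1)
      max_dw <- max(abs(Wnew - W3))
      W3 <- Wnew
      yp <- pmax(y, 0)
      max_dq <- 0
      if (!cfg$freeze_q) {
        dQ <- istdp_update(Q, yp, cfg$eta, cfg$alpha)
        Qnew <- clip(Q + dQ, 0, 1)
        diag(Qnew) <- 0
        max_dq <- max(abs(Qnew - Q))
        Q <- Qnew
      }
      scans_run <- step
      slot <- ((step - 1L) %% cfg$window) + 1L
      win_dw[slot] <- max_dw
      win_dq[slot] <- max_dq
      rate_acc <- rate_acc + mean(y)
      if (any(yp > 0)) {
        si_acc <- si_acc + sparseness_index(yp)
        si_n <- si_n + 1L
      }
      if (step %% cfg$window == 0L) {
        hist_rows[[length(hist_rows) + 1L]] <- data.frame(
          scan = step, max_dw = max(win_dw), max_dq = max(win_dq),
          mean_response = rate_acc / cfg$window,
          sparseness = if (si_n > 0) si_acc / si_n else NA_real_)
        rate_acc <- 0; si_acc <- 0; si_n <- 0L
        if (max(win_dw, win_dq) < cfg$convergence_eps) {
          converged <- TRUE
          break
        }
      }
    }
  })
  lobe$W <- aperm(array(W3, dim = c(n, LAMINA_N, N_DELAYS)), c(1, 3, 2))
  lobe$Q <- Q
  lobe$trained <- TRUE
  lobe$converged <- converged
  lobe$scans_run <- scans_run
  lobe$history <- do.call(rbind, hist_rows)
  lobe$config <- cfg
  lobe
}

#' Extract the spatiotemporal receptive field of a lobula unit
#'
#' Returns the five delay slices of unit `i`'s lamina weights, each
#' reshaped to the 25 x 25 lamina grid. Signs are preserved (positive =
#' excitatory, negative = inhibitory); an oriented on/off structure that
#' drifts across slices indicates orientation and direction selectivity.
#'
#' @param weights a `visual_lobe_weights` object.
#' @param i lobula unit index.
#' @return An object of class `receptive_field`: a list of five 25 x 25
#'   matrices (`slices`) plus the unit index.
#' @export
receptive_field <- function(weights, i) {
  stopifnot(inherits(weights, "visual_lobe_weights"))
  if (i < 1 || i > weights$n_lobula) {
    stop("lobula unit index out of range", call. = FALSE)
  }
  slices <- lapply(seq_len(N_DELAYS), function(k) {
    matrix(weights$W[i, k, ], 25, 25)
  })
  structure(list(slices = slices, unit = i), class = "receptive_field")
}

#' Tile a population's receptive fields into one image
#'
#' Concatenates the five delay slices of each unit horizontally and stacks
#' units in a grid, rescaled to `[0, 1]` for export with
#' [write_image_png()].
#'
#' @param weights a `visual_lobe_weights` object.
#' @param ncol_units units per grid row.
#' @return A single intensity matrix.
#' @export
rf_mosaic <- function(weights, ncol_units = 10) {
  n <- weights$n_lobula
  rows <- ceiling(n / ncol_units)
  tile_h <- 26L; tile_w <- 26L * N_DELAYS
  out <- matrix(NA_real_, rows * tile_h, ncol_units * tile_w)
  rng <- max(abs(weights$W))
  for (i in seq_len(n)) {
    rf <- receptive_field(weights, i)
    strip <- do.call(cbind, lapply(rf$slices, function(s) {
      cbind(rbind(s / (2 * rng) + 0.5, 0), 0)
    }))
    r0 <- ((i - 1) %/% ncol_units) * tile_h
    c0 <- ((i - 1) %% ncol_units) * tile_w
    out[r0 + seq_len(tile_h), c0 + seq_len(tile_w)] <- strip
  }
  out[is.na(out)] <- 0.5
  out
}
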