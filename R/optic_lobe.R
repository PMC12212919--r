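# Forward model of the optic lobe: 75x75 photoreceptors -> 625 lamina
# neurons (non-overlapping 3x3 pooling + sigmoid) -> leaky integrate-and-
# fire medulla banks -> delay-aligned lobula units with lateral inhibition.
#
# Delay alignment is implemented by buffering: the five medulla banks of a
# lobula unit are each driven by one patch of the scan, and their rates are
# summed at the final instant, so the lobula integrates the whole sweep at
# a single synchronised time point.

LAMINA_N <- 625L  # 25 x 25 lamina grid
N_DELAYS <- 5L    # medulla banks per lobula unit (one per patch)

#' Sigmoidal activation of a lamina neuron
#'
#' `f(r) = A0 / (1 + exp(m r + b))`; with the default parameters
#' (`A0 = 1`, `m = -1`, `b = 0.5`) the function is strictly increasing and
#' `f(0.5) = 0.5`.
#'
#' @param r summed photoreceptor input (vectorised).
#' @param p a [sigmoid_params()] object.
#' @return Activity values in `(0, A0)`.
#' @export
sigmoid_activation <- function(r, p = sigmoid_params()) {
  p$A0 / (1 + exp(p$m * r + p$b))
}

#' Lamina response to a photoreceptor patch
#'
#' Each of the 625 lamina neurons pools a non-overlapping 3 x 3 block of
#' photoreceptors (summed intensities) and passes the sum through the
#' sigmoid activation.
#'
#' @param patch 75 x 75 intensity matrix in `[0, 1]`.
#' @param p a [sigmoid_params()] object.
#' @return Numeric vector of length 625 (25 x 25 grid, column-major).
#' @export
lamina_response <- function(patch, p = sigmoid_params()) {
  if (!is.matrix(patch) || nrow(patch) != 75 || ncol(patch) != 75) {
    stop("photoreceptor patch must be 75 x 75", call. = FALSE)
  }
  idx <- (seq_len(75L) - 1L) %/% 3L + 1L
  pooled <- t(rowsum(t(rowsum(patch, idx)), idx))  # 25 x 25 block sums
  as.numeric(sigmoid_activation(pooled, p))
}

#' Closed-form LIF firing rate for a constant current
#'
#' For `R I > VT` the interspike interval of the leaky integrate-and-fire
#' neuron is `ISI = tau_m log((R I - v0) / (R I - VT))` ms and the rate is
#' `1000 / ISI` spikes/s; subthreshold currents give zero. Used for fast
#' rate-level forward passes; [lif_rate()] integrates the same dynamics
#' explicitly.
#'
#' @param I constant input current (vectorised).
#' @param p a [lif_params()] object.
#' @return Firing rate(s) in spikes/s.
#' @export
lif_rate_closed <- function(I, p = lif_params()) {
  drive <- p$R * I
  out <- numeric(length(I))
  supra <- is.finite(drive) & drive > p$VT
  out[supra] <- 1000 / (p$tau_m * log((drive[supra] - p$v0) /
                                        (drive[supra] - p$VT)))
  out
}

#' Simulated LIF response to a constant current
#'
#' Forward-Euler integration of `tau_m du/dt = -u + R I` from `u(0) = v0`,
#' with spike-and-reset to `v0` at threshold `VT`. The simulated
#' interspike interval matches the closed form of [lif_rate_closed()] to
#' within one integration step.
#'
#' @param I constant input current.
#' @param p a [lif_params()] object.
#' @return A list with `rate` (spikes/s over `p$duration`) and `spikes`
#'   (spike times, ms).
#' @export
lif_rate <- function(I, p = lif_params()) {
  if (!is.finite(I)) stop("input current must be finite", call. = FALSE)
  n <- ceiling(p$duration / p$dt)
  u <- p$v0
  spikes <- numeric(0)
  drive <- p$R * I
  k <- p$dt / p$tau_m
  for (i in seq_len(n)) {
    u <- u + k * (drive - u)
    if (u >= p$VT) {
      spikes <- c(spikes, i * p$dt)
      u <- p$v0
    }
  }
  list(rate = 1000 * length(spikes) / p$duration, spikes = spikes)
}

#' Initialise visual-lobe connectivity
#'
#' Feed-forward weights `W` (one 625-vector per lobula unit and delay
#' bank) start as Gaussian white noise `N(0, 1)` clipped to `[-1, 1]`:
#' untrained weight vectors are far above the equilibrium norm that
#' Oja-type learning maintains, so the untrained population responds
#' strongly and broadly to any input. Lateral inhibitory weights `Q`
#' start uniform on `[0, 1]` with a zero diagonal. Input gains convert dimensionless lamina activity into LIF
#' current at the medulla (`gain_me`) and summed medulla rates into LIF
#' current at the lobula (`gain_lo`); their defaults are calibrated so a
#' trained unit fires at roughly 25-30 spikes/s for a full-contrast
#' preferred stimulus (see the methods vignette).
#'
#' @param n_lobula number of lobula units (medulla size is `5 * n_lobula`).
#' @param seed integer seed for the initial weights.
#' @param gain_me lamina-to-medulla current gain.
#' @param gain_lo medulla-to-lobula current gain.
#' @param noise_scale Poisson count-noise magnitude (0 disables noise).
#' @return An object of class `visual_lobe_weights` with fields `W`
#'   (`n_lobula x 5 x 625` array), `Q` (`n_lobula x n_lobula`), gains and
#'   metadata.
#' @export
init_visual_lobe <- function(n_lobula = 50, seed = 1, gain_me = 0.5,
                             gain_lo = 0.003, noise_scale = 1) {
  stopifnot(n_lobula >= 1)
  with_seed(seed, {
    W <- array(clip(stats::rnorm(n_lobula * N_DELAYS * LAMINA_N), -1, 1),
               dim = c(n_lobula, N_DELAYS, LAMINA_N))
    Q <- matrix(stats::runif(n_lobula^2), n_lobula, n_lobula)
    diag(Q) <- 0
    structure(list(W = W, Q = Q, n_lobula = as.integer(n_lobula),
                   gain_me = gain_me, gain_lo = gain_lo,
                   noise_scale = noise_scale, seed = seed,
                   trained = FALSE, history = NULL),
              class = "visual_lobe_weights")
  })
}

#' @export
print.visual_lobe_weights <- function(x, ...) {
  cat(sprintf("visual_lobe_weights: %d lobula units x %d delay banks x %d lamina inputs (%s)\n",
              x$n_lobula, N_DELAYS, LAMINA_N,
              if (isTRUE(x$trained)) "trained" else "untrained"))
  invisible(x)
}

# apply seeded Poisson count noise around a deterministic rate; the noisy
# rate has the deterministic rate as its mean and scale = 0 is noise-free
.noisy_rates <- function(rates, noise_scale, duration_ms) {
  if (noise_scale <= 0) return(rates)
  counts <- rates * duration_ms / 1000
  rates + noise_scale * (stats::rpois(length(counts), counts) - counts) *
    1000 / duration_ms
}

#' Medulla response to a lamina activity vector
#'
#' The medulla current is the weighted sum of the adapted lamina
#' activities (`I = gain * sum(W_slice * (lamina - baseline))`, where the
#' baseline is the phasic lamina's adaptation level — within a scan, the
#' sweep-average activity of each lamina unit) driving a LIF neuron;
#' seeded Poisson count noise perturbs the deterministic spike count
#' around its mean (`noise_scale = 0` reproduces the noise-free rate
#' exactly).
#'
#' @param lamina length-625 lamina activity vector.
#' @param W_slice length-625 weight vector of this medulla neuron.
#' @param p a [lif_params()] object.
#' @param gain lamina-to-current gain.
#' @param noise_scale Poisson noise magnitude.
#' @param seed optional integer seed for the noise draw.
#' @param baseline adaptation level subtracted from the lamina input; by
#'   default zero (an isolated presentation with no adaptation history).
#' @return A list with `rate` (spikes/s) and `current`.
#' @export
medulla_response <- function(lamina, W_slice, p = lif_params(), gain = 0.5,
                             noise_scale = 0, seed = NULL, baseline = 0) {
  if (length(lamina) != length(W_slice)) {
    stop("weight slice must match lamina length", call. = FALSE)
  }
  I <- gain * sum(W_slice * (lamina - baseline))
  rate <- lif_rate_closed(I, p)
  rate <- with_seed(seed, .noisy_rates(rate, noise_scale, p$duration))
  list(rate = max(rate, 0), current = I)
}

#' Lobula population response to a scan sequence
#'
#' Runs the full forward pass: each of the five patches drives the lamina,
#' whose activity excites delay-bank `k` of every lobula unit through
#' `W[, k, ]`; bank rates are buffered and summed at the final instant
#' (delay alignment), and lateral inhibition `Q` is resolved by a damped
#' fixed-point iteration on rates,
#' `r <- (1 - d) r + d LIF(gain_lo * max(0, drive - Q r))`, until the
#' largest rate change falls below `tol` or `max_iter` iterations (default 250; the adaptively damped iteration needs headroom when inhibition is strong)
#' (non-convergence is flagged and the last iterate returned).
#'
#' @param scan a [make_scan()] or [make_moving_bar()] `scan_sequence`.
#' @param weights a `visual_lobe_weights` object.
#' @param p a [lif_params()] object.
#' @param noise_scale Poisson noise on medulla rates; defaults to the
#'   value stored in `weights`.
#' @param seed optional integer seed for the noise draws.
#' @param stages if `TRUE`, also return lamina and medulla activities.
#' @param tol fixed-point convergence tolerance (spikes/s).
#' @param max_iter fixed-point iteration cap.
#' @return A list with `rates` (length `n_lobula`, spikes/s), `converged`,
#'   `iterations`, and (with `stages = TRUE`) `lamina` (625 x 5) and
#'   `medulla` (`n_lobula` x 5) matrices.
#' @export
lobula_response <- function(scan, weights, p = lif_params(),
                            noise_scale = NULL, seed = NULL,
                            stages = FALSE, tol = 1e-3, max_iter = 250) {
  pre <- lobula_precompute(scan, weights, p)
  out <- lobula_sample(pre, weights, p, noise_scale = noise_scale,
                       seed = seed, tol = tol, max_iter = max_iter)
  if (stages) { out$lamina <- pre$lamina; out$medulla <- out$medulla_noisy }
  out$medulla_noisy <- NULL
  out
}

#' Precompute the deterministic stages of a scan's forward pass
#'
#' Computes the lamina activities and the noise-free medulla rates for a
#' scan once, so repeated noisy presentations of the same stimulus (e.g.
#' conditioning trials and choice tests) only redraw the Poisson noise and
#' re-solve the lateral-inhibition fixed point.
#'
#' @inheritParams lobula_response
#' @return An object of class `lobula_drive` with `lamina` (625 x 5) and
#'   `medulla_det` (`n_lobula` x 5) matrices.
#' @export
lobula_precompute <- function(scan, weights, p = lif_params()) {
  stopifnot(inherits(scan, "scan_sequence"),
            inherits(weights, "visual_lobe_weights"))
  if (length(scan$patches) != N_DELAYS) {
    stop("scan must contain exactly five patches", call. = FALSE)
  }
  n <- weights$n_lobula
  lam <- vapply(scan$patches, lamina_response, numeric(LAMINA_N),
                p = sigmoid_params())
  # the lamina is phasic: sustained activity adapts away, so each delay
  # bank is driven by the deviation of its patch from the sweep-average
  # activity of that lamina unit. A static (zero-shift) sweep therefore
  # drives the lobula only weakly, while lateral motion refreshes the
  # contrast signal at every step.
  eff <- lam - rowMeans(lam)
  med <- matrix(0, n, N_DELAYS)
  for (k in seq_len(N_DELAYS)) {
    I <- weights$gain_me * (matrix(weights$W[, k, ], nrow = n) %*% eff[, k])
    med[, k] <- lif_rate_closed(as.numeric(I), p)
  }
  structure(list(lamina = lam, medulla_det = med), class = "lobula_drive")
}

#' Sample a lobula response from a precomputed drive
#'
#' @param pre a `lobula_drive` from [lobula_precompute()].
#' @inheritParams lobula_response
#' @return As [lobula_response()].
#' @export
lobula_sample <- function(pre, weights, p = lif_params(),
                          noise_scale = NULL, seed = NULL,
                          tol = 1e-3, max_iter = 250) {
  stopifnot(inherits(pre, "lobula_drive"))
  if (is.null(noise_scale)) noise_scale <- weights$noise_scale
  n <- weights$n_lobula
  med <- with_seed(seed, matrix(pmax(.noisy_rates(as.numeric(pre$medulla_det),
                                                  noise_scale, p$duration), 0),
                                n, N_DELAYS))
  drive <- rowSums(med)
  fp <- .lobula_fixed_point(drive, weights$Q, weights$gain_lo, p,
                            tol = tol, max_iter = max_iter)
  if (!fp$converged) {
    warning("lobula lateral-inhibition fixed point did not converge; returning last iterate",
            call. = FALSE)
  }
  list(rates = fp$rates, converged = fp$converged, iterations = fp$iterations,
       medulla_noisy = med)
}

# damped fixed-point iteration on rates, r <- LIF(gain * max(drive - Q r, 0)).
# The damping halves whenever the residual of the undamped map grows, which
# tames the two-cycles that strong uniform inhibition otherwise produces.
.lobula_fixed_point <- function(drive, Q, gain, p, tol = 1e-3,
                                max_iter = 250) {
  r <- lif_rate_closed(gain * drive, p)
  damp <- 0.3
  prev_res <- Inf
  converged <- FALSE
  iter <- 0L
  for (it in seq_len(max_iter)) {
    iter <- it
    target <- lif_rate_closed(gain * pmax(drive - as.numeric(Q %*% r), 0), p)
    res <- max(abs(target - r))
    if (res < tol) { r <- target; converged <- TRUE; break }
    if (res > prev_res) damp <- max(damp * 0.5, 0.02)
    prev_res <- res
    r <- (1 - damp) * r + damp * target
  }
  list(rates = pmax(r, 0), converged = converged, iterations = iter)
}
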