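# Parameter constructors. Values follow the model description: membrane
# gain R = 10, tau = 10 ms, reset -80 mV, threshold 0 mV; lamina sigmoid
# A0 = 1, m = -1, b = 0.5. Presentation duration and integration step are
# model choices (see the methods vignette).

#' Leaky integrate-and-fire parameters
#'
#' Membrane dynamics are `tau_m du/dt = -u + R I(t)` with reset to `v0`
#' whenever `u >= VT`. For a constant suprathreshold current the interspike
#' interval has the closed form `ISI = tau_m log((R I - v0) / (R I - VT))`.
#'
#' @param R membrane resistance (dimensionless input gain).
#' @param tau_m membrane time constant (ms).
#' @param v0 reset potential (mV).
#' @param VT spike threshold (mV).
#' @param dt Euler integration step (ms).
#' @param duration presentation window per patch (ms).
#' @return An object of class `lif_params`.
#' @export
#' @examples
#' p <- lif_params()
#' lif_rate_closed(16, p) # about 246.6 spikes/s
lif_params <- function(R = 10, tau_m = 10, v0 = -80, VT = 0, dt = 0.1,
                       duration = 100) {
  stopifnot(v0 < VT, dt > 0, dt < tau_m, duration > 0, tau_m > 0)
  structure(list(R = R, tau_m = tau_m, v0 = v0, VT = VT, dt = dt,
                 duration = duration),
            class = "lif_params")
}

#' Lamina activation-function parameters
#'
#' The lamina squashes pooled photoreceptor input through
#' `f(r) = A0 / (1 + exp(m r + b))`; with the default negative slope the
#' function is strictly increasing in `r`.
#'
#' @param A0 maximum activity.
#' @param m slope parameter (negative for an increasing response).
#' @param b offset controlling the midpoint.
#' @return An object of class `sigmoid_params`.
#' @export
sigmoid_params <- function(A0 = 1, m = -1, b = 0.5) {
  stopifnot(A0 > 0)
  structure(list(A0 = A0, m = m, b = b), class = "sigmoid_params")
}

#' Non-associative learning configuration
#'
#' Controls the exposure-driven training of the visual lobe: `gamma` scales
#' the Oja updates of the feed-forward tensor `W`, `eta` the symmetric
#' inhibitory-STDP updates of the lateral matrix `Q`, and `alpha` sets the
#' target pairwise co-activity (in (spikes/s)^2) towards which `Q` drives
#' the lobula population. Training stops when the maximum absolute weight
#' change over a sliding window of `window` scans drops below
#' `convergence_eps`, or after `n_patches` scans.
#'
#' Defaults keep the discrete updates stable: the Oja step is a
#' contraction only while `gamma * y^2 < 1` for the linear population
#' response `y`, whose variance is of order one once the weight norm has
#' relaxed, and `alpha` is expressed in the same (contrast-signal)^2
#' units as the rectified co-activities that drive `Q` (see the methods
#' vignette for the calibration).
#'
#' @param gamma Oja learning rate.
#' @param eta inhibitory-STDP learning rate.
#' @param alpha target pairwise co-activity of the rectified linear
#'   responses.
#' @param n_patches maximum number of training scans.
#' @param convergence_eps weight-change threshold terminating training
#'   (a 0.001 change on an order-one weight scale, rescaled to the
#'   equilibrium weight norm used here, whose entries are of order 0.02).
#' @param window sliding-window length (scans) for the convergence check.
#' @param freeze_q if `TRUE`, lateral inhibitory weights stay at their
#'   initial values (fixed-inhibition ablation).
#' @param seed integer seed for scan sampling and initial weights.
#' @return An object of class `learning_config`.
#' @export
learning_config <- function(gamma = 3e-3, eta = 4e-3, alpha = 0.04,
                            n_patches = 50000, convergence_eps = 2e-5,
                            window = 100, freeze_q = FALSE, seed = 1) {
  stopifnot(gamma >= 0, eta >= 0, alpha >= 0, convergence_eps > 0,
            n_patches >= 1, window >= 1)
  structure(list(gamma = gamma, eta = eta, alpha = alpha,
                 n_patches = as.integer(n_patches),
                 convergence_eps = convergence_eps,
                 window = as.integer(window),
                 freeze_q = isTRUE(freeze_q), seed = seed),
            class = "learning_config")
}

#' STDP kernel parameters
#'
#' @param A maximum kernel magnitude.
#' @param tau kernel time constant (ms).
#' @return An object of class `stdp_params`.
#' @export
stdp_params <- function(A = 0.01, tau = 20) {
  stopifnot(A > 0, tau > 0)
  structure(list(A = A, tau = tau), class = "stdp_params")
}

#' Differential-conditioning protocol
#'
#' @param n_exposures rewarded/punished presentations per pattern.
#' @param n_bees independent mushroom-body initialisations.
#' @param n_tests unrewarded choice tests per bee.
#' @param region scanned region (`"whole"`, `"lower_half"`, `"lower_left"`).
#' @param shift_px pixel shift between consecutive patches (speed proxy:
#'   0 px is hovering, 15 px is 0.1 m/s, 45 px is 0.3 m/s).
#' @param distal if `TRUE`, patterns are viewed from the far distance
#'   (shrunk five-fold on the canvas) before scanning.
#' @param seed base seed; per-bee streams are derived from it.
#' @return An object of class `conditioning_protocol`.
#' @export
conditioning_protocol <- function(n_exposures = 100, n_bees = 20,
                                  n_tests = 50, region = "lower_half",
                                  shift_px = 15, distal = FALSE, seed = 1) {
  stopifnot(n_exposures >= 0, n_bees >= 1, n_tests >= 1, shift_px >= 0)
  region <- match.arg(region, c("whole", "lower_half", "lower_left"))
  structure(list(n_exposures = as.integer(n_exposures),
                 n_bees = as.integer(n_bees), n_tests = as.integer(n_tests),
                 region = region, shift_px = as.integer(shift_px),
                 distal = isTRUE(distal), seed = seed),
            class = "conditioning_protocol")
}
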