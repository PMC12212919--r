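# Mushroom-body classifier: sparse random Kenyon-cell expansion of the
# lobula code, a single output neuron (MBON), reward-modulated STDP on the
# KC-to-MBON weights, the differential-conditioning protocol and the
# two-alternative choice test. Lower MBON rate signals preference.

KC_TAU_SYN <- 5  # exponential synaptic trace time constant (ms)

#' Initialise mushroom-body connectivity for one simulated bee
#'
#' The lobula-to-KC projection `S` is random excitatory (uniform on
#' `[0, w_max]`) and fixed for the bee's lifetime; the plastic KC-to-MBON
#' readout `D` starts uniform on `[0.4, 0.6]` so the untrained MBON
#' responds equally to any two patterns with headroom to move either way.
#' Thresholded KC activation keeps fewer than 5% of KCs active per
#' stimulus.
#'
#' @param n_lobula lobula population size feeding the projection.
#' @param n_kc number of Kenyon cells.
#' @param w_max upper bound of the random projection weights.
#' @param kc_sparsity target fraction of KCs active per stimulus.
#' @param kc_gain KC firing rate (spikes/s) per unit suprathreshold drive.
#' @param mbon_gain MBON input current per unit weighted KC synaptic trace.
#' @param seed integer seed for `S` and `D`.
#' @return An object of class `mushroom_body_weights`.
#' @export
mushroom_body <- function(n_lobula, n_kc = 2000, w_max = 0.25,
                          kc_sparsity = 0.05, kc_gain = 20,
                          mbon_gain = 0.05, seed = 1) {
  stopifnot(n_lobula >= 1, n_kc >= 20, w_max > 0,
            kc_sparsity > 0, kc_sparsity < 1)
  with_seed(seed, {
    S <- matrix(stats::runif(n_lobula * n_kc, 0, w_max), n_lobula, n_kc)
    D <- stats::runif(n_kc, 0.4, 0.6)
    structure(list(S = S, D = D, n_lobula = as.integer(n_lobula),
                   n_kc = as.integer(n_kc), w_max = w_max,
                   kc_sparsity = kc_sparsity, kc_gain = kc_gain,
                   mbon_gain = mbon_gain, seed = seed),
              class = "mushroom_body_weights")
  })
}

#' @export
print.mushroom_body_weights <- function(x, ...) {
  cat(sprintf("mushroom_body_weights: %d lobula -> %d KCs -> 1 MBON (w_max %.3g)\n",
              x$n_lobula, x$n_kc, x$w_max))
  invisible(x)
}

#' Kenyon-cell response to a lobula rate vector
#'
#' KC drive is the random projection `t(S) %*% rates`; a per-stimulus
#' threshold at the `1 - kc_sparsity` quantile of the drive distribution
#' is subtracted and the excess rectified, so at most `kc_sparsity` of the
#' population is active for any stimulus (all-zero input gives all-zero
#' output). Active KCs fire Poisson spike trains at `kc_gain` spikes/s per
#' unit suprathreshold drive over the presentation window.
#'
#' @param lobula_rates lobula rate vector.
#' @param mb a [mushroom_body()] object.
#' @param p a [lif_params()] object (presentation window).
#' @param seed optional integer seed for the spike draws.
#' @param spikes if `TRUE`, draw spike trains for the active cells.
#' @return A list with `rates` (length `n_kc`), `active` (indices),
#'   `active_fraction`, and optionally `spikes` (list of spike-time
#'   vectors parallel to `active`).
#' @export
kc_response <- function(lobula_rates, mb, p = lif_params(), seed = NULL,
                        spikes = FALSE) {
  stopifnot(inherits(mb, "mushroom_body_weights"),
            length(lobula_rates) == mb$n_lobula)
  drive <- as.numeric(crossprod(mb$S, lobula_rates))
  thr <- stats::quantile(drive, 1 - mb$kc_sparsity, names = FALSE)
  act <- pmax(drive - thr, 0)
  rates <- mb$kc_gain * act
  active <- which(act > 0)
  out <- list(rates = rates, active = active,
              active_fraction = length(active) / mb$n_kc)
  if (spikes) {
    out$spikes <- with_seed(seed, lapply(active, function(k) {
      nsp <- stats::rpois(1, rates[k] * p$duration / 1000)
      sort(stats::runif(nsp, 0, p$duration))
    }))
  }
  out
}

#' MBON response to Kenyon-cell activity
#'
#' All KCs project to the single MBON through the plastic weights `D`.
#' With spike trains supplied, each KC spike injects a unit jump into an
#' exponentially decaying synaptic trace (time constant 5 ms) and the
#' MBON membrane is integrated step by step; otherwise the rate is the
#' closed-form LIF response to the mean synaptic current
#' `mbon_gain * sum(D * r_kc) * tau_syn / 1000`.
#'
#' @param kc the output of [kc_response()].
#' @param mb a [mushroom_body()] object (supplies `D` and `mbon_gain`).
#' @param p a [lif_params()] object.
#' @return A list with `rate` (spikes/s) and `spikes` (spike times, ms;
#'   empty in the closed-form path).
#' @export
mbon_response <- function(kc, mb, p = lif_params()) {
  stopifnot(inherits(mb, "mushroom_body_weights"))
  if (!is.null(kc$spikes)) {
    nb <- ceiling(p$duration / p$dt)
    impulses <- numeric(nb)
    for (i in seq_along(kc$active)) {
      ts <- kc$spikes[[i]]
      if (length(ts)) {
        bins <- pmin(pmax(ceiling(ts / p$dt), 1L), nb)
        for (b in bins) impulses[b] <- impulses[b] + mb$D[kc$active[i]]
      }
    }
    decay <- exp(-p$dt / KC_TAU_SYN)
    g <- as.numeric(stats::filter(impulses, decay, method = "recursive"))
    u <- p$v0
    k <- p$dt / p$tau_m
    sp <- numeric(0)
    for (t in seq_len(nb)) {
      u <- u + k * (p$R * mb$mbon_gain * g[t] - u)
      if (u >= p$VT) { sp <- c(sp, t * p$dt); u <- p$v0 }
    }
    list(rate = 1000 * length(sp) / p$duration, spikes = sp)
  } else {
    I <- mb$mbon_gain * sum(mb$D * kc$rates) * KC_TAU_SYN / 1000
    list(rate = lif_rate_closed(I, p), spikes = numeric(0))
  }
}

#' Reward-modulated STDP kernel
#'
#' Dopamine mode (punished stimuli) is the classical antisymmetric kernel:
#' `+A exp(-dt / tau)` when the postsynaptic spike follows the
#' presynaptic one (`dt > 0`) and `-A exp(dt / tau)` when it precedes it.
#' Octopamine mode (rewarded stimuli) depresses for either ordering:
#' `-A exp(-|dt| / tau)`. Coincident spikes (`dt = 0`) contribute zero.
#'
#' @param dt `t_post - t_pre` in ms (vectorised).
#' @param mode `"dopamine"` or `"octopamine"`.
#' @param p a [stdp_params()] object.
#' @return Weight change(s).
#' @export
#' @examples
#' stdp_kernel(20, "dopamine")    # 0.01 * exp(-1)
#' stdp_kernel(-20, "octopamine") # -0.01 * exp(-1)
stdp_kernel <- function(dt, mode = c("dopamine", "octopamine"),
                        p = stdp_params()) {
  mode <- match.arg(mode)
  mag <- p$A * exp(-abs(dt) / p$tau)
  out <- if (mode == "dopamine") sign(dt) * mag else -mag
  out[dt == 0] <- 0
  out
}

#' One conditioning trial
#'
#' Presents a scanned pattern with a reinforcement valence and updates the
#' KC-to-MBON weights. The forward pass generates KC and MBON spike
#' trains; each KC spike leaves an eligibility trace that the next MBON
#' spikes convert into a weight change, i.e. every causal (KC spike
#' before MBON spike) pair within five kernel time constants (100 ms)
#' contributes `stdp_kernel(t_post - t_pre)` with octopamine for rewarded
#' and dopamine for punished stimuli: rewarded-pattern synapses are
#' depressed, punished-pattern synapses potentiated. Only KCs that spiked
#' are touched, `D` is clipped to `[0, 1]`, and `S` is never modified.
#'
#' @param scan a `scan_sequence`, or `NULL` when `pre` is supplied.
#' @param valence `"reward"` or `"punishment"`.
#' @param lobe a `visual_lobe_weights` object.
#' @param mb a [mushroom_body()] object.
#' @param p a [lif_params()] object.
#' @param stdp a [stdp_params()] object.
#' @param seed integer seed for the trial's noise and spike draws.
#' @param pre optional [lobula_precompute()] result for `scan`.
#' @return `mb` with updated `D`; the attribute `mbon_rate` records the
#'   measured MBON rate during the trial.
#' @export
conditioning_trial <- function(scan, valence = c("reward", "punishment"),
                               lobe, mb, p = lif_params(),
                               stdp = stdp_params(), seed = NULL,
                               pre = NULL) {
  valence <- match.arg(valence)
  if (is.null(pre)) pre <- lobula_precompute(scan, lobe, p)
  lob <- lobula_sample(pre, lobe, p, seed = sub_seed(seed, "lob"))
  # the mushroom body integrates over the full five-patch sweep
  p_mb <- p
  p_mb$duration <- p$duration * SCAN_LEN
  kc <- kc_response(lob$rates, mb, p_mb, seed = sub_seed(seed, "kc"),
                    spikes = TRUE)
  mbon <- with_seed(sub_seed(seed, "mbon"), mbon_response(kc, mb, p_mb))
  mode <- if (valence == "reward") "octopamine" else "dopamine"
  if (length(mbon$spikes) && length(kc$active)) {
    for (i in seq_along(kc$active)) {
      ts <- kc$spikes[[i]]
      if (!length(ts)) next
      dts <- outer(mbon$spikes, ts, "-")
      dts <- dts[dts > 0 & dts <= 5 * stdp$tau]
      if (!length(dts)) next
      k <- kc$active[i]
      mb$D[k] <- clip(mb$D[k] + sum(stdp_kernel(dts, mode, stdp)), 0, 1)
    }
  }
  attr(mb, "mbon_rate") <- mbon$rate
  mb
}

#' Unrewarded two-alternative choice test
#'
#' Computes the MBON rate for both scans with fresh noise and no
#' plasticity; the simulated bee chooses the pattern with the lower MBON
#' rate (learned preference), breaking exact ties uniformly at random.
#' Rates are measured as spike counts of the simulated MBON over one
#' patch-presentation window (a brief decision glance), driven by Poisson
#' KC spike trains, so choices carry the count noise of a short
#' behavioural observation. Conditioning, by contrast, integrates
#' eligibility over the full five-patch sweep.
#'
#' @param mb a trained [mushroom_body()] object.
#' @param lobe a `visual_lobe_weights` object.
#' @param scanA,scanB `scan_sequence` objects, or `NULL` when `preA` /
#'   `preB` are supplied.
#' @param p a [lif_params()] object.
#' @param seed integer seed for the test's noise draws.
#' @param preA,preB optional precomputed drives for the two scans.
#' @return An object of class `choice_outcome`: list with `rate_a`,
#'   `rate_b` and `choice` (1 for A, 2 for B).
#' @export
choice_test <- function(mb, lobe, scanA = NULL, scanB = NULL,
                        p = lif_params(), seed = NULL,
                        preA = NULL, preB = NULL) {
  if (is.null(preA)) preA <- lobula_precompute(scanA, lobe, p)
  if (is.null(preB)) preB <- lobula_precompute(scanB, lobe, p)
  ra <- lobula_sample(preA, lobe, p, seed = sub_seed(seed, "A"))$rates
  rb <- lobula_sample(preB, lobe, p, seed = sub_seed(seed, "B"))$rates
  kca <- kc_response(ra, mb, p, seed = sub_seed(seed, "kcA"), spikes = TRUE)
  kcb <- kc_response(rb, mb, p, seed = sub_seed(seed, "kcB"), spikes = TRUE)
  rate_a <- with_seed(sub_seed(seed, "mA"), mbon_response(kca, mb, p))$rate
  rate_b <- with_seed(sub_seed(seed, "mB"), mbon_response(kcb, mb, p))$rate
  choice <- if (rate_a < rate_b) 1L else if (rate_b < rate_a) 2L else {
    with_seed(sub_seed(seed, "tie"), sample(1:2, 1))
  }
  structure(list(rate_a = rate_a, rate_b = rate_b, choice = choice),
            class = "choice_outcome")
}

#' Run a differential-conditioning protocol over a cohort of bees
#'
#' For each simulated bee (independent mushroom-body initialisation), the
#' rewarded pattern `S+` and punished pattern `S-` are presented in
#' random interleaved order (`n_exposures` each) under the protocol's
#' scanning condition, then `n_tests` plasticity-free choice tests are
#' run. The visual lobe is read-only throughout.
#'
#' @param protocol a [conditioning_protocol()] object.
#' @param lobe a trained `visual_lobe_weights` object.
#' @param patterns list of two intensity matrices: the rewarded pattern
#'   first, the punished one second.
#' @param p a [lif_params()] object.
#' @param stdp a [stdp_params()] object.
#' @param n_kc,w_max mushroom-body size parameters passed to
#'   [mushroom_body()].
#' @param learning_curve if `TRUE`, record per-exposure MBON rates.
#' @return A list of class `protocol_result` with `accuracy` (per-bee data
#'   frame), `mean_accuracy`, `sem_accuracy`, and `curves` (per-exposure
#'   MBON rates, when recorded).
#' @export
run_protocol <- function(protocol, lobe, patterns, p = lif_params(),
                         stdp = stdp_params(), n_kc = 2000, w_max = 0.25,
                         learning_curve = FALSE) {
  stopifnot(inherits(protocol, "conditioning_protocol"), length(patterns) == 2)
  # viewing geometry: the eye's 75-px window covers the lower half of a
  # pattern at the reference (2 cm) distance; seeing the whole pattern
  # requires twice that distance (2x shrink) and the distal condition
  # five times (5x shrink)
  factor <- if (protocol$distal) 5L else if (protocol$region == "whole") 2L else 1L
  imgs <- lapply(patterns, function(im) {
    if (factor > 1L) distal_view(im, factor) else im
  })
  scans <- lapply(imgs, make_scan,
                  region = if (protocol$region == "whole") "whole" else
                    protocol$region,
                  shift_px = protocol$shift_px)
  pres <- lapply(scans, lobula_precompute, weights = lobe, p = p)
  acc <- data.frame(bee = seq_len(protocol$n_bees), seed = NA_integer_,
                    n_correct = NA_integer_, n_tests = protocol$n_tests,
                    accuracy = NA_real_)
  curves <- list()
  for (b in seq_len(protocol$n_bees)) {
    bee_seed <- sub_seed(protocol$seed, paste0("bee", b))
    mb <- mushroom_body(lobe$n_lobula, n_kc = n_kc, w_max = w_max,
                        seed = bee_seed)
    order_idx <- with_seed(sub_seed(bee_seed, "order"),
                           sample(rep(1:2, protocol$n_exposures)))
    for (e in seq_along(order_idx)) {
      pat <- order_idx[e]
      mb <- conditioning_trial(NULL,
                               valence = if (pat == 1) "reward" else "punishment",
                               lobe = lobe, mb = mb, p = p, stdp = stdp,
                               seed = sub_seed(bee_seed, paste0("exp", e)),
                               pre = pres[[pat]])
      if (learning_curve) {
        curves[[length(curves) + 1L]] <- data.frame(
          bee = b, exposure = e, pattern = c("S+", "S-")[pat],
          mbon_rate = attr(mb, "mbon_rate"))
      }
    }
    correct <- 0L
    for (t in seq_len(protocol$n_tests)) {
      out <- choice_test(mb, lobe, p = p,
                         seed = sub_seed(bee_seed, paste0("test", t)),
                         preA = pres[[1]], preB = pres[[2]])
      if (out$choice == 1L) correct <- correct + 1L
    }
    acc$seed[b] <- bee_seed
    acc$n_correct[b] <- correct
    acc$accuracy[b] <- correct / protocol$n_tests
  }
  structure(list(accuracy = acc,
                 mean_accuracy = mean(acc$accuracy),
                 sem_accuracy = stats::sd(acc$accuracy) /
                   sqrt(nrow(acc)),
                 curves = if (length(curves)) do.call(rbind, curves) else NULL,
                 protocol = protocol),
            class = "protocol_result")
}

#' @export
print.protocol_result <- function(x, ...) {
  cat(sprintf("protocol_result: %d bees, %s scan, shift %d px: mean accuracy %.1f%% (SEM %.1f)\n",
              nrow(x$accuracy), x$protocol$region, x$protocol$shift_px,
              100 * x$mean_accuracy, 100 * x$sem_accuracy))
  invisible(x)
}
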