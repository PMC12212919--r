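# Population-coding and tuning metrics: Treves-Rolls sparseness, angular
# distance between population responses, response decorrelation,
# orientation and velocity tuning with a gamma-shaped velocity fit.

#' Treves-Rolls sparseness index
#'
#' `SI = (sum(r) / N)^2 / (sum(r^2) / N)`, bounded by `1/N` (one-hot,
#' maximally sparse) and 1 (uniform, fully distributed). Lower values mean
#' sparser population activity.
#'
#' @param rates non-negative firing-rate vector with at least one positive
#'   entry.
#' @return The sparseness index in `[1/N, 1]`, or `NA` (with a warning)
#'   for an all-zero vector, where the index is undefined.
#' @export
#' @examples
#' sparseness_index(rep(3, 10))   # 1
#' sparseness_index(c(1, 0, 0, 0)) # 0.25
sparseness_index <- function(rates) {
  n <- length(rates)
  if (n == 0 || all(rates == 0)) {
    warning("sparseness index undefined for an all-zero vector", call. = FALSE)
    return(NA_real_)
  }
  (sum(rates) / n)^2 / (sum(rates^2) / n)
}

#' Angular distance between two population response vectors
#'
#' `theta = acos(r1 . r2 / (|r1| |r2|))` in degrees; 0 for parallel
#' responses, 90 for orthogonal ones. Scale-invariant and symmetric.
#'
#' @param r1,r2 nonzero numeric vectors of equal length.
#' @return Angle in degrees, in `[0, 180]`.
#' @export
angular_distance <- function(r1, r2) {
  stopifnot(length(r1) == length(r2))
  n1 <- sqrt(sum(r1^2)); n2 <- sqrt(sum(r2^2))
  if (n1 == 0 || n2 == 0) {
    stop("angular distance undefined for a zero vector", call. = FALSE)
  }
  acos(clip(sum(r1 * r2) / (n1 * n2), -1, 1)) * 180 / pi
}

#' Pairwise response correlations across a stimulus battery
#'
#' Pearson correlation between neurons' rate profiles across stimuli.
#' Neurons with constant responses (zero variance) are excluded and listed
#' in the `excluded` attribute.
#'
#' @param responses stimuli x neurons rate matrix (at least two stimuli).
#' @return A list with `matrix` (neuron x neuron correlations, unit
#'   diagonal) and `mean_abs_offdiag`.
#' @export
response_correlation <- function(responses) {
  if (!is.matrix(responses) || nrow(responses) < 2) {
    stop("need a matrix with at least two stimulus rows", call. = FALSE)
  }
  v <- apply(responses, 2, stats::var)
  keep <- which(v > 0)
  if (length(keep) < 2) {
    stop("fewer than two neurons with non-constant responses", call. = FALSE)
  }
  cm <- stats::cor(responses[, keep, drop = FALSE])
  off <- cm[upper.tri(cm)]
  out <- list(matrix = cm, mean_abs_offdiag = mean(abs(off)))
  attr(out, "excluded") <- setdiff(seq_len(ncol(responses)), keep)
  out
}

# response to the orientation orthogonal to `pref`, averaged over both
# motion directions present on the probe grid
.orth_rate <- function(angles, rates, pref) {
  mean(vapply(c((pref + 90) %% 360, (pref + 270) %% 360), function(o) {
    rates[which.min(abs(((angles - o + 180) %% 360) - 180))]
  }, numeric(1)))
}

#' Orientation tuning of a lobula unit
#'
#' Probes the unit with moving bars at each angle (motion orthogonal to
#' the bar axis), averaging over `n_reps` independent noise draws, and
#' summarises selectivity with `OSI = (r_pref - r_orth) /
#' (r_pref + r_orth)` where `r_orth` is the response to the orthogonal
#' bar orientation, averaged over its two motion directions (the probe
#' angles 90 degrees either side of the preferred one).
#'
#' @param lobe a `visual_lobe_weights` object.
#' @param unit lobula unit index.
#' @param angles probe orientations in degrees.
#' @param n_reps noise repetitions per angle.
#' @param shift_px bar displacement per frame.
#' @param contrast bar contrast.
#' @param lif a [lif_params()] object.
#' @param seed integer seed for the noise draws.
#' @return A list of class `tuning_curve` with `curve` (data frame:
#'   `angle`, `rate`, `sem`), `preferred` (angle of maximal mean rate),
#'   and `osi`.
#' @export
orientation_tuning <- function(lobe, unit, angles = seq(0, 330, by = 30),
                               n_reps = 50, shift_px = 15, contrast = 1,
                               lif = lif_params(), seed = 1) {
  stopifnot(inherits(lobe, "visual_lobe_weights"))
  rows <- lapply(seq_along(angles), function(ai) {
    scan <- make_moving_bar(angles[ai], shift_px = shift_px,
                            contrast = contrast)
    rs <- vapply(seq_len(n_reps), function(rep) {
      lobula_response(scan, lobe, p = lif,
                      seed = sub_seed(seed, paste0("ot", ai, "_", rep))
                      )$rates[unit]
    }, numeric(1))
    data.frame(angle = angles[ai], rate = mean(rs),
               sem = stats::sd(rs) / sqrt(n_reps))
  })
  curve <- do.call(rbind, rows)
  pref <- curve$angle[which.max(curve$rate)]
  r_p <- max(curve$rate)
  r_o <- .orth_rate(curve$angle, curve$rate, pref)
  osi <- if (r_p + r_o > 0) (r_p - r_o) / (r_p + r_o) else 0
  structure(list(curve = curve, preferred = pref, osi = osi, unit = unit),
            class = "tuning_curve")
}

#' @export
print.tuning_curve <- function(x, ...) {
  lab <- if (!is.null(x$osi)) sprintf("preferred %g deg, OSI %.3f", x$preferred, x$osi)
  else sprintf("peak at %g", x$preferred)
  cat(sprintf("tuning_curve (unit %d): %d points, %s\n",
              x$unit, nrow(x$curve), lab))
  invisible(x)
}

#' Velocity tuning of a lobula unit with a gamma-shaped fit
#'
#' Measures the unit's response to its preferred-orientation moving bar at
#' a range of per-frame displacements (the scanning-speed proxy) and fits
#' the gamma-density-shaped curve `r(v) = c v^(k-1) exp(-v / theta)`
#' (`k > 1`) by nonlinear least squares, giving a band-pass velocity
#' characteristic with fitted peak `(k - 1) theta`.
#'
#' @param lobe a `visual_lobe_weights` object.
#' @param unit lobula unit index.
#' @param angle probe orientation (the unit's preferred angle).
#' @param shifts per-frame displacements (px) to test.
#' @param n_reps noise repetitions per displacement.
#' @param lif a [lif_params()] object.
#' @param seed integer seed.
#' @return A list of class `tuning_curve` with `curve` (data frame:
#'   `shift`, `rate`, `sem`), `fit` (named vector `c`, `k`, `theta` or
#'   `NULL` if degenerate), `peak_shift`, and `preferred` (the fitted peak,
#'   falling back to the empirical argmax).
#' @export
velocity_tuning <- function(lobe, unit, angle, shifts = seq(0, 60, by = 5),
                            n_reps = 20, lif = lif_params(), seed = 1) {
  rows <- lapply(seq_along(shifts), function(si) {
    scan <- make_moving_bar(angle, shift_px = shifts[si])
    rs <- vapply(seq_len(n_reps), function(rep) {
      lobula_response(scan, lobe, p = lif,
                      seed = sub_seed(seed, paste0("vt", si, "_", rep))
                      )$rates[unit]
    }, numeric(1))
    data.frame(shift = shifts[si], rate = mean(rs),
               sem = stats::sd(rs) / sqrt(n_reps))
  })
  curve <- do.call(rbind, rows)
  fit <- NULL
  peak <- curve$shift[which.max(curve$rate)]
  if (any(curve$rate > 0)) {
    st <- list(c = max(curve$rate), k = 2, theta = max(peak, 5))
    fit_try <- tryCatch(
      minpack.lm::nlsLM(rate ~ c * ifelse(shift > 0, shift, 0)^(k - 1) *
                          exp(-shift / theta),
                        data = curve, start = st,
                        lower = c(c = 0, k = 1.001, theta = 0.5),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit_try)) {
      cf <- stats::coef(fit_try)
      fit <- cf
      peak <- unname((cf["k"] - 1) * cf["theta"])
    } else {
      warning("gamma velocity fit degenerate; reporting empirical peak",
              call. = FALSE)
    }
  }
  structure(list(curve = curve, fit = fit, peak_shift = peak,
                 preferred = peak, unit = unit),
            class = "tuning_curve")
}

#' Count orientation-selective units in a population
#'
#' Convenience screen used by the training experiments: computes the OSI
#' of every unit at a reduced number of noise repetitions and returns the
#' fraction with OSI above `threshold`.
#'
#' @param lobe a `visual_lobe_weights` object.
#' @param angles probe orientations.
#' @param n_reps noise repetitions per angle.
#' @param threshold OSI cut-off for calling a unit selective.
#' @param lif a [lif_params()] object.
#' @param seed integer seed.
#' @return A list with `osi` (per-unit vector), `selective` (logical) and
#'   `fraction`.
#' @export
population_osi <- function(lobe, angles = seq(0, 330, by = 30), n_reps = 5,
                           threshold = 0.3, lif = lif_params(), seed = 1) {
  n <- lobe$n_lobula
  # share forward passes across units: one population response per probe
  rates <- array(0, c(length(angles), n_reps, n))
  for (ai in seq_along(angles)) {
    scan <- make_moving_bar(angles[ai], shift_px = 15)
    for (rep in seq_len(n_reps)) {
      rates[ai, rep, ] <- lobula_response(
        scan, lobe, p = lif,
        seed = sub_seed(seed, paste0("posi", ai, "_", rep)))$rates
    }
  }
  mean_rates <- apply(rates, c(1, 3), mean)  # angle x unit
  osi <- vapply(seq_len(n), function(u) {
    r <- mean_rates[, u]
    pref <- angles[which.max(r)]
    ro <- .orth_rate(angles, r, pref)
    if (max(r) + ro > 0) (max(r) - ro) / (max(r) + ro) else 0
  }, numeric(1))
  list(osi = osi, selective = osi > threshold, fraction = mean(osi > threshold))
}
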