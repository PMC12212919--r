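# Config-driven reproduction of the model's experiments: receptive-field
# training, sparseness/decorrelation analyses, tuning curves, scanning-
# condition discrimination, population-size and fixed-inhibition
# ablations, plus the nonparametric statistics used to compare conditions.

#' Simulation profiles
#'
#' `"fast"` is a reduced-scale profile (16 lobula units, 500 KCs, 5000
#' training scans, 5 bees x 20 tests) sized so a full experiment runs in
#' minutes; `"paper"` keeps the full-scale settings (50 lobula units,
#' 50,000 scans, 20 bees x 50 tests, 100 exposures per pattern).
#'
#' @param name `"fast"` or `"paper"`.
#' @return A named list of scale parameters.
#' @export
sim_profile <- function(name = c("fast", "paper")) {
  name <- match.arg(name)
  if (name == "fast") {
    list(n_lobula = 16, n_kc = 500, n_patches = 5000, n_scenes = 8,
         n_bees = 5, n_tests = 20, n_exposures = 50)
  } else {
    list(n_lobula = 50, n_kc = 2000, n_patches = 50000, n_scenes = 20,
         n_bees = 20, n_tests = 50, n_exposures = 100)
  }
}

#' Experiment configuration
#'
#' @param experiment one of `"rf_training"`, `"sparseness"`, `"tuning"`,
#'   `"scanning_conditions"`, `"generalisation"`, `"population_size"`,
#'   `"fixed_inhibition"`.
#' @param profile `"fast"` or `"paper"` (see [sim_profile()]).
#' @param seed global seed; all randomness flows from it.
#' @param outdir optional output directory for CSV tables and PNGs.
#' @param ... overrides for individual profile fields (e.g. `n_bees`).
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(experiment = c("rf_training", "sparseness",
                                             "tuning", "scanning_conditions",
                                             "generalisation",
                                             "population_size",
                                             "fixed_inhibition"),
                              profile = "fast", seed = 1, outdir = NULL,
                              ...) {
  experiment <- match.arg(experiment)
  prof <- utils::modifyList(sim_profile(profile), list(...))
  structure(list(experiment = experiment, profile = profile, prof = prof,
                 seed = seed, outdir = outdir),
            class = "experiment_config")
}

# training scenes shared by all experiments
.make_scene_set <- function(n_scenes, seed, shuffled = FALSE) {
  scenes <- lapply(seq_len(n_scenes), function(i) {
    make_synthetic_scene(sub_seed(seed, paste0("scene", i)))
  })
  if (shuffled) {
    scenes <- lapply(seq_along(scenes), function(i) {
      shuffle_image(scenes[[i]], seed = sub_seed(seed, paste0("shuf", i)))
    })
  }
  scenes
}

# pretrain a visual lobe under a config (used by several experiments)
.pretrain_lobe <- function(prof, seed, shuffled = FALSE, freeze_q = FALSE,
                           n_lobula = NULL) {
  scenes <- .make_scene_set(prof$n_scenes, seed, shuffled = shuffled)
  cfg <- learning_config(n_patches = prof$n_patches, freeze_q = freeze_q,
                         seed = sub_seed(seed, "train"))
  train_visual_lobe(scenes, cfg,
                    n_lobula = if (is.null(n_lobula)) prof$n_lobula else n_lobula)
}

# held-out scans used to probe population responses
.probe_scans <- function(seed, n = 20) {
  lapply(seq_len(n), function(i) {
    img <- make_synthetic_scene(sub_seed(seed, paste0("probe", i)))
    make_scan(img, region = "custom", shift_px = 15,
              window_row = 1 + (i * 37) %% (nrow(img) - 75),
              start_col = 1 + (i * 53) %% (ncol(img) - 135))
  })
}

# population rate matrix (scans x units), noise-free
.population_responses <- function(lobe, scans, p = lif_params()) {
  t(vapply(scans, function(s) {
    lobula_response(s, lobe, p = p, noise_scale = 0)$rates
  }, numeric(lobe$n_lobula)))
}

#' Run a named experiment end to end
#'
#' Executes the configured pipeline (pretraining the visual lobe where
#' required, then the conditioning/metric stage) and returns a results
#' bundle; when `cfg$outdir` is set, tables are written as CSV and the
#' receptive-field mosaic as PNG. Every random draw derives from
#' `cfg$seed`, so a rerun with the same config reproduces the bundle.
#'
#' @param cfg an [experiment_config()] object.
#' @return A list of class `results_bundle` with `tables` (named list of
#'   data frames), `objects` (trained weights etc.) and `manifest`.
#' @export
run_experiment <- function(cfg) {
  stopifnot(inherits(cfg, "experiment_config"))
  prof <- cfg$prof
  seed <- cfg$seed
  tables <- list()
  objects <- list()

  if (cfg$experiment == "rf_training") {
    lobe <- .pretrain_lobe(prof, seed)
    posi <- population_osi(lobe, seed = sub_seed(seed, "osi"))
    tables$units <- data.frame(unit = seq_len(lobe$n_lobula), osi = posi$osi,
                               selective = posi$selective)
    tables$history <- lobe$history
    objects$lobe <- lobe
  } else if (cfg$experiment == "sparseness") {
    lobe_nat <- .pretrain_lobe(prof, seed)
    lobe_shuf <- .pretrain_lobe(prof, seed, shuffled = TRUE)
    lobe_pre <- init_visual_lobe(prof$n_lobula, seed = sub_seed(seed, "train"))
    scans <- .probe_scans(sub_seed(seed, "heldout"))
    res <- lapply(list(pre = lobe_pre, natural = lobe_nat,
                       shuffled = lobe_shuf), .population_responses,
                  scans = scans)
    si <- vapply(res, function(m) {
      mean(apply(m, 1, function(r) if (any(r > 0)) sparseness_index(r) else NA),
           na.rm = TRUE)
    }, numeric(1))
    corr <- vapply(res, function(m) {
      tryCatch(response_correlation(m)$mean_abs_offdiag,
               error = function(e) NA_real_)
    }, numeric(1))
    tables$summary <- data.frame(condition = names(si), sparseness = si,
                                 mean_abs_corr = corr)
    objects$lobes <- list(natural = lobe_nat, shuffled = lobe_shuf)
  } else if (cfg$experiment == "tuning") {
    lobe <- .pretrain_lobe(prof, seed)
    posi <- population_osi(lobe, seed = sub_seed(seed, "osi"))
    unit <- which.max(posi$osi)
    ot <- orientation_tuning(lobe, unit, n_reps = 20,
                             seed = sub_seed(seed, "ot"))
    vt <- velocity_tuning(lobe, unit, angle = ot$preferred, n_reps = 10,
                          seed = sub_seed(seed, "vt"))
    contrasts <- seq(0.2, 1, by = 0.2)
    ct <- do.call(rbind, lapply(contrasts, function(cc) {
      otc <- orientation_tuning(lobe, unit,
                                angles = c(ot$preferred,
                                           (ot$preferred + 90) %% 360),
                                n_reps = 10, contrast = cc,
                                seed = sub_seed(seed, paste0("ct", cc)))
      data.frame(contrast = cc,
                 rate_pref = otc$curve$rate[1], rate_orth = otc$curve$rate[2])
    }))
    tables$orientation <- ot$curve
    tables$velocity <- vt$curve
    tables$contrast <- ct
    objects$lobe <- lobe
    objects$unit <- unit
    objects$orientation <- ot
    objects$velocity <- vt
  } else if (cfg$experiment == "scanning_conditions") {
    lobe <- .pretrain_lobe(prof, seed)
    conds <- expand.grid(region = c("lower_half", "lower_left", "whole"),
                         shift = c(0L, 15L, 45L), distal = c(FALSE, TRUE),
                         stringsAsFactors = FALSE)
    # drop geometrically impossible traverses (45-px quadrant scans)
    conds <- conds[!(conds$region == "lower_left" & conds$shift == 45L), ]
    pats <- list(make_pattern("plus"), make_pattern("multiplication"))
    rows <- lapply(seq_len(nrow(conds)), function(i) {
      pr <- run_protocol(conditioning_protocol(
        n_exposures = prof$n_exposures, n_bees = prof$n_bees,
        n_tests = prof$n_tests, region = conds$region[i],
        shift_px = conds$shift[i], distal = conds$distal[i],
        seed = sub_seed(seed, paste0("cond", i))),
        lobe, pats, n_kc = prof$n_kc)
      data.frame(region = conds$region[i], shift_px = conds$shift[i],
                 distal = conds$distal[i],
                 accuracy = 100 * pr$mean_accuracy,
                 sem = 100 * pr$sem_accuracy)
    })
    # control: a visual lobe without non-associative learning
    pr0 <- run_protocol(conditioning_protocol(
      n_exposures = prof$n_exposures, n_bees = prof$n_bees,
      n_tests = prof$n_tests, region = "lower_half", shift_px = 15L,
      seed = sub_seed(seed, "untrained")),
      init_visual_lobe(prof$n_lobula, seed = sub_seed(seed, "rawlobe")),
      pats, n_kc = prof$n_kc)
    rows[[length(rows) + 1L]] <- data.frame(
      region = "untrained_control", shift_px = 15L, distal = FALSE,
      accuracy = 100 * pr0$mean_accuracy, sem = 100 * pr0$sem_accuracy)
    tables$accuracy <- do.call(rbind, rows)
    objects$lobe <- lobe
  } else if (cfg$experiment == "generalisation") {
    lobe <- .pretrain_lobe(prof, seed)
    tasks <- list(
      bars_90 = list(make_pattern("bar", angle = 45),
                     make_pattern("bar", angle = 135)),
      plus_mult = list(make_pattern("plus"), make_pattern("multiplication")),
      spirals = list(make_pattern("spiral", handedness = 1),
                     make_pattern("spiral", handedness = -1)),
      gratings = list(make_pattern("grating", angle = 45),
                      make_pattern("grating", angle = 135)))
    rows <- lapply(names(tasks), function(nm) {
      pr <- run_protocol(conditioning_protocol(
        n_exposures = prof$n_exposures, n_bees = prof$n_bees,
        n_tests = prof$n_tests, region = "lower_half", shift_px = 15,
        seed = sub_seed(seed, nm)), lobe, tasks[[nm]], n_kc = prof$n_kc)
      data.frame(task = nm, accuracy = 100 * pr$mean_accuracy,
                 sem = 100 * pr$sem_accuracy)
    })
    tables$accuracy <- do.call(rbind, rows)
    objects$lobe <- lobe
  } else if (cfg$experiment == "population_size") {
    sizes <- c(4, 16, 36, prof$n_lobula)
    sizes <- sort(unique(sizes))
    pats <- list(make_pattern("plus"), make_pattern("multiplication"))
    rows <- lapply(sizes, function(nl) {
      lobe <- .pretrain_lobe(prof, seed, n_lobula = nl)
      pr <- run_protocol(conditioning_protocol(
        n_exposures = prof$n_exposures, n_bees = prof$n_bees,
        n_tests = prof$n_tests, region = "lower_half", shift_px = 15,
        seed = sub_seed(seed, paste0("size", nl))), lobe, pats,
        n_kc = prof$n_kc)
      data.frame(n_lobula = nl, accuracy = 100 * pr$mean_accuracy,
                 sem = 100 * pr$sem_accuracy)
    })
    tables$accuracy <- do.call(rbind, rows)
  } else if (cfg$experiment == "fixed_inhibition") {
    lobe_plastic <- .pretrain_lobe(prof, seed)
    lobe_fixed <- .pretrain_lobe(prof, seed, freeze_q = TRUE)
    osi_p <- population_osi(lobe_plastic, seed = sub_seed(seed, "osi"))
    osi_f <- population_osi(lobe_fixed, seed = sub_seed(seed, "osi"))
    tables$selectivity <- data.frame(
      condition = c("plastic_inhibition", "fixed_inhibition"),
      n_selective = c(sum(osi_p$selective), sum(osi_f$selective)),
      fraction_selective = c(osi_p$fraction, osi_f$fraction))
    objects$lobes <- list(plastic = lobe_plastic, fixed = lobe_fixed)
  }

  manifest <- list(experiment = cfg$experiment, profile = cfg$profile,
                   prof = prof, seed = seed,
                   package_version = as.character(utils::packageVersion("beevision")))
  if (!is.null(cfg$outdir)) {
    dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(tables)) {
      utils::write.csv(tables[[nm]],
                       file.path(cfg$outdir,
                                 paste0(cfg$experiment, "_", nm, ".csv")),
                       row.names = FALSE)
    }
    if (!is.null(objects[["lobe"]]) && requireNamespace("png", quietly = TRUE)) {
      write_image_png(rf_mosaic(objects[["lobe"]]),
                      file.path(cfg$outdir,
                                paste0(cfg$experiment, "_rf_mosaic.png")))
    }
  }
  structure(list(tables = tables, objects = objects, manifest = manifest),
            class = "results_bundle")
}

#' @export
print.results_bundle <- function(x, ...) {
  cat(sprintf("results_bundle: experiment '%s' (profile %s, seed %s)\n",
              x$manifest$experiment, x$manifest$profile, x$manifest$seed))
  cat("tables:", paste(names(x$tables), collapse = ", "), "\n")
  invisible(x)
}

#' Nonparametric comparison of accuracy groups
#'
#' Two groups: Wilcoxon signed-rank test for paired data, Wilcoxon
#' rank-sum (Mann-Whitney U) for independent samples. More than two
#' groups: Kruskal-Wallis, followed by Dunn's post hoc z-tests with
#' Holm-adjusted p-values.
#'
#' @param values numeric vector of outcomes (e.g. per-bee accuracies).
#' @param group factor of the same length.
#' @param paired logical; observations matched across two groups.
#' @param alpha significance level for the `significant` flags.
#' @return A data frame of test statistics, p-values and significance
#'   flags; for identical paired groups (all-zero differences) the p-value
#'   is reported as `NA` with a note.
#' @export
compare_conditions <- function(values, group, paired = FALSE, alpha = 0.05) {
  group <- factor(group)
  k <- nlevels(group)
  if (k < 2) stop("need at least two groups", call. = FALSE)
  if (k == 2) {
    g <- split(values, group)
    if (paired) {
      if (length(g[[1]]) != length(g[[2]])) {
        stop("paired comparison needs equal group sizes", call. = FALSE)
      }
      d <- g[[1]] - g[[2]]
      if (all(d == 0)) {
        return(data.frame(comparison = paste(levels(group), collapse = " vs "),
                          test = "wilcoxon_signed_rank", statistic = NA,
                          p_value = NA, significant = FALSE,
                          note = "all differences zero"))
      }
      wt <- stats::wilcox.test(g[[1]], g[[2]], paired = TRUE, exact = FALSE)
    } else {
      wt <- stats::wilcox.test(g[[1]], g[[2]], exact = FALSE)
    }
    return(data.frame(comparison = paste(levels(group), collapse = " vs "),
                      test = if (paired) "wilcoxon_signed_rank" else
                        "wilcoxon_rank_sum",
                      statistic = unname(wt$statistic), p_value = wt$p.value,
                      significant = wt$p.value < alpha, note = ""))
  }
  kw <- stats::kruskal.test(values, group)
  out <- data.frame(comparison = "omnibus", test = "kruskal_wallis",
                    statistic = unname(kw$statistic), p_value = kw$p.value,
                    significant = kw$p.value < alpha, note = "")
  # Dunn's post hoc: pairwise z on mean rank differences with tie correction
  n <- length(values)
  r <- rank(values)
  ties <- table(values)
  tie_corr <- sum(ties^3 - ties) / (12 * (n - 1))
  lv <- levels(group)
  prs <- utils::combn(lv, 2, simplify = FALSE)
  zrows <- lapply(prs, function(pr) {
    i <- group == pr[1]; j <- group == pr[2]
    z <- (mean(r[i]) - mean(r[j])) /
      sqrt((n * (n + 1) / 12 - tie_corr) * (1 / sum(i) + 1 / sum(j)))
    data.frame(comparison = paste(pr, collapse = " vs "), test = "dunn",
               statistic = z, p_value = 2 * stats::pnorm(-abs(z)),
               significant = NA, note = "")
  })
  zt <- do.call(rbind, zrows)
  zt$p_value <- stats::p.adjust(zt$p_value, method = "holm")
  zt$significant <- zt$p_value < alpha
  rbind(out, zt)
}
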