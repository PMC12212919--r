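# Shared fixtures, built once per test run and cached in this
# environment. Trainings use reduced scale (16 lobula units, small scene
# sets) so the whole suite stays fast.

.fixtures <- new.env(parent = emptyenv())

fixture_scenes <- function(n = 6, offset = 0) {
  key <- paste0("scenes", n, "_", offset)
  if (is.null(.fixtures[[key]])) {
    .fixtures[[key]] <- lapply(seq_len(n), function(i) {
      make_synthetic_scene(1000 + offset + i)
    })
  }
  .fixtures[[key]]
}

# a small visual lobe trained on structured scenes (used by metric and
# mushroom-body tests that need realistic sparse codes)
fixture_trained_lobe <- function() {
  if (is.null(.fixtures$lobe)) {
    cfg <- learning_config(n_patches = 3000, seed = 7)
    .fixtures$lobe <- suppressWarnings(
      train_visual_lobe(fixture_scenes(), cfg, n_lobula = 16))
  }
  .fixtures$lobe
}

# a hand-built lobe whose first unit is a vertical-bar template stepping
# left to right across the five delay slices (15 px per patch = 5 lamina
# columns per slice)
fixture_template_lobe <- function() {
  lobe <- init_visual_lobe(4, seed = 42, noise_scale = 0)
  lobe$W[] <- 0
  for (k in 1:5) {
    slice <- matrix(-0.05, 25, 25)
    centre <- 13 + (k - 3) * 5
    cols <- intersect(seq(centre - 1, centre + 1), 1:25)
    slice[, cols] <- 1
    lobe$W[1, k, ] <- as.numeric(slice)
  }
  lobe$Q[] <- 0
  lobe
}

expect_in_unit_interval <- function(img) {
  expect_true(all(img >= 0 & img <= 1))
}
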