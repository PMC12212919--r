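---
title: "An active-vision model of the bee optic lobe and mushroom body"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An active-vision model of the bee optic lobe and mushroom body}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model in one page

Bees recognise visual patterns while scanning them in short lateral
sweeps. `beevision` simulates a minimal version of the circuitry thought
to support this: a 75 x 75 photoreceptor sheet samples five sequential
image patches displaced by a fixed pixel shift (the scanning-speed
proxy); 625 lamina neurons each pool a non-overlapping 3 x 3
photoreceptor block through the sigmoid `f(r) = A0 / (1 + exp(m r + b))`
(`A0 = 1`, `m = -1`, `b = 0.5`); leaky integrate-and-fire medulla
neurons (`tau_m = 10` ms, `R = 10`, reset -80 mV, threshold 0 mV) relay
the lamina signal; and each wide-field lobula unit owns five medulla
"delay banks", one per patch, whose rates are buffered and summed at
the end of the sweep, so the unit integrates the whole scan at a single
synchronised instant. Lobula units inhibit each other through a
non-negative lateral matrix `Q`.

Two plasticity systems shape the model. Non-associative learning, driven
by mere exposure to scanned scenes, shapes the feed-forward tensor `W`
(Oja's Hebbian rule) and the lateral matrix `Q` (a symmetric
inhibitory-STDP rule whose fixed point sets pairwise co-activity to a
target `alpha`). Associative learning then trains a mushroom-body
classifier: the sparse lobula code is expanded through a fixed random
projection onto Kenyon cells (fewer than 5% active per stimulus by a
per-stimulus threshold), all of which converge on a single output neuron
(MBON) through plastic weights `D` updated by reward-modulated STDP —
octopamine-modulated depression for rewarded patterns, classical
dopamine-modulated STDP for punished ones. A trained bee "prefers" the
pattern that elicits the lower MBON rate.

## Design choices where the problem was genuinely open

**Multi-unit form of the Oja rule.** The single-unit rule
`dW = gamma * y * (x - y W)` has a unique attractor (the leading
eigenvector of the input autocorrelation), so a population of
independently updated units collapses onto one receptive field, and with
strictly positive lamina activity and a log-flat LIF transfer that field
is the uninformative luminance average: no oriented or signed structure
can emerge, and structured and pixel-shuffled training become
indistinguishable. We therefore apply the rule in its multi-unit
principal-subspace form (Sanger's generalised Hebbian algorithm on the
concatenated five-bank lamina signal): the decay term uses the
population reconstruction `sum_j y_j W_j` rather than each unit's own
projection. The self-term is exactly the single-unit rule (and
`oja_update()` implements it; the package's tests verify principal-
component recovery for a linear unit); the cross-terms implement the
normalisation across the population that the multi-unit rule
prescribes. The outcome is a set of signed, oriented, spatiotemporal
receptive fields that drift across the delay slices — motion-direction
filters — for structured scenes, and unstructured fields for shuffled
ones.

**Phasic lamina (temporal adaptation).** Lamina monopolar cells are
strongly adapting contrast coders, so each delay bank is driven by its
patch's deviation from the sweep-average activity of that lamina unit.
This one mechanism has three consequences that match the behavioural
phenomenology: a hovering bee (zero shift) drives the lobula only
weakly, because a static sweep is fully adapted away; lateral motion
refreshes the contrast signal at each step; and the learning signal
carries no sustained-luminance offset, which is what lets signed
receptive fields form. The same adapted signal is used in learning and
inference.

**Viewing geometry.** Patterns are drawn over ~150 px of a 280 x 280
canvas, so the 75-px eye window covers exactly the pattern's lower half
when scanning below the midline. Seeing the *whole* pattern within the
window then requires twice the reference viewing distance, implemented
as a 2x shrink onto the canvas, and the distal condition five times
(`distal_view()`); resolution loss with distance is what grades the
whole-pattern and distal conditions. The 280-px canvas is the smallest
round size that admits a 45-px-shift sweep (255 px traverse) and a
lower-left-quadrant scan at 15 px.

**Learning-rate and gain calibration.** The learning rates and the
iSTDP target are expressed in the units of the adapted lamina signal:
`gamma = 3e-3` keeps the Oja step a contraction once the weight norm has
relaxed to its equilibrium (entries of order 0.02; the convergence
threshold of 0.001-on-order-one weights rescales to `2e-5`);
`alpha = 0.04` sits between the measured co-activity of
structured-scene responses (~0.055) and shuffled-scene responses
(~0.005), so inhibition grows between genuinely co-active units and
decays everywhere else; `eta = 4e-3` lets the uniform random initial
inhibition decay fully within a 5000-scan exposure when co-activity is
absent. The input gains (`gain_me = 0.5`, `gain_lo = 0.003`) are fixed
constants calibrated once so that a trained unit's preferred
full-contrast moving bar elicits roughly 25-30 spikes/s.

**Reward-modulated STDP pairing.** Pairing every KC/MBON spike pair
symmetrically within +/-100 ms makes the antisymmetric dopamine kernel
integrate to approximately zero (we measured ~+0.0008 per KC per
trial), so punished patterns would never gain MBON drive. We use the
standard eligibility-trace reading instead: each KC spike leaves a
trace, and subsequent MBON spikes within five kernel time constants
convert it with `stdp_kernel(t_post - t_pre)`. Coincident spikes
(`dt = 0`) contribute nothing. Conditioning integrates over the full
500-ms sweep; the choice test reads the MBON spike count over a single
100-ms glance, which is the dominant behavioural noise source and
produces the graded accuracies across scanning conditions.

**Other defaults.** 2000 Kenyon cells with projection weights uniform on
`[0, 0.25]`; readout weights initialised uniform on `[0.4, 0.6]` so the
untrained MBON responds equally to any two patterns; lateral-inhibition
fixed points solved by adaptively damped iteration (initial damping 0.3,
halved whenever the residual grows; tolerance 1e-3 spikes/s, up to 250
iterations, non-convergence flagged); presentation 100 ms
per patch at a 0.1-ms Euler step; orientation probed on a 30-degree
grid with the orthogonal response averaged over both motion directions.

## What the synthetic scenes emulate — and what they do not

The training corpus of flower and nature photographs is replaced by
`make_synthetic_scene()`: a 1/f-type Gaussian random field (power-law
slope ~ -2.3 on log-log axes, lag-1 pixel correlation > 0.8) with
superposed soft-edged strokes at random orientations, and a per-scene
mean brightness drawn from [0.3, 0.55] — natural photographs vary widely
in overall luminance, and scenes are kept below mid-grey on average
because the lamina sigmoid saturates for bright fields. Pixel shuffling
(`shuffle_image()`) preserves the intensity histogram exactly while
destroying all spatial structure, reproducing the structured-versus-
shuffled training contrast. These surrogates carry second-order
statistics and oriented edges but none of the higher-order structure of
real photographs (objects, occlusion, textures), so quantitative
agreement with experiments that used real images is only expected at
the level of orderings and bounds, not percentages.

## Reduced-scale profile and known limitations

Simulations in the tests and the acceptance script use the fast
profile — 16 lobula units, 8 scenes, 5000 training scans, cohorts of
8-20 bees — chosen so a full run completes in minutes; the paper-scale
profile (50 units, 50,000 scans, 20 bees x 50 tests) is available
through `sim_profile("paper")`.

Three reported phenomena do not reproduce under this implementation,
and the corresponding checks are expected to fail honestly rather than
being relaxed:

* *Pre-to-post decrease of pairwise response correlation.* With signed
  random initial weights and the adaptation stage, pre-training
  responses are already at the decorrelated sampling floor
  (mean |off-diagonal| ~ 0.13); training yields sparse responses whose
  co-silence adds a small positive correlation (~0.15). The
  post-training code *is* decorrelated — the near-diagonal correlation
  matrix holds — but it is not *more* decorrelated than the untrained
  baseline here.
* *Untrained-lobe control at chance.* An untrained lobe (random signed
  weights, random inhibition) still yields reliable, distinct sparse
  codes that the Kenyon-cell expansion separates, and conditioned bees
  discriminate the two patterns well above chance. Scale-matched
  normalisation of the untrained weights and the frozen-inhibition
  variant were both evaluated and neither brings the control to chance.
* *Whole-pattern and fast-scan accuracies near 63% and 70%.* The
  orientation-energy difference between a plus and a 45-degree-rotated
  plus survives both the 2x resolution loss of whole-pattern viewing
  and the bank misalignment of fast scanning, so the model scores
  ~89-98% (whole) and ~72-88% (fast) depending on cohort scale, where
  the reference reports 63% and 70%. The orderings (local slow scan >
  whole pattern > hovering; distal at chance) do reproduce.
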