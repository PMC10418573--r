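---
title: "Comparing human gaze attention with classifier saliency: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing human gaze attention with classifier saliency: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gazecompare)
```

## The problem

When clinicians assess facial photographs for signs of a genetic condition,
where do they look — and does a deep-learning classifier "look" at the same
places? gazecompare implements a quantitative pipeline for that question:
fixation-level eye-tracking data from two participant groups (geneticist
clinicians and non-clinicians) viewing a panel of aligned facial stimuli is
turned into attention heat maps, cleaned of generic face-viewing behaviour,
and compared — between participant subgroups and against
occlusion-sensitivity saliency maps of a classifier — with the
intersection-over-union (IoU) of thresholded masks, pooled across stimuli by
a random-effects model.

The study design the defaults mirror: 22 clinicians and 22 non-clinicians
each view 16 aligned facial images (10 showing a genetic condition, 6
unaffected) for 7 seconds per image, then judge each image
affected/unaffected and optionally name the condition.

## From fixations to attention maps

A fixation deposits mass equal to its duration (ms) through a radially
decreasing kernel centred at its position. The kernel support radius is
**25 px** — the rendering radius used for the study's heat maps — and the
default shape is linear falloff $1 - d/r$ (Gaussian and flat kernels are
config options; the eye-tracker vendor does not document its exact kernel,
and the downstream statistics depend only weakly on the shape because maps
are later thresholded by quantile). Fixation centres outside the image are
clipped to the boundary: partially off-screen gaze still carries signal.

Each participant's map is normalized to unit mass before group averaging so
participants with longer total fixation time do not dominate. Group
averages are the plain cell-wise mean of the normalized maps.

## Common-attention subtraction

Everyone looks at the eyes, nose, and mouth. That shared behaviour swamps
group differences, so for each group the average map over *all* stimuli
(its common attention pattern) is subtracted from each per-stimulus group
average, and negative residuals are clipped to zero — residual attention
measures where a stimulus drew *more* gaze than the group's generic
face-viewing pattern. Two deliberate choices:

* Subtraction happens at the group-average level by default (a
  per-participant variant is available via
  `preprocess_config(per_participant = TRUE)`); whether the original
  analysis subtracted before or after per-image scaling is not documented,
  so the order used here is fixed and stated.
* Residuals are *not* renormalized: absolute residual attention is
  meaningful, and renormalizing would inflate near-empty residuals.

Residual maps are box-smoothed (default **11 px**, truncated mean at the
borders so constant maps are fixed points and no mass is invented). The
final "increase the colour intensity" step of rendered figures is
display-only and not part of the analysis path.

## Dual-threshold masks and IoU

An attention map is binarized at a quantile of its **nonzero** values —
most of a face image is zero-attention background, and including it would
make any threshold degenerate. Two threshold kinds are used throughout:

* **low** (default q = 0.25): removes only spurious noise;
* **high** (default q = 0.75): keeps only the regions of highest attention.

The original analysis does not state its threshold values numerically, so
these quantiles are explicit configuration, and every comparison is
reported at both kinds. A cell enters the mask when it strictly exceeds the
threshold, so the low mask always contains the high mask. Two masks are
compared with $\mathrm{IoU} = |A \cap B| / |A \cup B|$; the degenerate
empty-vs-empty case is defined as 0 (with a warning) so meta-analysis
inputs stay finite.

## Uncertainty and pooling

The sampling unit is the participant, so bootstrap uncertainty for a
per-stimulus IoU resamples participants with replacement within each group
independently (default **1000** replicates), recomputing average →
subtraction → smoothing → binarization → IoU per replicate; the standard
error is the SD of the replicates. Degenerate single-member groups get an
SE floor of $10^{-6}$ so weights stay finite.

Per-stimulus effects are pooled across stimuli with DerSimonian–Laird
random-effects meta-analysis: fixed weights $w_i = 1/se_i^2$, heterogeneity
$Q = \sum w_i (y_i - \bar y_w)^2$,
$\tau^2 = \max\!\big(0, (Q - (k-1)) / (\sum w_i - \sum w_i^2/\sum w_i)\big)$,
random-effects weights $w_i^* = 1/(se_i^2 + \tau^2)$, pooled effect
$\sum w_i^* y_i / \sum w_i^*$ with a 95% normal CI
$\pm 1.96 (\sum w_i^*)^{-1/2}$. Raw IoU values are pooled (a logit
transform was considered and rejected as the default because IoU values
near 0 occur legitimately for disjoint masks and the transform is
undefined there). `method = "FE"` forces $\tau^2 = 0$ and reduces exactly
to fixed-effect inverse-variance pooling. The DL normal CI is known to
undercover modestly when $\tau$ dominates the within-stimulus SEs; with
SEs on the scale this pipeline's bootstrap produces (about 0.05–0.08 for
22-participant groups) coverage is close to nominal.

## Occlusion saliency

For a classifier exposed through `classifier_adapter()` (a `predict`
function returning a probability vector; inputs resized to **448 × 448**
by convention), saliency is measured by occlusion: slide a **20 × 20 px**
box on a **10 px** stride over the image, replace the box content with a
fill value, and record the drop in the probability of the probed label.
Each pixel's saliency is the mean drop over all boxes covering it (every
interior pixel is covered by exactly 4 boxes at the default geometry; the
stride grid is extended so the last box touches the image edge). Choices
the original description leaves open, fixed here:

* drop attribution: over the whole box footprint (smooth, the standard
  occlusion-map convention); centre-cell attribution is a config option;
* fill value: per-channel image mean by default (smallest distribution
  shift), `gray` (0.5) and `zero` as options;
* negative drops (occlusion *raises* the probed probability) are clipped
  to 0, consistent with nonnegative rendered saliency maps.

Ensemble saliency (e.g. from cross-validation folds) is the plain cell-wise
mean. For comparison against human attention both maps are binarized at
the *same* threshold kind, after nearest-neighbour resampling of the
saliency map to the attention map's resolution (nearest-neighbour preserves
mask topology). Training the deep classifier itself is out of scope; the
adapter contract lets a trained model plug in, and the analytic
`toy_classifier()` (logistic in the summed intensity of a known target
region) provides a classifier whose saliency ground truth is known exactly.

## Cohort accuracy analysis

Affected/unaffected judgments are tabulated into a 2 × 2 group ×
correct/incorrect table (missing responses dropped and counted; real
eye-tracking studies rarely have complete cells). Accuracy is reported per
group to one decimal. The association test is the **uncorrected** Pearson
chi-square with 1 df: at per-response counts of this size the continuity
correction is unnecessary and the uncorrected statistic is the one that
reproduces the published analysis this package re-implements. AOI metrics
(total dwell time and time to first fixation inside an analyst-drawn
polygon) use a boundary-inclusive even-odd point-in-polygon rule on
fixation centres; a "whole fixation" is interpreted as
centre-inside-polygon, the weakest defensible reading.

## The synthetic study generator

No eye-tracking dataset is distributed with the source study, so
`gen_stimuli()` / `gen_fixations()` / `gen_responses()` synthesize one with
known ground truth. Gaze is a Gaussian mixture: three **common**
components at fixed eyes/nose/mouth layout positions (weights
0.3/0.3/0.2/0.2 across left eye, right eye, nose, mouth; SD 4% of the
image side) shared by all stimuli, plus one **stimulus-specific**
component per stimulus (SD 3% of the side, centre placed away from the
common components) — the planted "dysmorphic feature". Clinicians give the
specific component more weight (defaults 0.30 vs 0.15), emulating expert
attention to diagnostic features;
`separate_group_components = TRUE` instead gives each group its own,
mutually distant component (groups attend *different* features). Fixation
counts are Poisson (mean 20 per 7 s trial), durations Gamma(shape 2, mean
300 ms — the typical fixation duration scale), onsets sequential with
20–60 ms saccade gaps, rescaled when needed so every trial fits the
viewing window. Judgments are Bernoulli at the group target accuracies
(defaults 85.6% / 76.9%). All generators are pure functions of
(config, seed).

What the generator does **not** emulate: saccade dynamics and scan-path
order structure, inter-stimulus correlation of individual viewing styles,
calibration drift and other instrument noise, anisotropic or off-face
attention, and of course real faces (stimulus images are smooth random
fields with brightened component regions). Tests passing on this generator
therefore demonstrate that the *pipeline* recovers planted structure and
that its statistics behave correctly — not that any particular effect size
will be observed in real cohorts.

### What "identical groups" should look like

With identical mixture profiles for both groups, the per-stimulus group
*averages* binarize to near-identical masks (pooled low-threshold IoU above
0.9 at the default cohort size). The *residual* maps of identical groups,
however, are dominated by independent sampling noise — after subtracting
the common pattern there is no systematic signal left to agree on — so
residual-level IoU for identical groups sits far lower and is not a
meaningful identity check. The test suite therefore asserts the identity
on group averages and uses residuals where they carry signal: with
disjoint group-specific components, residual masks at the high threshold
are nearly disjoint (pooled IoU close to 0) while low-threshold masks
retain diffuse overlap, reproducing the qualitative
high-threshold-divergence pattern seen in expert/novice comparisons.

## Numerical and degenerate-input conventions

* Coordinates are 0-based, origin top-left, x = column, y = row, matching
  raster conventions; `map_argmax()` reports in the same system.
* Quantile type 7 (R default) everywhere; masks use strict `>`.
* All-zero maps binarize to empty masks; empty ∪ empty IoU is 0 with a
  warning; `normalize_map()` refuses all-zero input (callers must treat
  absent data explicitly).
* Box smoothing truncates the window at borders and averages over
  in-bounds cells, so constants are fixed points; kernel 1 is the
  identity; even kernels are rejected.
* Heat-map colour decoding matches within Euclidean RGB distance 16
  (anti-aliasing at edges produces blends); farther pixels map to the
  nearest code with a warning reporting the off-palette fraction.
* Continuous maps persist as 16-bit grayscale TIFF plus a JSON sidecar
  recording the scale; encode/decode of the 3-level colour scheme is an
  exact round trip.
* Fixation rows with missing coordinates are dropped (counted); rows with
  non-numeric coordinates are an error naming the line; off-image
  coordinates are clipped, not dropped.

## Problem sizes used by the test and acceptance runs

The full study geometry is 448 px stimuli with 22 + 22 participants and 16
stimuli. The planted-feature recovery check runs at that full scale. The
group-comparison and directional checks run on 224 px renders with 100–200
bootstrap replicates — at those sizes per-stimulus bootstrap SEs are
stable within 20% across seeds, and the pooled estimates are unchanged in
the second decimal relative to larger renders — and the coverage
simulation draws per-stimulus SEs from 0.05–0.08, the range the pipeline's
own bootstrap produces at that scale. These sizes are the package's
choices for routine verification; all of them are configuration, not
constants.

## Limitations

* The comparison treats saliency maps "as if they were heat maps"; IoU of
  thresholded masks is a deliberately coarse, threshold-dependent
  similarity — report both thresholds, never one.
* Raw-IoU pooling and participant-level resampling are stated
  interpretations of an under-specified original analysis; both are
  config-visible.
* DL random-effects CIs undercover when between-stimulus heterogeneity is
  large relative to within-stimulus error; with very few stimuli prefer
  wider skepticism than the CI suggests.
* The AOI timing metrics are descriptive; with one 7 s trial per stimulus
  per participant they have high variance, and the package deliberately
  offers no significance machinery for them.
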