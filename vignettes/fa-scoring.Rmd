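---
title: "Quantifying RPE disease area from early-phase FA image pairs"
author: "fascore"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying RPE disease area from early-phase FA image pairs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fascore)
```

## The problem

Retinal pigment epithelium (RPE) atrophy — the substrate of geographic
atrophy in age-related macular degeneration and the outcome measure for
RPE-transplantation studies — appears in early-phase fluorescein
angiography (FA) as a *window defect*: mottled hyperfluorescence where the
choroidal background shines through missing RPE. Quantifying how this area
changes between visits is hard for three reasons: the hyperfluorescence is
speckled with unclear boundaries, every capture carries its own smooth
luminance slope and brightness/contrast, and frames from different visits
are translated, rotated, scaled and skewed against each other.

`fascore` implements a two-step pipeline for this problem:

1. **Abnormal-region mask.** A segmentation model (or a clinician
   annotation file, or synthetic ground truth) marks the overall abnormal
   region of each frame. The mask filters out everything the score should
   not see — healthy retina and most of the vasculature.
2. **Mask-restricted binarized scoring.** The pair is registered
   (FAST corners, BRIEF descriptors, RANSAC affine), photometrically
   normalized (division by a sigma = 70 px Gaussian background, then
   histogram matching), binarized at 1.2 x the mode intensity, and the
   hyperfluorescent pixels inside the **union** of the two masks are
   counted per image. The *Score* is that count; the *Growth rate* is
   `(test score - reference score) / reference score`.

Vessels inside the mask are counted in both Scores and therefore cancel in
the numerator of the Growth rate; vessels outside the mask never enter.

## Pipeline stages and their parameters

| Parameter | Default | Units | Meaning |
|---|---|---|---|
| frame size | 496 x 496 | px | canonical 8-bit grid after preprocessing |
| `sigma` | 70 | px | Gaussian background scale for illumination removal |
| `multiplier` | 1.2 | — | binarization threshold as a multiple of the mode |
| `probThreshold` | 0.5 | — | segmenter probability cutoff |
| `residualThreshold` | 3 | px | RANSAC inlier radius |
| `ransacMaxIter` | 2000 | — | RANSAC iteration cap (adaptive early stop) |
| `fastThreshold` | 20 | 8-bit levels | FAST segment-test contrast |

Preprocessing rescales any input to 496 x 496 with order-0 (nearest)
sampling — no anti-aliasing — so binary annotation masks survive the
rescale without new gray levels; non-square inputs are rescaled
anisotropically (no letterboxing). RGB-encoded grayscale exports are
collapsed by channel average.

**Mode estimation.** The corrected (ratio-unit) image is quantized into
256 uniform bins over its observed range; the mode is the centre of the
most populated bin, ties broken toward the lower bin. By default the mode
is taken over the whole valid frame; `modeWithinMask = TRUE` restricts it
to the merged mask. Binarization uses a strict `>` at
`multiplier x mode` (boundary pixels are background; configurable by
changing the multiplier).

**Registration direction.** The transform maps *aligned* (test) image
coordinates onto the *reference* frame; the test image and its mask are
resampled onto the reference grid (images bilinearly, masks with nearest
neighbour so they stay binary). Pixels that leave the frame are flagged in
a validity mask that every downstream stage honours: modes, thresholds and
both Scores are computed over mutually valid pixels only, so frame edges
cannot bias the Growth rate asymmetrically.

**Histogram matching** remaps the test image's 256-bin intensity CDF onto
the reference's (monotone, reference untouched; direction swappable with
`matchDirection`). Two caveats discovered while validating the pipeline
are worth knowing:

* Exact histogram specification equalizes the pair's *global* intensity
  distributions. Because the binarization threshold is itself
  distribution-linked (1.2 x mode), the global above-threshold counts of
  the two images become nearly equal; what the Growth rate then measures
  is the *redistribution* of bright pixels relative to the merged mask.
  Genuine in-mask growth is attenuated — in default synthetic scenes about
  half of a +20% mottle increase survives, and the attenuation grows as
  the out-of-mask bright population (vessels) shrinks. Clinical pairs
  selected for equal vessel brightness need only a mild touch-up from
  matching, so the attenuation there is modest. For photometrically
  calibrated pairs, `faConfig(matchHistograms = FALSE)` disables matching
  and makes the Growth rate track ground-truth counts exactly.
* Strong inter-visit transforms change which anatomy falls inside the
  mutually valid region; matching then redistributes ranks across the
  composition change. Growth rates between heavily transformed pairs carry
  a negative bias of several percent for this reason.

## The synthetic study conditions

No public FA dataset with annotated RPE-disease regions exists, so the
package ships a generator whose scenes back every test:

* **Vessel tree** — recursive branching random walk with decreasing
  calibre (3 px trunks), giving FAST-detectable corners at bifurcations,
  which is exactly what the registration stage keys on in real FA frames.
* **Lesions** — one or two blobs with harmonic-modulated radii of
  0.12-0.22 of the frame side (60-110 px at 496), plus a small diffuse
  elevation (+10 of 255) of the lesion interior, as window defects show
  diffuse hyperfluorescence beneath the speckle.
* **Mottle** — band-pass noise (sigma 2/4.5 px) thresholded inside the
  lesion at a 30% fill fraction; multi-pixel speckle patches, not
  single-pixel noise, matching the scale of real mottled
  hyperfluorescence. The mottle gain (+70) places speckle near 1.4 x the
  local background after flattening, clearly above the 1.2 x threshold.
* **Illumination** — a low-order slope plus a broad Gaussian bump, capped
  at +/-30%, which the sigma = 70 division must remove.
* **Pairs** — the aligned frame is *re-rendered* from the ground-truth
  layers resampled through the true affine transform (a second capture of
  the same eye is sharp, not an interpolated copy), with optional
  gain/offset shifts and Gaussian sensor noise.

Everything is a pure function of its parameters and a seed. What the
generator does **not** emulate: choroidal texture, late-phase leakage
dynamics, halo artifacts, haemorrhage (except as a mottle-blocking blob in
the discrepancy tests), and real annotation ambiguity. Passing tests on
these scenes therefore validate the *mechanics* of the pipeline — not its
clinical accuracy, which requires clinical data.

## The segmentation model

The abnormal-region segmenter is a small U-net-family encoder-decoder
implemented natively in R (im2col convolutions over BLAS): 3 resolution
levels, 8 base channels doubling per level, two 3 x 3 convolutions per
level with ReLU, 2 x 2 max-pooling, nearest upsampling with skip
concatenation, a 1 x 1 sigmoid output, binary cross-entropy loss (Dice
optional) and Adam. Inputs are scaled to [0, 1] and subsampled to a 62 x
62 grid (factor 8); predictions are nearest-upsampled back. The coarse
grid is a deliberate choice: lesions span tens of pixels even at 62 x 62,
the receptive field covers most of a lesion, and thirty epochs over fifty
scenes train in under two minutes on one CPU while reaching ~0.91
sensitivity and ~0.96 specificity on held-out scenes. The probability
threshold (0.5 default) trades sensitivity against specificity in the
usual way, and `predictMask` is monotone in it.

The mask source is deliberately pluggable (`model`, `annotation_file`,
`synthetic_truth`): the scoring pipeline is fully exercisable without any
trained model, which is also how a clinic with its own annotation workflow
would run it.

## The trend test

Agreement with clinician judgment is assessed with the
Jonckheere-Terpstra test for an increasing trend of Growth rate across
ordinal worsening ranks (1 approximately the same < 2 slightly worse < 3
much worse). The statistic sums pairwise Mann-Whitney counts with 1/2
weight on ties. For pooled n <= 10 the p-value is computed by exhaustive
permutation over all assignments of the observed values to the group
sizes; above that, a normal approximation with tie-corrected variance is
used (continuity correction off by default; the two agree to well under
0.02 by n = 9-12). The one-sided increasing alternative is the default
because a worsening rank hypothesizes a larger Growth rate.

## Numerical choices and degenerate inputs

* Gaussian blurs use exact reflected boundaries, implemented as dense
  banded-operator matrix products.
* Division guard: background values below `1e-6 x max` are clamped;
  an all-zero frame yields an all-zero corrected image with a warning.
* A constant reference histogram maps the test to that constant (warning).
* Mode ties break toward the lower bin; an all-invalid frame is an error.
* A zero reference Score makes the Growth rate *undefined* (`NA`), never
  infinite.
* RANSAC is seeded and uses adaptive iteration counts; fewer than three
  matches raises a classed fallback condition pointing at the
  correspondence-CSV route rather than failing silently.
* Scenes are drawn and restored under a private RNG scope, so generating
  fixtures does not disturb the caller's RNG state.

## Problem sizes used in the shipped checks

The test-suite and the acceptance script regenerate all inputs at run
time: 20 full-size scenes for the scoring oracle, 50 transformed pairs
(rotation <= 10 degrees, scale 0.9-1.1, translation <= 30 px, 30% injected
outlier matches) for registration recovery, 50 same-scene pairs with
photometric jitter, sensor noise and small recapture motion for the
same-day stability analogue, 2000 null replicates at group sizes 3/3/3
for trend-test calibration, and a 50-scene / 10-held-out split for the
segmenter. These sizes were chosen so the whole battery runs on a single
CPU in minutes while keeping every estimate's Monte-Carlo error well below
the tolerance it is checked against.

## Known limitations

* The Growth rate underestimates progression when new hypofluorescent
  blocking (haemorrhage, lipid) appears inside an enlarging lesion; the
  series runner flags exactly this signature (mask area up, Growth rate
  down) rather than pretending to resolve it.
* Histogram matching attenuates genuine in-mask growth (see above).
* Strongly transformed pairs carry a residual negative growth bias from
  resampling and valid-region composition changes.
* The binarization threshold is sensitive to non-smooth photometric
  artifacts (halos); such frames should be excluded upstream, as the
  pipeline has no halo detector.
* Synthetic training data cannot certify clinical segmentation accuracy;
  the shipped model architecture is a desk-scale surrogate, and clinical
  use requires training on annotated clinical frames via the same
  `trainSegmenter` interface.
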