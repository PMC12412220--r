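---
title: "Methods: image-spectrum fusion and attention-augmented residual networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: image-spectrum fusion and attention-augmented residual networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(seedfuse)
```

This vignette records the model, the procedure, and the design decisions
behind `seedfuse` — what is computed, under which assumptions, and where
the genuinely open choices were resolved.

## The task and the data model

The package targets seed-variety classification from two paired
modalities per seed: an RGB crop cut from a multi-seed board photograph,
and a point reflectance spectrum over 350–2500 nm at 1 nm steps (2151
values, the native range of VNIR/NIR/SWIR field spectroradiometers; the
grid is fixed package-wide by `wavelengthGrid()`). The study conditions
the package emulates are 8 varieties with 1600 seeds each (12,800 seeds),
split 7:2:1 into training/validation/test, one spectrum per seed.

Real acquisitions of this kind are private; the synthetic-data module
generates the same structure so that every downstream stage is testable:

* **Appearance.** Each variety is a colour/shape/texture prototype: seeds
  are filled, rotated ellipses (semi-axes drawn per class in roughly
  15–22 × 10–14 px, jitter SD 1.2 px, never below 8 px so seeds stay
  segmentable) with per-seed colour jitter (SD 6 intensity units) and
  multiplicative per-pixel texture (amplitude 0.08), on a dark board
  (intensity 30) with mild sensor noise (SD 1.5). Variety colours are
  confined to a luminance band of about 125–185: bright enough that every
  seed pixel clears a background/seed threshold, and narrow enough that
  Otsu's criterion always prefers the background/seed split over a split
  between seed classes — with a minority foreground, between-class
  variance is weight-sensitive, and an unconstrained colour spread could
  make a bright-seed/rest split optimal, silently dropping dark seeds.
* **Spectra.** Each variety has a smooth archetype: baseline plus gentle
  slope plus three broad Gaussian bumps (widths 80–260 nm), clipped to
  [0.02, 0.95], with i.i.d. additive Gaussian noise (SD 0.02, clipped to
  [0, 1]) per sampled seed. Archetypes are pairwise distinct, and a
  nearest-archetype classifier attains 100% on noiseless spectra — the
  synthetic task is learnable by construction.
* **Modality switches.** `colorGroups`/`spectralGroups` collapse either
  modality's signal: with `colorGroups = 4, spectralGroups = 2` for 8
  classes, colour identifies a class only up to pairs and the spectrum
  only up to quadruples, while the pair (colour, spectrum) is unique.
  This is the configuration under which a fusion benefit is a property of
  the data rather than an accident.
* **Boards.** Seeds are placed by rejection sampling with a minimum
  centre separation (default 80 px, comfortably above twice the maximum
  seed radius plus the morphological closing reach, so seeds never touch)
  and a border margin; 10,000 failed placement attempts raise a capacity
  error. All generators are pure functions of explicit integer seeds:
  randomness is scoped with a save/restore of the RNG state, and child
  seeds are derived arithmetically (kept below 2^31), so no global state
  leaks between calls.

What the generator does **not** model: specular highlights, dust,
touching or overlapping seeds, illumination gradients, camera optics.
Passing tests therefore demonstrate correctness of the pipeline's
mechanics and the claimed properties on clean, well-separated seeds — not
robustness to field imagery.

## Segmentation

`segmentBoard()` composes four steps, each exposed separately:

1. Grayscale by BT.601 luminance (0.299 R + 0.587 G + 0.114 B), kept in
   floating point until thresholding (no intermediate rounding).
2. Automatic global thresholding by Otsu's criterion over 256 histogram
   bins ("automatic global thresholding" names no algorithm; Otsu is the
   standard choice). Foreground polarity is chosen as the minority class
   (fraction ≤ 0.5): seeds occupy a small part of a board whether they
   are brighter or darker than it, which also makes the crop geometry
   invariant under brightness inversion. A separability guard (between-
   class variance over total variance at the chosen threshold < 0.7, vs.
   ≈ 2/π ≈ 0.64 for a unimodal noise image and > 0.95 for a real seed
   board) classifies seed-free boards as empty rather than thresholding
   noise.
3. Morphological opening then closing with a disc of radius 2 (an
   idempotent filter), then removal of components below 64 px — a speck
   floor well under the smallest plausible seed (≈ 200 px).
4. 8-connected component extraction (4-connected labeling plus diagonal
   equivalence merging), centroid-centred square windows of side
   max(bbox side, 32), edge replication at borders, bilinear resize to
   224×224, returned in row-major centroid order.

Touching seeds are deliberately not split (no watershed): the generator
never produces them and the upstream protocol keeps seeds separated.

## Spectral preprocessing and curve images

Savitzky–Golay filtering (window 11, polynomial order 3 — the common
spectroscopy default; both exposed) smooths each curve while passing
polynomials up to the fitted order through unchanged, including at the
endpoints (boundary windows are fitted with the same polynomial).
Normalisations that renormalise amplitude (SNV, MSC, derivatives) are
deliberately excluded: the rasterised curve's shape and amplitude are the
features.

`renderCurveImage()` maps wavelength linearly onto columns 1–224 and a
y-range onto rows 224–1 (larger reflectance = higher), draws the polyline
1 px thick with Bresenham segments, black on white, no anti-aliasing —
rendering is bit-exact and a pure function of curve and range. Axes,
ticks and margins are presentation, not information, and are omitted.
The y-range should be dataset-global (the experiment helpers use the
archetype range ± 0.1) so between-class amplitude differences survive;
per-curve `"auto"` is available but renormalises each curve. Out-of-range
values clip to the border rows; a constant curve under `"auto"` widens
its range by ±0.5 rather than failing.

## Fusion and splits

A fused sample is the 224×448×3 horizontal concatenation (crop left,
pseudo-RGB curve right); it is invertible by construction. The network
input contract is 224×224×3, so `prepareModelInput()` bilinearly resizes
the composite by default — feeding the unresized 224×448 composite is
supported (global average pooling accepts any spatial size) but resizing
is the default because the input-size contract is explicit. Intensities
are scaled to [0, 1]; per-channel standardisation is optional and off by
default. Splits are stratified 7:2:1 with per-class shuffling and
largest-remainder apportionment (ties resolved train > val > test), so
1600-seed classes split exactly 1120/320/160. Fusion happens before
splitting, so a seed's crop and spectrum can never land in different
groups.

## The network family

Standard residual networks: basic blocks for depths 18/34, bottleneck
blocks (1×1–3×3–1×1, expansion 4) for 50/101; stage widths
64/128/256/512; 7×7 stride-2 stem with 3×3 stride-2 max pooling; global
average pooling and a fully connected head. Attention blocks are
inserted once after the *last* residual block of each configured stage
(default conv2 and conv3) — stage-level insertion matches the design the
package follows; per-block insertion was considered and rejected as a
different architecture, not a variant. DSC replaces only the 3×3
convolutions (1×1 convolutions are already pointwise) of the configured
stages (default conv4; conv4+conv5 available), each factor followed by
batch normalisation.

Attention parameters: SE/CBAM share reduction r = 16; CBAM's spatial
kernel is 7×7; ECA uses γ = 2, b = 1 with kernel size = nearest odd
integer to log₂(C)/γ + b, ties rounded up, floored at 3 — the rounding
rule is fixed here because bracket notation alone does not define one.
The pooled-descriptor MLPs carry no biases, matching the published
equations; sigmoid outputs keep all attention weights strictly inside
(0, 1).

All layers are implemented in the package (batched forward and backward;
grouped/depthwise convolution via an im2col + BLAS Rcpp kernel) because
no deep-learning framework exists in the supported R stack. Correctness
rests on two oracle families in the tests: closed-form evaluations of the
attention equations, and central finite-difference gradient checks
through a composite network containing every layer type (agreement ~1e-6
relative; batch norm's curvature at tiny spatial sizes limits tighter
bounds).

## Training protocol

Momentum SGD on softmax cross-entropy: learning rate 0.001, momentum 0.9,
weight decay 0.01, batch size 8, 50 epochs, no schedule, final-epoch
model reported (no early stopping). Cross-entropy is the standard choice
for a softmax head. He-normal initialisation for conv/FC weights, BN
scale 1/shift 0, running statistics with momentum 0.1 and ε = 1e-5.
Initialisation and shuffling derive from explicit seeds; identical data
and seeds reproduce identical runs bit for bit.

## Metrics and statistics

Per class, one-vs-rest TP/FN/FP/TN yield specificity, recall, precision
and F1; accuracy is trace/total. Macro (unweighted) averaging is used
because the emulated classes are balanced; 0/0 ratios are defined as 0
with a warning. Repeated-run summaries use Student-t confidence intervals
(default 95%) and classical one-way ANOVA (F = MS_between/MS_within,
df (k−1, N−k)); identical group means give F = 0, p = 1, while zero
within-group variance is rejected as degenerate. Calibration is
property-tested: interval coverage for n = 10 normal samples falls in
93–97%, and the ANOVA type-I error rate at α = 0.05 falls in 3–7% under
the null.

## Desk-scale experiment design

Two experiments make the package's qualitative claims checkable on one
CPU:

* **Fusion benefit** (`fusionBenefit()`): 8 classes × 100 seeds with the
  crossed modality switches, depth 18, 5 epochs, 3 seeds, inputs resized
  to 32×32, batch 32 for this experiment. 32×32 retains the colour and
  coarse curve-shape signal while keeping nine training runs within
  minutes; batch 32 (rather than the protocol default 8) reduces
  per-batch overhead without changing the comparison, which holds all
  optimisation settings fixed across modalities. Expected outcome, and
  the tested property: mean fused accuracy strictly exceeds both
  single-modality accuracies (neither modality alone identifies all 8
  classes; together they do).
* **Ablation grid** (`ablationGrid()`): the 8 combinations of the
  fusion/CBAM/DSC flags on a shared split with per-repeat seeds, mean
  accuracy plus analytic profile columns (params in millions, GFLOPs).
  The profile columns use the conventional 224×224×3 input and 1000-way
  head so they read like standard architecture tables; training uses the
  task head (8 classes) at whatever input size the data were prepared at.

## Profiling conventions

`profileModel()` counts parameters (conv + BN + FC + attention weights)
and multiply–accumulates (k_h·k_w·C_in·C_out·H_out·W_out per convolution,
divided by groups; in·out per FC layer; BN/activations/pooling excluded)
analytically from the architecture descriptors. Profile mode uses a
1000-way head — the convention under which the depth-50 baseline reads
25.6 M parameters and ≈ 4.09 GFLOPs. Published cost tables for
attention/DSC variants of this architecture family are not exactly
additive under any single insertion scheme, so beyond the baseline the
package asserts cost *orderings* (DSC < baseline < baseline + CBAM for
both parameters and MACs) rather than third-party point values.

## Numerical choices and degenerate inputs

* Otsu on a constant image: degenerate-input error (no separable
  classes); `segmentBoard()` maps seed-free boards to zero crops via the
  separability guard instead.
* Empty mask: empty crop list with a warning, not an error.
* BN at spatial size 1×1 with small batches is numerically fragile in
  *checks* (third derivatives explode), not in training; gradient tests
  therefore use spatial sizes ≥ 2.
* Attention-weight neutrality (all weights forced to 1) reproduces the
  unattended network exactly and is exposed as a diagnostic
  (`predictSeedNet(..., neutralAttention = TRUE)`).
* Max-pooling and channel-max ties resolve to the first index,
  deterministically.
* The curve rasteriser rounds with R's banker's rounding; the constant
  0.5 curve on range (0, 1) lands on 0-based row 112.

## Known limitations

Training at study scale (12,800 fused images, depth 50, 50 epochs) is far
outside one-CPU desk scale; the package's training loop is exercised at
reduced input sizes and epoch counts, and the study-scale accuracy values
are consequently out of scope. Segmentation assumes non-touching seeds;
the spectral noise model is i.i.d. Gaussian (no wavelength-correlated
sensor effects); curve rasterisation quantises reflectance to 224 rows,
which bounds the amplitude resolution per curve to its y-range / 223.
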