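# seedfuse

Seed variety identification from paired RGB photographs and point
reflectance spectra, using data-level image–spectrum fusion and
attention-augmented deep residual networks — implemented end to end in R.

## The problem

Verifying the variety of crop seeds (here modelled on sorghum) by eye is
slow and subjective, and neither modality alone tells the whole story:
RGB images capture colour, shape and texture but miss composition, while
a 350–2500 nm reflectance curve captures chemistry but not appearance.
`seedfuse` implements a fusion pipeline in which both modalities are
represented as images and classified jointly:

1. **Segmentation** — a board photograph containing many seeds is
   converted to grayscale (BT.601 luminance), thresholded with Otsu's
   automatic global threshold (foreground = minority class), cleaned by
   morphological opening + closing with a disc element, and cut into one
   224×224×3 crop per 8-connected component.
2. **Spectral encoding** — each seed's reflectance curve is smoothed with
   a Savitzky–Golay filter (default window 11, order 3) and rasterised
   into a 224×224 black-on-white curve image (wavelength → columns,
   reflectance → rows), then replicated to pseudo-RGB. No SNV/MSC
   normalisation: the curve's shape *is* the signal.
3. **Fusion** — crop and curve image are concatenated side by side into a
   224×448×3 composite and resized to the network input.
4. **Classification** — residual networks of depth 18/34/50/101, with
   optional channel/spatial attention after the conv2 and conv3 stages and
   optional depthwise separable convolutions (DSC) in conv4:
   - **SE**: `s = σ(W₂ · relu(W₁ · z))` with `z_c = (1/HW) Σᵢⱼ X_c(i,j)`
     and reduction ratio r = 16;
   - **CBAM**: channel weights `σ(MLP(AvgPool F) + MLP(MaxPool F))`
     followed by a spatial map `σ(f⁷ˣ⁷[AvgPool F; MaxPool F])`;
   - **ECA**: a 1-D convolution across the pooled channel vector with
     adaptive kernel `k = nearest odd to log₂(C)/γ + b` (γ = 2, b = 1);
   - **DSC**: each 3×3 convolution factorised into depthwise + pointwise
     stages (k²C + C·C′ weights instead of k²C·C′).

The whole network stack — batched convolution/BN/pooling forward and
backward passes, momentum SGD (lr 0.001, momentum 0.9, weight decay 0.01,
batch 8, 50 epochs) — is implemented in the package with an
Rcpp/RcppArmadillo hot path, and is verified against finite-difference
gradients and closed-form attention oracles in the test suite.

Evaluation uses the five standard metrics from the confusion matrix
(accuracy plus macro specificity/recall/precision/F1), Student-t 95%
confidence intervals over repeated runs, one-way ANOVA across models, an
8-row ablation grid over the fusion/CBAM/DSC flags with parameter/FLOP
profile columns, and an analytic profiler (conv+FC multiply–accumulates).

A synthetic-data module generates class-structured seed boards (textured
ellipses on a dark background) and smooth per-class reflectance
archetypes with Gaussian noise, so every stage is testable without any
external download. Its switches can place the class signal in both
modalities or split it across them, which is how the fusion benefit is
demonstrated.

## Worked example

```r
library(seedfuse)

# synthetic study data: 3 varieties, one small board
profiles <- makeVarietyProfiles(3, rngSeed = 7)
board <- renderBoard(profiles,
                     BoardSpec(600, 600, nSeeds = 8, rngSeed = 21),
                     c(3, 3, 2))
crops <- segmentBoard(board$board)
length(crops)
#> [1] 8

# one seed's spectrum -> curve image -> fused composite
sp <- sampleSpectrum(profiles[[1]], rngSeed = 1)
ci <- renderCurveImage(sgFilter(sp), c(0, 1))
fused <- fuseImages(crops[[1]], grayToPseudoRgb(ci), "V01")
dim(pixels(fused))
#> [1] 224 448   3

# profile the ablation backbone
profileModel(modelConfig(depth = 50))
#> ModelProfile: 25.6 M params, 4.09 GFLOPs at 224x224x3

# desk-scale training run
d <- makeFusionExperimentData(nPerClass = 12, rngSeed = 5, inputSize = 16)
m <- buildModel(modelConfig(depth = 18, numClasses = 8),
                classes = sort(unique(d$labels)), rngSeed = 1)
fit <- trainModel(m, d$fused, d$labels,
                  config = trainConfig(batchSize = 16, epochs = 2))
metricsFromConfusion(evaluateModel(fit$model, d$fused, d$labels))
#> MetricsReport: accuracy 0.2396 | macro specificity 0.8914 | recall 0.2396
#> | precision 0.1028 | F1 0.1367
```

The profile line reads as in architecture tables: 25.6 million trainable
weights and 4.09×10⁹ conv+FC multiply–accumulates for one 224×224×3
forward pass of the depth-50 baseline with a 1000-way head. The final
metrics line shows a 96-sample, 2-epoch toy run that has barely left
chance (1/8) — it demonstrates the API, not performance; the
properly-sized desk-scale experiment (100 seeds per class, 5 epochs,
3 seeds) lives in `fusionBenefit()` and the methods vignette.

A thin CLI covering generation, segmentation, curve rendering and
profiling ships at `inst/cli/seedfuse.R`:

```sh
Rscript inst/cli/seedfuse.R profile --depth 50 --attention cbam
```

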