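# Desk-scale experiments: the fusion-benefit comparison (fused vs
# single-modality inputs on data whose class signal is split across
# modalities) and the eight-row ablation grid over the fusion/CBAM/DSC
# flags with profile columns.

#' Generate a paired crop/spectrum dataset for fusion experiments
#'
#' Renders one seed crop and samples one smoothed, rasterised reflectance
#' curve per seed, and prepares three model-input tensors: the fused
#' composite, the RGB crop alone, and the curve image alone, all resized
#' to `inputSize`. With `crossed = TRUE` the class signal is split across
#' modalities (colour identifies the class only up to groups of 2, the
#' spectrum only up to groups of 4), so no single modality can separate
#' all 8 classes but the pair can.
#'
#' @param nPerClass Seeds per class.
#' @param rngSeed Integer master seed.
#' @param inputSize Square model-input side in pixels (default 32; see the
#'   methods vignette for the desk-scale rationale).
#' @param nClasses Number of classes (default 8).
#' @param crossed Split class signal across modalities (default TRUE).
#' @return List with `fused`, `rgb`, `hsi` (inputSize x inputSize x 3 x N
#'   arrays), `labels`, and the generating `profiles`.
#' @export
makeFusionExperimentData <- function(nPerClass, rngSeed, inputSize = 32,
                                     nClasses = 8, crossed = TRUE) {
  profiles <- if (crossed)
    makeVarietyProfiles(nClasses, rngSeed, colorGroups = max(nClasses %/% 2, 1),
                        spectralGroups = 2)
  else makeVarietyProfiles(nClasses, rngSeed)
  archRange <- range(vapply(profiles, function(p) range(p@spectralArchetype),
                            numeric(2)))
  yRange <- archRange + c(-0.1, 0.1)  # dataset-global render range
  N <- nClasses * nPerClass
  tgt <- c(inputSize, inputSize)
  fused <- array(0, c(inputSize, inputSize, 3, N))
  rgb <- array(0, c(inputSize, inputSize, 3, N))
  hsi <- array(0, c(inputSize, inputSize, 3, N))
  labels <- character(N)
  n <- 0L
  for (ci in seq_len(nClasses)) {
    p <- profiles[[ci]]
    for (j in seq_len(nPerClass)) {
      n <- n + 1L
      crop <- renderSeedCrop(p, childSeed(rngSeed, 2L * n))
      sp <- sampleSpectrum(p, childSeed(rngSeed, 2L * n + 1L))
      ciimg <- grayToPseudoRgb(renderCurveImage(sgFilter(sp), yRange))
      fu <- fuseImages(crop, ciimg, p@name)
      fused[, , , n] <- prepareModelInput(fu, tgt)
      rgb[, , , n] <- prepareModelInput(crop@pixels, tgt)
      hsi[, , , n] <- prepareModelInput(ciimg, tgt)
      labels[n] <- p@name
    }
  }
  list(fused = fused, rgb = rgb, hsi = hsi, labels = labels,
       profiles = profiles)
}

#' Fusion-benefit experiment
#'
#' Trains the same architecture on fused inputs and on each single
#' modality, over several seeded repeats, and reports test accuracy. On
#' data whose class signal is split across modalities the fused mean
#' accuracy should strictly exceed both single-modality accuracies.
#'
#' @param nPerClass Seeds per class (default 100).
#' @param depth Residual-network depth (default 18).
#' @param epochs Training epochs (default 5).
#' @param seeds Integer vector of repeat seeds (default 1:3).
#' @param inputSize Model-input side (default 32).
#' @param batchSize Minibatch size for this experiment (default 32).
#' @param dataSeed Seed for the generated dataset (default 99).
#' @param data Optional precomputed [makeFusionExperimentData()] result.
#' @return Data frame (modality, seed, accuracy) with a `means` attribute.
#' @export
fusionBenefit <- function(nPerClass = 100, depth = 18, epochs = 5,
                          seeds = 1:3, inputSize = 32, batchSize = 32,
                          dataSeed = 99, data = NULL) {
  if (is.null(data))
    data <- makeFusionExperimentData(nPerClass, dataSeed, inputSize)
  split <- stratifiedSplit(data$labels, c(0.7, 0.2, 0.1), dataSeed)
  tr <- as.integer(trainIds(split))
  te <- as.integer(testIds(split))
  classes <- sort(unique(data$labels))
  rows <- list()
  for (mod in c("fused", "rgb", "hsi")) {
    x <- data[[mod]]
    for (s in seeds) {
      model <- buildModel(modelConfig(depth = depth,
                                      numClasses = length(classes)),
                          classes = classes, rngSeed = s)
      fit <- trainModel(model, x[, , , tr, drop = FALSE], data$labels[tr],
                        config = trainConfig(batchSize = batchSize,
                                             epochs = epochs, rngSeed = s))
      cm <- evaluateModel(fit$model, x[, , , te, drop = FALSE],
                          data$labels[te])
      rows[[length(rows) + 1]] <-
        data.frame(modality = mod, seed = s,
                   accuracy = sum(diag(cm)) / sum(cm))
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "means") <- tapply(out$accuracy, out$modality, mean)
  out
}

#' Ablation grid over the fusion / CBAM / DSC flags
#'
#' Trains and evaluates the eight flag combinations (no-flag baseline;
#' each flag alone; each pair; all three) on identical splits and
#' per-repeat seeds, reporting mean test accuracy plus the profile columns
#' (params in millions, GFLOPs at the profile input). The `fusion` flag
#' switches the input tensor (fused composite vs RGB alone); `cbam` adds
#' channel+spatial attention after the conv2/conv3 stages; `dsc` replaces
#' the conv4 3x3 convolutions with depthwise separable ones.
#'
#' @param data List with `fused`, `rgb` input tensors and `labels`, as
#'   from [makeFusionExperimentData()].
#' @param config A [TrainConfig-class] for the desk-scale training runs.
#' @param nRepeats Training repeats per row (default 1).
#' @param depth Backbone depth (default 50, the ablation backbone).
#' @param splitSeed Seed of the shared stratified split (default 1).
#' @param profileInput Input shape for the profile columns
#'   (default c(224, 224, 3)).
#' @return Data frame with columns fusion, cbam, dsc, accuracy,
#'   params_millions, flops_g (8 rows).
#' @export
ablationGrid <- function(data, config = trainConfig(), nRepeats = 1,
                         depth = 50, splitSeed = 1,
                         profileInput = c(224, 224, 3)) {
  stopIfNot(all(c("fused", "rgb", "labels") %in% names(data)),
            "invalid argument: data needs fused, rgb and labels")
  flags <- expand.grid(fusion = c(FALSE, TRUE), cbam = c(FALSE, TRUE),
                       dsc = c(FALSE, TRUE))
  ord <- c(1, 2, 3, 5, 4, 6, 7, 8)  # none, f, c, d, fc, fd, cd, fcd
  flags <- flags[ord, ]
  split <- stratifiedSplit(data$labels, c(0.7, 0.2, 0.1), splitSeed)
  tr <- as.integer(trainIds(split))
  te <- as.integer(testIds(split))
  classes <- sort(unique(data$labels))
  rows <- list()
  for (i in seq_len(nrow(flags))) {
    fl <- flags[i, ]
    cfg <- modelConfig(depth = depth,
                       attention = if (fl$cbam) "cbam" else "none",
                       dscStages = if (fl$dsc) "conv4" else character(0),
                       numClasses = length(classes))
    x <- if (fl$fusion) data$fused else data$rgb
    accs <- vapply(seq_len(nRepeats), function(rep) {
      s <- childSeed(splitSeed, 100 * i + rep)
      model <- buildModel(cfg, classes = classes, rngSeed = s)
      tc <- config
      tc@rngSeed <- s
      fit <- trainModel(model, x[, , , tr, drop = FALSE], data$labels[tr],
                        config = tc)
      cm <- evaluateModel(fit$model, x[, , , te, drop = FALSE],
                          data$labels[te])
      sum(diag(cm)) / sum(cm)
    }, numeric(1))
    prof <- profileModel(cfg, profileInput)
    rows[[i]] <- data.frame(fusion = fl$fusion, cbam = fl$cbam, dsc = fl$dsc,
                            accuracy = mean(accs),
                            params_millions = paramsMillions(prof),
                            flops_g = flopsG(prof))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
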