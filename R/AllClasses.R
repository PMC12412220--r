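# S4 classes for the fusion pipeline. Image pixel containers are plain
# numeric arrays in [0, 255] with dim c(rows, cols, channels); reflectance
# values are unitless in [0, 1].

#' SpectralCurve: one seed's reflectance spectrum
#'
#' Wavelength/reflectance pairs for a single seed, normally on the standard
#' 350-2500 nm grid (see [wavelengthGrid()]).
#'
#' @slot wavelengths Numeric, strictly increasing, in nanometres.
#' @slot reflectance Numeric, same length, finite.
#' @export
setClass("SpectralCurve",
  representation(wavelengths = "numeric", reflectance = "numeric"),
  validity = function(object) {
    w <- object@wavelengths; r <- object@reflectance
    if (length(w) != length(r)) return("wavelengths and reflectance lengths differ")
    if (length(w) < 5) return("curve needs at least 5 points")
    if (any(diff(w) <= 0)) return("wavelengths must be strictly increasing")
    if (!all(is.finite(r))) return("reflectance must be finite")
    TRUE
  })

#' @describeIn SpectralCurve-class Constructor.
#' @param wavelengths,reflectance See slots.
#' @export
SpectralCurve <- function(wavelengths, reflectance)
  new("SpectralCurve", wavelengths = as.numeric(wavelengths),
      reflectance = as.numeric(reflectance))

#' SeedCrop: a single-seed 224x224x3 image with provenance
#'
#' @slot pixels 224x224x3 array of intensities in \[0, 255\].
#' @slot sourceBbox Integer (row0, col0, row1, col1) in source-board
#'   coordinates (the square window the crop was resized from).
#' @slot sourceBoard Identifier of the source board.
#' @export
setClass("SeedCrop",
  representation(pixels = "array", sourceBbox = "numeric", sourceBoard = "character"),
  validity = function(object) {
    d <- dim(object@pixels)
    if (length(d) != 3 || d[1] != 224 || d[2] != 224 || d[3] != 3)
      return("pixels must be 224x224x3")
    if (length(object@sourceBbox) != 4) return("sourceBbox must have 4 entries")
    TRUE
  })

#' CurveImage: rasterised reflectance curve
#'
#' A 224x224 binary-valued grayscale image (background 255, curve 0) of one
#' reflectance curve, together with the y-range used for vertical scaling.
#'
#' @slot pixels 224x224 matrix with values in \{0, 255\}.
#' @slot yRange Numeric length 2, (min, max) reflectance mapped to rows.
#' @export
setClass("CurveImage",
  representation(pixels = "matrix", yRange = "numeric"),
  validity = function(object) {
    if (!all(dim(object@pixels) == c(224, 224))) return("pixels must be 224x224")
    if (!all(object@pixels %in% c(0, 255))) return("pixels must be 0 or 255")
    if (length(object@yRange) != 2 || object@yRange[1] >= object@yRange[2])
      return("yRange must be (min, max) with min < max")
    TRUE
  })

#' FusedImage: RGB crop and pseudo-RGB curve image, side by side
#'
#' @slot pixels 224x448x3 array; columns 1-224 hold the RGB crop, columns
#'   225-448 the pseudo-RGB curve image.
#' @slot leftSource,rightSource Identifiers of crop and spectrum.
#' @slot label Variety name.
#' @export
setClass("FusedImage",
  representation(pixels = "array", leftSource = "character",
                 rightSource = "character", label = "character"),
  validity = function(object) {
    d <- dim(object@pixels)
    if (length(d) != 3 || d[1] != 224 || d[2] != 448 || d[3] != 3)
      return("pixels must be 224x448x3")
    TRUE
  })

#' VarietyProfile: generative description of one seed variety
#'
#' Parameters for the synthetic generator: seed appearance (mean colour,
#' ellipse axes, texture) and a smooth spectral archetype with additive
#' Gaussian noise.
#'
#' @slot name Variety label.
#' @slot meanColor RGB intensities in \[0, 255\].
#' @slot colorSd Per-seed colour jitter SD.
#' @slot axisMean Ellipse semi-axes (pixels), each >= 8 so seeds stay
#'   segmentable.
#' @slot axisSd Axis jitter SD.
#' @slot textureAmp Multiplicative texture amplitude in \[0, 1\].
#' @slot spectralArchetype Reflectance on the standard grid, in \[0, 1\].
#' @slot spectralNoiseSd SD of additive per-wavelength Gaussian noise.
#' @export
setClass("VarietyProfile",
  representation(name = "character", meanColor = "numeric", colorSd = "numeric",
                 axisMean = "numeric", axisSd = "numeric", textureAmp = "numeric",
                 spectralArchetype = "numeric", spectralNoiseSd = "numeric"),
  validity = function(object) {
    if (length(object@meanColor) != 3 || any(object@meanColor < 0 | object@meanColor > 255))
      return("meanColor must be 3 intensities in [0,255]")
    if (length(object@axisMean) != 2 || any(object@axisMean < 8))
      return("axisMean must be a pair with both semi-axes >= 8 px")
    if (length(object@spectralArchetype) != length(wavelengthGrid()))
      return("spectralArchetype must live on the standard wavelength grid")
    if (any(object@spectralArchetype < 0 | object@spectralArchetype > 1))
      return("spectralArchetype values must be in [0,1]")
    if (object@colorSd < 0 || object@axisSd < 0 || object@spectralNoiseSd < 0)
      return("standard deviations must be nonnegative")
    if (object@textureAmp < 0 || object@textureAmp > 1)
      return("textureAmp must be in [0,1]")
    TRUE
  })

#' BoardSpec: geometry of a synthetic seed board
#'
#' @slot height,width Board size in pixels.
#' @slot nSeeds Number of seeds to place.
#' @slot minSeparation Minimum centre-to-centre distance in pixels.
#' @slot backgroundColor RGB background intensities.
#' @slot rngSeed Integer seed controlling all randomness of the board.
#' @export
setClass("BoardSpec",
  representation(height = "numeric", width = "numeric", nSeeds = "numeric",
                 minSeparation = "numeric", backgroundColor = "numeric",
                 rngSeed = "numeric"),
  validity = function(object) {
    if (object@nSeeds < 0) return("nSeeds must be >= 0")
    if (object@minSeparation <= 0) return("minSeparation must be > 0")
    if (length(object@backgroundColor) != 3) return("backgroundColor must be RGB")
    TRUE
  })

#' @describeIn BoardSpec-class Constructor with generator defaults.
#' @param height,width,nSeeds,minSeparation,backgroundColor,rngSeed See slots.
#' @export
BoardSpec <- function(height = 1600, width = 1600, nSeeds = 80,
                      minSeparation = 80, backgroundColor = c(30, 30, 30),
                      rngSeed = 1L)
  new("BoardSpec", height = height, width = width, nSeeds = nSeeds,
      minSeparation = minSeparation, backgroundColor = backgroundColor,
      rngSeed = rngSeed)

#' GroundTruth: planted-seed record for a synthetic board
#'
#' @slot centers n x 2 matrix of (row, col) seed centres.
#' @slot labels Variety name per seed.
#' @slot bboxes n x 4 matrix of (row0, col0, row1, col1) boxes inside the
#'   board.
#' @export
setClass("GroundTruth",
  representation(centers = "matrix", labels = "character", bboxes = "matrix"),
  validity = function(object) {
    n <- nrow(object@centers)
    if (length(object@labels) != n || nrow(object@bboxes) != n)
      return("centers, labels and bboxes must have equal length")
    TRUE
  })

#' DatasetSplit: stratified train/validation/test partition
#'
#' @slot trainIds,valIds,testIds Disjoint identifier vectors whose union is
#'   the full id set.
#' @slot ratios Numeric triple summing to 1 (default 0.7/0.2/0.1).
#' @slot rngSeed Integer seed used for the per-class shuffles.
#' @export
setClass("DatasetSplit",
  representation(trainIds = "character", valIds = "character",
                 testIds = "character", ratios = "numeric", rngSeed = "numeric"),
  validity = function(object) {
    ids <- c(object@trainIds, object@valIds, object@testIds)
    if (anyDuplicated(ids)) return("split groups must be disjoint")
    if (length(object@ratios) != 3) return("ratios must be a triple")
    TRUE
  })

#' ModelConfig: residual-network architecture configuration
#'
#' @slot depth One of 18, 34, 50, 101.
#' @slot attention One of "none", "se", "cbam", "eca".
#' @slot attentionSites Stages receiving an attention block after their last
#'   residual block; subset of conv2..conv5 (default conv2, conv3).
#' @slot dscStages Stages whose 3x3 convolutions are replaced by depthwise
#'   separable convolutions (default conv4).
#' @slot numClasses Training head size (default 8).
#' @slot seReduction Channel-reduction ratio r of the SE/CBAM MLPs
#'   (default 16).
#' @slot ecaGamma,ecaB Kernel-size law parameters of ECA (defaults 2 and 1).
#' @slot cbamSpatialKernel Odd spatial-attention kernel (default 7).
#' @slot profileHeadClasses Head size used when profiling (default 1000).
#' @export
setClass("ModelConfig",
  representation(depth = "numeric", attention = "character",
                 attentionSites = "character", dscStages = "character",
                 numClasses = "numeric", seReduction = "numeric",
                 ecaGamma = "numeric", ecaB = "numeric",
                 cbamSpatialKernel = "numeric", profileHeadClasses = "numeric"),
  validity = function(object) {
    if (!object@depth %in% c(18, 34, 50, 101)) return("depth must be 18/34/50/101")
    if (!object@attention %in% c("none", "se", "cbam", "eca"))
      return("attention must be none/se/cbam/eca")
    sites <- c("conv2", "conv3", "conv4", "conv5")
    if (!all(object@attentionSites %in% sites)) return("invalid attentionSites")
    if (!all(object@dscStages %in% sites)) return("invalid dscStages")
    if (object@cbamSpatialKernel %% 2 != 1) return("cbamSpatialKernel must be odd")
    if (object@seReduction < 1) return("seReduction must be >= 1")
    if (object@numClasses < 2) return("numClasses must be >= 2")
    if (object@ecaGamma <= 0) return("ecaGamma must be positive")
    TRUE
  })

#' @describeIn ModelConfig-class Constructor with the defaults used
#'   throughout: attention after conv2 and conv3, DSC in conv4, r = 16,
#'   ECA gamma = 2, b = 1, 7x7 spatial kernel, 8-class training head,
#'   1000-class profiling head.
#' @param depth,attention,attentionSites,dscStages,numClasses See slots.
#' @param seReduction,ecaGamma,ecaB,cbamSpatialKernel,profileHeadClasses
#'   See slots.
#' @export
modelConfig <- function(depth = 50, attention = "none",
                        attentionSites = c("conv2", "conv3"),
                        dscStages = character(0), numClasses = 8,
                        seReduction = 16, ecaGamma = 2, ecaB = 1,
                        cbamSpatialKernel = 7, profileHeadClasses = 1000)
  new("ModelConfig", depth = depth, attention = attention,
      attentionSites = attentionSites, dscStages = dscStages,
      numClasses = numClasses, seReduction = seReduction,
      ecaGamma = ecaGamma, ecaB = ecaB,
      cbamSpatialKernel = cbamSpatialKernel,
      profileHeadClasses = profileHeadClasses)

#' SeedNet: an instantiated residual-network classifier
#'
#' Built by [buildModel()]. Holds the architecture descriptors, the flat
#' parameter list, batch-norm running statistics, and the class labels.
#'
#' @slot config The [ModelConfig-class] used to build the network.
#' @slot arch Nested list of layer descriptors.
#' @slot params Named list of weight arrays.
#' @slot state Named list of batch-norm running means/variances.
#' @slot classes Class labels of the head.
#' @export
setClass("SeedNet",
  representation(config = "ModelConfig", arch = "list", params = "list",
                 state = "list", classes = "character"))

#' ModelProfile: parameter and FLOP counts of a configuration
#'
#' @slot paramsTotal Total trainable weights (conv + BN + FC + attention).
#' @slot paramsMillions paramsTotal / 1e6 rounded to one decimal.
#' @slot macsTotal Multiply-accumulates of conv and FC layers at the given
#'   input size (grouped convolutions divided by groups).
#' @slot flopsG macsTotal / 1e9 rounded to two decimals.
#' @slot inputShape (H, W, C) used for the MAC count.
#' @export
setClass("ModelProfile",
  representation(paramsTotal = "numeric", paramsMillions = "numeric",
                 macsTotal = "numeric", flopsG = "numeric",
                 inputShape = "numeric"),
  validity = function(object) {
    if (object@paramsTotal <= 0 || object@macsTotal <= 0)
      return("counts must be positive")
    TRUE
  })

#' MetricsReport: five-metric summary of a confusion matrix
#'
#' @slot accuracy Overall accuracy (trace / total).
#' @slot macroSpecificity,macroRecall,macroPrecision,macroF1 Unweighted
#'   means of the per-class one-vs-rest metrics.
#' @slot perClass Data frame with one row per class
#'   (specificity, recall, precision, f1).
#' @slot confusion The K x K confusion matrix the report was computed from.
#' @export
setClass("MetricsReport",
  representation(accuracy = "numeric", macroSpecificity = "numeric",
                 macroRecall = "numeric", macroPrecision = "numeric",
                 macroF1 = "numeric", perClass = "data.frame",
                 confusion = "matrix"))

setMethod("show", "SpectralCurve", function(object) {
  w <- object@wavelengths
  cat(sprintf("SpectralCurve: %d points, %g-%g nm, reflectance [%.3f, %.3f]\n",
              length(w), min(w), max(w), min(object@reflectance),
              max(object@reflectance)))
})

setMethod("show", "SeedCrop", function(object) {
  cat(sprintf("SeedCrop: 224x224x3 from board '%s', bbox (%d,%d)-(%d,%d)\n",
              object@sourceBoard, object@sourceBbox[1], object@sourceBbox[2],
              object@sourceBbox[3], object@sourceBbox[4]))
})

setMethod("show", "FusedImage", function(object) {
  cat(sprintf("FusedImage: 224x448x3, label '%s' (left: %s, right: %s)\n",
              object@label, object@leftSource, object@rightSource))
})

setMethod("show", "VarietyProfile", function(object) {
  cat(sprintf("VarietyProfile '%s': colour (%g,%g,%g), axes (%g,%g) px, noise sd %g\n",
              object@name, object@meanColor[1], object@meanColor[2],
              object@meanColor[3], object@axisMean[1], object@axisMean[2],
              object@spectralNoiseSd))
})

setMethod("show", "ModelConfig", function(object) {
  cat(sprintf("ModelConfig: ResNet%d, attention %s [%s], DSC [%s], %d classes\n",
              object@depth, object@attention,
              paste(object@attentionSites, collapse = ","),
              paste(object@dscStages, collapse = ","), object@numClasses))
})

setMethod("show", "SeedNet", function(object) {
  np <- sum(vapply(object@params, length, numeric(1)))
  cat(sprintf("SeedNet: ResNet%d (%s attention), %d classes, %s parameters\n",
              object@config@depth, object@config@attention,
              length(object@classes), format(np, big.mark = ",")))
})

setMethod("show", "ModelProfile", function(object) {
  cat(sprintf("ModelProfile: %.1f M params, %.2f GFLOPs at %dx%dx%d\n",
              object@paramsMillions, object@flopsG, object@inputShape[1],
              object@inputShape[2], object@inputShape[3]))
})

setMethod("show", "MetricsReport", function(object) {
  cat(sprintf(paste0("MetricsReport: accuracy %.4f | macro specificity %.4f",
                     " | recall %.4f | precision %.4f | F1 %.4f\n"),
              object@accuracy, object@macroSpecificity, object@macroRecall,
              object@macroPrecision, object@macroF1))
})
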