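# Data-level fusion: RGB crop (left) and pseudo-RGB curve image (right)
# concatenated into a 224x448x3 composite, model-input preparation, and
# stratified 7:2:1 dataset splitting.

#' Fuse an RGB seed crop with a pseudo-RGB curve image
#'
#' Horizontal concatenation, crop left, curve image right, giving the
#' 224x448x3 composite. Fusion is invertible: the halves can be recovered
#' bit-exactly from the result.
#'
#' @param crop A [SeedCrop-class] or 224x224x3 array.
#' @param curveRgb 224x224x3 pseudo-RGB curve image (see
#'   [grayToPseudoRgb()]).
#' @param label Variety name.
#' @param leftSource,rightSource Provenance identifiers.
#' @return A [FusedImage-class].
#' @export
fuseImages <- function(crop, curveRgb, label,
                       leftSource = "crop", rightSource = "spectrum") {
  cp <- if (is(crop, "SeedCrop")) crop@pixels else crop
  stopIfNot(length(dim(cp)) == 3 && all(dim(cp) == c(224, 224, 3)),
            "invalid argument: crop must be 224x224x3")
  stopIfNot(length(dim(curveRgb)) == 3 && all(dim(curveRgb) == c(224, 224, 3)),
            "invalid argument: curve image must be 224x224x3")
  fused <- array(0, c(224, 448, 3))
  fused[, 1:224, ] <- cp
  fused[, 225:448, ] <- curveRgb
  new("FusedImage", pixels = fused, leftSource = leftSource,
      rightSource = rightSource, label = as.character(label))
}

#' Recover the two halves of a fused image
#'
#' @param fused A [FusedImage-class].
#' @return List with `crop` and `curveRgb`, each 224x224x3.
#' @export
splitFusedImage <- function(fused) {
  p <- if (is(fused, "FusedImage")) fused@pixels else fused
  list(crop = p[, 1:224, , drop = FALSE],
       curveRgb = p[, 225:448, , drop = FALSE])
}

#' Prepare a fused image as model input
#'
#' Bilinear resize of the 224x448x3 composite to `target` (default
#' 224x224, the network's stated input size; pass `c(224, 448)` to feed
#' the composite unresized -- global average pooling accepts any spatial
#' size), then intensity scaling to \[0, 1\], optionally followed by
#' per-channel standardisation with supplied training-set statistics.
#'
#' @param fused A [FusedImage-class] or H x W x 3 array in \[0, 255\].
#' @param target Integer (height, width), both positive.
#' @param channelStats Optional list with `mean` and `sd`, each length 3,
#'   applied after scaling.
#' @return target\[1\] x target\[2\] x 3 numeric array.
#' @export
prepareModelInput <- function(fused, target = c(224, 224), channelStats = NULL) {
  stopIfNot(length(target) == 2 && all(target > 0),
            "invalid argument: target must be two positive sizes")
  p <- if (is(fused, "FusedImage")) fused@pixels else fused
  if (!all(dim(p)[1:2] == target)) p <- resizeArray(p, target[1], target[2])
  x <- p / 255
  if (!is.null(channelStats)) {
    for (ch in 1:3)
      x[, , ch] <- (x[, , ch] - channelStats$mean[ch]) / channelStats$sd[ch]
  }
  x
}

#' Stratified train/validation/test split
#'
#' Shuffles each class with the given seed and apportions it to the three
#' groups by largest-remainder assignment (floors first, remainders by
#' largest fractional part, ties resolved train > validation > test), so
#' per-class proportions match the ratios to within rounding.
#'
#' @param labels Vector of variety names; names(labels) are used as ids if
#'   present, positions otherwise.
#' @param ratios Positive triple summing to 1 (default 0.7, 0.2, 0.1).
#' @param rngSeed Integer seed; the split is deterministic given it.
#' @return A [DatasetSplit-class].
#' @export
#' @examples
#' s <- stratifiedSplit(rep(c("a", "b"), each = 10), c(0.7, 0.2, 0.1), 1)
#' length(trainIds(s))  # 14
stratifiedSplit <- function(labels, ratios = c(0.7, 0.2, 0.1), rngSeed = 1L) {
  stopIfNot(length(ratios) == 3 && all(ratios > 0),
            "invalid argument: ratios must be three positive numbers")
  stopIfNot(abs(sum(ratios) - 1) <= 1e-9,
            "invalid argument: ratios must sum to 1")
  ids <- if (!is.null(names(labels))) names(labels) else
    as.character(seq_along(labels))
  cls <- split(ids, as.character(labels))
  if (any(vapply(cls, length, integer(1)) < 3))
    stop("invalid argument: every class needs at least 3 members", call. = FALSE)
  groups <- list(character(0), character(0), character(0))
  for (ci in seq_along(cls)) {
    members <- withSeed(childSeed(rngSeed, ci), sample(cls[[ci]]))
    n <- length(members)
    exact <- n * ratios
    base <- floor(exact)
    rem <- n - sum(base)
    if (rem > 0) {
      frac <- exact - base
      extra <- order(-frac, seq_along(frac))[seq_len(rem)]
      base[extra] <- base[extra] + 1
    }
    cuts <- cumsum(base)
    groups[[1]] <- c(groups[[1]], members[seq_len(base[1])])
    if (base[2] > 0)
      groups[[2]] <- c(groups[[2]], members[(cuts[1] + 1):cuts[2]])
    if (base[3] > 0)
      groups[[3]] <- c(groups[[3]], members[(cuts[2] + 1):cuts[3]])
  }
  new("DatasetSplit", trainIds = groups[[1]], valIds = groups[[2]],
      testIds = groups[[3]], ratios = as.numeric(ratios),
      rngSeed = as.numeric(rngSeed))
}
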