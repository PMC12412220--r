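# Board -> single-seed crops: grayscale conversion, automatic global
# (Otsu) thresholding with minority-class foreground polarity,
# morphological opening+closing with a disc element plus small-component
# removal, 8-connected component extraction, and centroid-centred square
# crops resized to 224x224.

#' Convert an RGB board image to grayscale
#'
#' ITU-R BT.601 luminance: 0.299 R + 0.587 G + 0.114 B. Values are kept as
#' floating point (no intermediate rounding) so the threshold step is not
#' affected by rounding dialects.
#'
#' @param board H x W x 3 array of intensities in \[0, 255\].
#' @return H x W numeric matrix in \[0, 255\].
#' @export
toGrayscale <- function(board) {
  d <- dim(board)
  stopIfNot(length(d) == 3 && d[3] == 3,
            "invalid argument: board must have 3 channels")
  g <- 0.299 * board[, , 1] + 0.587 * board[, , 2] + 0.114 * board[, , 3]
  matrix(g, d[1], d[2])
}

#' Automatic global threshold (Otsu) with minority-foreground polarity
#'
#' Chooses the threshold maximising between-class variance over 256
#' histogram bins (Otsu's criterion, via \pkg{EBImage}), then picks the
#' foreground polarity so the foreground fraction is at most 0.5 -- seeds
#' are always the minority class on a board, whether they are brighter or
#' darker than the background.
#'
#' @param gray H x W numeric matrix in \[0, 255\] with at least two
#'   distinct values.
#' @return List with `threshold` (on the 0-255 scale), `mask` (logical
#'   matrix, TRUE = foreground) and `foregroundFraction`.
#' @export
binarizeAuto <- function(gray) {
  stopIfNot(is.matrix(gray), "invalid argument: gray must be a matrix")
  if (length(unique(as.vector(gray))) < 2)
    stop("degenerate input: constant image has no separable classes",
         call. = FALSE)
  thr <- EBImage::otsu(EBImage::Image(gray / 255), range = c(0, 1),
                       levels = 256) * 255
  mask <- gray > thr
  if (mean(mask) > 0.5) mask <- !mask
  # Otsu effectiveness: between-class variance at the chosen threshold over
  # total variance. Near 1 for genuinely bimodal boards; about 2/pi for a
  # unimodal (seed-free) image, where the "threshold" only splits noise.
  hi <- gray > thr
  w1 <- mean(hi)
  sep <- if (w1 %in% c(0, 1)) 0 else
    w1 * (1 - w1) * (mean(gray[hi]) - mean(gray[!hi]))^2 /
      mean((gray - mean(gray))^2)
  list(threshold = thr, mask = mask, foregroundFraction = mean(mask),
       separability = sep)
}

#' Morphological cleaning of a binary mask
#'
#' Binary opening (erosion, dilation) followed by closing (dilation,
#' erosion) with a disc structuring element of the given radius, then
#' removal of connected foreground components smaller than `minArea`
#' pixels. The open-then-close filter with a fixed element is idempotent.
#'
#' @param mask Logical matrix.
#' @param radius Disc radius in pixels (>= 1).
#' @param minArea Minimum component area in pixels (default 64).
#' @return Cleaned logical matrix.
#' @export
morphologicalClean <- function(mask, radius, minArea = 64) {
  stopIfNot(is.numeric(radius) && radius >= 1,
            "invalid argument: radius must be >= 1")
  kern <- EBImage::makeBrush(2 * as.integer(radius) + 1, shape = "disc")
  m <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
  m <- EBImage::closing(EBImage::opening(m, kern), kern)
  m <- m > 0.5
  if (any(m)) {
    lab <- label8(m)
    sizes <- tabulate(lab[lab > 0])
    drop <- which(sizes < minArea)
    if (length(drop)) m[lab %in% drop] <- FALSE
  }
  m
}

# Exact 8-connected labeling: 4-connected bwlabel, then merge labels that
# touch diagonally (union-find over the label graph).
label8 <- function(mask) {
  lab <- EBImage::bwlabel(matrix(as.numeric(mask), nrow(mask), ncol(mask)))
  lab <- matrix(as.integer(lab), nrow(mask), ncol(mask))
  nlab <- max(lab)
  if (nlab <= 1) return(lab)
  H <- nrow(lab); W <- ncol(lab)
  a1 <- lab[-H, -W]; b1 <- lab[-1, -1]   # down-right diagonal
  a2 <- lab[-1, -W]; b2 <- lab[-H, -1]   # up-right diagonal
  sel1 <- a1 > 0 & b1 > 0 & a1 != b1
  sel2 <- a2 > 0 & b2 > 0 & a2 != b2
  pairs <- rbind(cbind(a1[sel1], b1[sel1]), cbind(a2[sel2], b2[sel2]))
  parent <- seq_len(nlab)
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  if (nrow(pairs)) {
    pairs <- unique(pairs)
    for (i in seq_len(nrow(pairs))) {
      ra <- find(pairs[i, 1]); rb <- find(pairs[i, 2])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  roots <- vapply(seq_len(nlab), find, integer(1))
  remap <- match(roots, sort(unique(roots)))
  out <- lab
  out[lab > 0] <- remap[lab[lab > 0]]
  out
}

# Bilinear resize of an (h, w, 3) or (h, w) array via EBImage (which stores
# images x-first, hence the transposes). Values stay on the 0-255 scale.
resizeArray <- function(img, h, w) {
  if (length(dim(img)) == 2) {
    out <- EBImage::resize(EBImage::Image(t(img)), w = w, h = h)
    return(t(EBImage::imageData(out)))
  }
  out <- EBImage::resize(EBImage::Image(aperm(img, c(2, 1, 3)),
                                        colormode = "Color"), w = w, h = h)
  aperm(EBImage::imageData(out), c(2, 1, 3))
}

#' Extract 224x224 single-seed crops from a board and its mask
#'
#' Enumerates 8-connected foreground components, takes for each a square
#' window centred on the component centroid with side
#' `max(bbox side, minSide)`, pads by edge replication where the window
#' leaves the board, and resizes the window to 224x224 with bilinear
#' interpolation. Crops are returned in row-major centroid order.
#'
#' @param board H x W x 3 array.
#' @param mask Logical matrix of the same spatial shape.
#' @param minSide Minimum window side before resizing (default 32).
#' @return List of [SeedCrop-class]; empty (with a warning) for an empty
#'   mask.
#' @export
extractSeedCrops <- function(board, mask, minSide = 32) {
  d <- dim(board)
  stopIfNot(all(dim(mask) == d[1:2]),
            "invalid argument: mask and board shapes differ")
  lab <- label8(mask)
  n <- max(lab)
  if (n == 0) {
    warning("empty mask: no seed components found")
    return(list())
  }
  idx <- which(lab > 0, arr.ind = TRUE)
  labs <- lab[lab > 0]
  ord <- order(labs)
  idx <- idx[ord, , drop = FALSE]
  labs <- labs[ord]
  bounds <- cumsum(tabulate(labs, n))
  starts <- c(1, head(bounds, -1) + 1)
  H <- d[1]; W <- d[2]
  crops <- vector("list", n)
  centroids <- matrix(0, n, 2)
  for (i in seq_len(n)) {
    px <- idx[starts[i]:bounds[i], , drop = FALSE]
    cen <- colMeans(px)
    centroids[i, ] <- cen
    side <- max(max(px[, 1]) - min(px[, 1]) + 1,
                max(px[, 2]) - min(px[, 2]) + 1, minSide)
    r0 <- round(cen[1] - side / 2); c0 <- round(cen[2] - side / 2)
    r1 <- r0 + side - 1; c1 <- c0 + side - 1
    rr <- pmin(pmax(r0:r1, 1), H)  # edge replication via index clamping
    cc <- pmin(pmax(c0:c1, 1), W)
    win <- board[rr, cc, , drop = FALSE]
    crops[[i]] <- new("SeedCrop",
                      pixels = resizeArray(win, 224, 224),
                      sourceBbox = c(max(r0, 1), max(c0, 1), min(r1, H), min(c1, W)),
                      sourceBoard = "board")
  }
  crops[order(centroids[, 1], centroids[, 2])]
}

#' Segment a board into single-seed crops
#'
#' Full pipeline composition: grayscale, automatic global threshold,
#' morphological cleaning, connected-component crop extraction. The crop
#' count equals the number of mask components.
#'
#' @inheritParams extractSeedCrops
#' @param radius Disc radius for morphological cleaning (default 2).
#' @param minArea Minimum component area in pixels (default 64).
#' @return List of [SeedCrop-class].
#' @export
#' @examples
#' profs <- makeVarietyProfiles(2, rngSeed = 1)
#' b <- renderBoard(profs, BoardSpec(400, 400, nSeeds = 4, rngSeed = 3),
#'                  c(2, 2))
#' length(segmentBoard(b$board))  # 4
segmentBoard <- function(board, radius = 2, minArea = 64, minSide = 32) {
  gray <- toGrayscale(board)
  bin <- binarizeAuto(gray)
  # a seed-free board is unimodal: thresholding it would only cut noise
  if (bin$separability < 0.7) return(list())
  mask <- morphologicalClean(bin$mask, radius, minArea)
  if (!any(mask)) return(list())
  extractSeedCrops(board, mask, minSide)
}
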