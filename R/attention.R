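# Channel/spatial attention primitives in functional form, operating on a
# single feature map stored C x H x W. These are the reference
# implementations of the squeeze-and-excitation, CBAM and ECA equations;
# the network layers in layers.R apply the same arithmetic to batched
# tensors and are property-tested against these.

checkMap <- function(map) {
  stopIfNot(is.array(map) && length(dim(map)) == 3,
            "invalid argument: feature map must be a C x H x W array")
  stopIfNot(all(is.finite(map)), "invalid argument: feature map must be finite")
}

#' Squeeze: per-channel global average pooling
#'
#' z_c = mean over the H x W plane of channel c, compressing a C x H x W
#' map to a length-C channel descriptor.
#'
#' @param map C x H x W array.
#' @return Numeric vector of length C.
#' @export
seSqueeze <- function(map) {
  checkMap(map)
  d <- dim(map)
  rowMeans(matrix(map, d[1], d[2] * d[3]))
}

#' Excite: two-layer reduction MLP with sigmoid gate
#'
#' s = sigmoid(W2 relu(W1 z)), with W1 mapping C to the reduced width
#' max(1, floor(C / r)) and W2 mapping back to C. Output values are
#' strictly in (0, 1).
#'
#' @param z Length-C channel descriptor.
#' @param W1 hidden x C weight matrix.
#' @param W2 C x hidden weight matrix.
#' @return Length-C vector of channel weights in (0, 1).
#' @export
seExcite <- function(z, W1, W2) {
  stopIfNot(ncol(W1) == length(z) && nrow(W2) == length(z) &&
              ncol(W2) == nrow(W1),
            "invalid argument: MLP weight shapes do not match z")
  as.vector(sigmoid(W2 %*% pmax(W1 %*% z, 0)))
}

#' Reweight a feature map channel-wise
#'
#' @param map C x H x W array.
#' @param s Length-C channel weights.
#' @return C x H x W array with channel c scaled by s\[c\].
#' @export
applyChannelWeights <- function(map, s) {
  checkMap(map)
  stopIfNot(length(s) == dim(map)[1],
            "invalid argument: weight length must equal channel count")
  map * as.vector(s)  # recycling runs over dim 1 = channels
}

#' CBAM channel attention weights
#'
#' sigmoid(MLP(avgpool(F)) + MLP(maxpool(F))) with the same MLP weights
#' applied to both pooled descriptors.
#'
#' @inheritParams seExcite
#' @param map C x H x W array.
#' @return Length-C vector in (0, 1).
#' @export
cbamChannelWeights <- function(map, W1, W2) {
  checkMap(map)
  d <- dim(map)
  m <- matrix(map, d[1], d[2] * d[3])
  zavg <- rowMeans(m)
  zmax <- apply(m, 1, max)
  mlp <- function(z) W2 %*% pmax(W1 %*% z, 0)
  as.vector(sigmoid(mlp(zavg) + mlp(zmax)))
}

#' CBAM spatial attention map
#'
#' Channel-wise mean and max maps are stacked into a 2 x H x W descriptor,
#' convolved with a k x k filter (same padding, no bias), and passed
#' through a sigmoid, giving a 1 x H x W map in (0, 1).
#'
#' @param map C x H x W array.
#' @param kernel k x k x 2 convolution weights (mean plane first), k odd.
#' @return 1 x H x W array.
#' @export
cbamSpatialMap <- function(map, kernel) {
  checkMap(map)
  kd <- dim(kernel)
  stopIfNot(length(kd) == 3 && kd[1] == kd[2] && kd[3] == 2,
            "invalid argument: kernel must be k x k x 2")
  stopIfNot(kd[1] %% 2 == 1, "invalid argument: kernel size must be odd")
  d <- dim(map)
  avg <- apply(map, c(2, 3), mean)
  mx <- apply(map, c(2, 3), max)
  x <- array(0, c(d[2], d[3], 2, 1))
  x[, , 1, 1] <- avg; x[, , 2, 1] <- mx
  w <- array(kernel, c(kd[1], kd[1], 2, 1))
  y <- cpp_conv2d_fw(x, w, 1L, (kd[1] - 1L) %/% 2L, 1L)
  array(sigmoid(y[, , 1, 1]), c(1, d[2], d[3]))
}

#' Adaptive ECA kernel size
#'
#' k = nearest odd integer to log2(C) / gamma + b (ties rounded up),
#' floored at 3, so the 1-D convolution's reach grows with the channel
#' count.
#'
#' @param C Channel count (>= 1).
#' @param gamma,b Kernel-size law parameters (defaults 2 and 1).
#' @return Odd integer kernel size >= 3.
#' @export
#' @examples
#' ecaKernelSize(256)  # 5
ecaKernelSize <- function(C, gamma = 2, b = 1) {
  stopIfNot(is.numeric(C) && length(C) == 1 && C >= 1,
            "invalid argument: C must be >= 1")
  stopIfNot(gamma > 0, "invalid argument: gamma must be positive")
  t <- log2(C) / gamma + b
  lower <- 2 * floor((t - 1) / 2) + 1
  upper <- lower + 2
  k <- if ((t - lower) < (upper - t)) lower else upper
  as.integer(max(3, k))
}

#' ECA channel attention weights
#'
#' sigmoid of a zero-padded 1-D convolution across the globally pooled
#' channel descriptor -- local cross-channel interaction with no
#' dimensionality reduction.
#'
#' @param map C x H x W array.
#' @param kernel 1-D convolution weights; its length must equal
#'   [ecaKernelSize()] for the map's channel count.
#' @param gamma,b Kernel-size law parameters (defaults 2 and 1).
#' @return Length-C vector in (0, 1).
#' @export
ecaChannelWeights <- function(map, kernel, gamma = 2, b = 1) {
  checkMap(map)
  C <- dim(map)[1]
  k <- ecaKernelSize(C, gamma, b)
  stopIfNot(length(kernel) == k,
            sprintf("invalid argument: kernel length must be %d for C = %d", k, C))
  z <- seSqueeze(map)
  as.vector(sigmoid(conv1dSame(matrix(z, C, 1), kernel)))
}

# Zero-padded same-size 1-D convolution down the rows of z (C x N).
conv1dSame <- function(z, kernel) {
  C <- nrow(z); k <- length(kernel)
  off <- (k + 1) %/% 2
  out <- matrix(0, C, ncol(z))
  for (j in seq_len(k)) {
    s <- j - off  # source row = c + s
    src <- seq_len(C) + s
    ok <- src >= 1 & src <= C
    out[ok, ] <- out[ok, ] + kernel[j] * z[src[ok], , drop = FALSE]
  }
  out
}
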