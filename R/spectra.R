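# Reflectance-curve preprocessing and rasterisation: Savitzky-Golay
# smoothing, axes-free 224x224 curve images (black polyline on white),
# pseudo-RGB replication. Deliberately no SNV/MSC/derivative
# preprocessing: those renormalisations distort the curve shapes the
# rasteriser is meant to preserve.

#' Savitzky-Golay smoothing of a reflectance curve
#'
#' Sliding least-squares polynomial smoother: each value is replaced by the
#' centre value of a degree-`polyorder` polynomial fitted over `window`
#' points (standard SG convolution weights, via \pkg{signal}). Endpoints
#' are handled by fitting the same polynomial to the first/last window and
#' evaluating it at the boundary positions, so polynomial signals up to
#' degree `polyorder` pass through unchanged everywhere.
#'
#' @param curve A [SpectralCurve-class].
#' @param window Odd window length, 3 <= window <= length(curve).
#' @param polyorder Polynomial degree < window.
#' @return Smoothed [SpectralCurve-class] on the same wavelengths.
#' @export
#' @examples
#' wl <- wavelengthGrid()
#' sgFilter(SpectralCurve(wl, rep(0.5, length(wl))), 11, 3)
sgFilter <- function(curve, window = 11, polyorder = 3) {
  stopIfNot(is(curve, "SpectralCurve"), "invalid argument: need a SpectralCurve")
  n <- length(curve@reflectance)
  stopIfNot(window %% 2 == 1, "invalid argument: window must be odd")
  stopIfNot(window >= 3 && window <= n,
            "invalid argument: window must be in [3, length(curve)]")
  stopIfNot(polyorder < window,
            "invalid argument: polyorder must be smaller than window")
  sm <- signal::sgolayfilt(curve@reflectance, p = polyorder, n = window)
  SpectralCurve(curve@wavelengths, sm)
}

# Integer Bresenham segment between (r0,c0) and (r1,c1); returns matrix of
# pixel (row, col) pairs, endpoints included.
bresenham <- function(r0, c0, r1, c1) {
  dr <- abs(r1 - r0); dc <- abs(c1 - c0)
  sr <- if (r0 < r1) 1L else -1L
  sc <- if (c0 < c1) 1L else -1L
  err <- dc - dr
  n <- dc + dr + 1L
  out <- matrix(0L, n, 2)
  i <- 0L
  repeat {
    i <- i + 1L
    out[i, ] <- c(r0, c0)
    if (r0 == r1 && c0 == c1) break
    e2 <- 2L * err
    if (e2 > -dr) { err <- err - dr; c0 <- c0 + sc }
    if (e2 < dc) { err <- err + dc; r0 <- r0 + sr }
  }
  out[seq_len(i), , drop = FALSE]
}

#' Rasterise a reflectance curve into a 224x224 curve image
#'
#' Axes-free rendering: the wavelength range maps linearly onto columns
#' 1..224, `yRange` maps linearly onto rows 224..1 (larger reflectance is
#' higher in the image). The polyline through all points is drawn
#' 1-pixel-thick with Bresenham segments, black (0) on white (255), no
#' anti-aliasing, so rendering is bit-exact and a pure function of the
#' curve and range. Reflectance outside `yRange` is clipped to the border
#' rows.
#'
#' @param curve A [SpectralCurve-class].
#' @param yRange Numeric (min, max) with min < max, or `"auto"` for the
#'   curve's own range (a constant curve is widened by 0.5 either side).
#'   Prefer a dataset-global range so between-class amplitude differences
#'   survive rasterisation.
#' @return A [CurveImage-class].
#' @export
#' @examples
#' wl <- wavelengthGrid()
#' img <- renderCurveImage(SpectralCurve(wl, rep(0.5, length(wl))), c(0, 1))
renderCurveImage <- function(curve, yRange = "auto") {
  stopIfNot(is(curve, "SpectralCurve"), "invalid argument: need a SpectralCurve")
  size <- 224L
  w <- curve@wavelengths; r <- curve@reflectance
  if (identical(yRange, "auto")) {
    yRange <- range(r)
    if (diff(yRange) == 0) yRange <- yRange + c(-0.5, 0.5)
  }
  stopIfNot(is.numeric(yRange) && length(yRange) == 2 && yRange[1] < yRange[2],
            "invalid argument: yRange must be (min, max) with min < max")
  cols <- round((w - w[1]) / (w[length(w)] - w[1]) * (size - 1)) + 1L
  rf <- pmin(pmax((r - yRange[1]) / (yRange[2] - yRange[1]), 0), 1)
  rows <- round((size - 1) * (1 - rf)) + 1L
  img <- matrix(255, size, size)
  img[cbind(rows[1], cols[1])] <- 0
  for (i in seq_len(length(w) - 1)) {
    if (rows[i] == rows[i + 1] && cols[i] == cols[i + 1]) next
    px <- bresenham(rows[i], cols[i], rows[i + 1], cols[i + 1])
    img[px] <- 0
  }
  new("CurveImage", pixels = img, yRange = as.numeric(yRange))
}

#' Replicate a grayscale curve image into three identical channels
#'
#' @param image A [CurveImage-class] or a 224x224 matrix.
#' @return 224x224x3 array with identical R, G, B channels.
#' @export
grayToPseudoRgb <- function(image) {
  m <- if (is(image, "CurveImage")) image@pixels else image
  stopIfNot(is.matrix(m) && all(dim(m) == c(224, 224)),
            "invalid argument: input must be a 224x224 single-channel image")
  array(m, c(224, 224, 3))
}
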