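# Shared fixtures, built in code at test time.

# small board with well-separated seeds and its ground truth
smallBoard <- function(nSeeds = 6, seed = 11, k = 3, size = 500) {
  profs <- makeVarietyProfiles(k, rngSeed = 5)
  counts <- rep(nSeeds %/% k, k)
  counts[1] <- counts[1] + nSeeds - sum(counts)
  rb <- renderBoard(profs, BoardSpec(size, size, nSeeds = nSeeds,
                                     minSeparation = 90, rngSeed = seed),
                    counts)
  rb$profiles <- profs
  rb
}

# brute-force Otsu over 256 bins: maximise between-class variance
otsuBruteForce <- function(gray) {
  q <- pmin(floor(gray), 255)  # 1-unit bins on the 0-255 scale
  counts <- tabulate(q + 1, 256)
  p <- counts / sum(counts)
  mu <- cumsum(p * (0:255))
  w <- cumsum(p)
  muT <- mu[256]
  sb2 <- (muT * w - mu)^2 / (w * (1 - w))
  sb2[!is.finite(sb2)] <- -Inf
  which.max(sb2[-256]) - 1  # threshold t: classes <= t and > t
}

randomCurve <- function(seed = 1, n = 2151) {
  wl <- wavelengthGrid()
  set.seed(seed)
  SpectralCurve(wl, pmin(pmax(0.4 + 0.2 * sin(wl / 300) +
                                rnorm(n, 0, 0.02), 0), 1))
}
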