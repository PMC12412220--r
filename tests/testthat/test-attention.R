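# Closed-form and brute-force oracles for the channel/spatial attention
# primitives (squeeze-and-excitation, CBAM, ECA).

randMap <- function(seed, C = 3, H = 4, W = 4) {
  set.seed(seed)
  array(rnorm(C * H * W), c(C, H, W))
}

test_that("squeeze is global average pooling", {
  expect_equal(seSqueeze(array(2.5, c(4, 3, 5))), rep(2.5, 4))
  one <- array(c(1, 3, 2, 4), c(1, 2, 2))  # [[1,2],[3,4]] row-major
  expect_equal(seSqueeze(one), 2.5)
  m <- randMap(1, C = 6)
  z <- seSqueeze(m)
  expect_length(z, 6)
  # brute-force loop oracle
  for (c in 1:6) expect_equal(z[c], mean(m[c, , ]))
})

test_that("excitation matches closed-form sigmoid evaluations", {
  expect_equal(seExcite(c(1, -2), matrix(0, 2, 2), matrix(0, 2, 2)),
               c(0.5, 0.5))
  I2 <- diag(2)
  expect_equal(seExcite(c(0, 0), I2, I2), c(0.5, 0.5))
  s <- seExcite(c(log(3), 0), I2, I2)
  expect_equal(s, c(0.75, 0.5), tolerance = 1e-12)  # sigmoid(log 3) = 3/4
  expect_error(seExcite(c(1, 2, 3), I2, I2), "invalid")
})

test_that("channel reweighting scales each channel by its weight", {
  m <- array(2, c(3, 2, 2))
  out <- applyChannelWeights(m, c(0.5, 1, 0.25))
  expect_equal(out[1, , ], matrix(1, 2, 2))
  expect_equal(out[2, , ], matrix(2, 2, 2))
  expect_equal(out[3, , ], matrix(0.5, 2, 2))
  # identity weights (limit case)
  expect_equal(applyChannelWeights(m, rep(1, 3)), m)
  # brute-force elementwise oracle on random input
  m <- randMap(2, C = 5)
  s <- runif(5)
  out <- applyChannelWeights(m, s)
  for (c in 1:5) expect_equal(out[c, , ], s[c] * m[c, , ])
  expect_error(applyChannelWeights(m, s[1:3]), "invalid")
})

test_that("CBAM channel weights follow sigmoid(MLP(avg) + MLP(max)) with shared MLP", {
  m <- randMap(3)
  expect_equal(cbamChannelWeights(m, matrix(0, 1, 3), matrix(0, 3, 1)),
               rep(0.5, 3))
  # constant map: avg == max, so M_C = sigmoid(2 MLP(z))
  cm <- array(1.3, c(2, 3, 3))
  W1 <- matrix(rnorm(4), 2, 2); W2 <- matrix(rnorm(4), 2, 2)
  z <- rep(1.3, 2)
  expected <- 1 / (1 + exp(-2 * (W2 %*% pmax(W1 %*% z, 0))))
  expect_equal(cbamChannelWeights(cm, W1, W2), as.vector(expected))
  # hand case: C=1 map [0, 4], identity MLP: avg 2, max 4 -> sigmoid(6)
  m1 <- array(c(0, 4), c(1, 1, 2))
  expect_equal(cbamChannelWeights(m1, matrix(1), matrix(1)),
               1 / (1 + exp(-6)))
})

test_that("CBAM spatial map stacks mean/max planes and convolves them", {
  m <- randMap(4, C = 3, H = 5, W = 5)
  zeroK <- array(0, c(3, 3, 2))
  expect_equal(cbamSpatialMap(m, zeroK), array(0.5, c(1, 5, 5)))
  out <- cbamSpatialMap(m, array(rnorm(18), c(3, 3, 2)))
  expect_equal(dim(out), c(1, 5, 5))
  expect_true(all(out > 0 & out < 1))
  # 1x1 map, 1x1 kernel (w_avg = w_max = 1): mean = max = 3 -> sigmoid(6)
  m1 <- array(3, c(1, 1, 1))
  expect_equal(as.vector(cbamSpatialMap(m1, array(1, c(1, 1, 2)))),
               1 / (1 + exp(-6)))
  expect_error(cbamSpatialMap(m, array(0, c(2, 2, 2))), "odd")
})

test_that("ECA kernel size follows the adaptive law with odd rounding and floor 3", {
  expect_equal(ecaKernelSize(256, 2, 1), 5L)  # t = 5
  expect_equal(ecaKernelSize(512, 2, 1), 5L)  # t = 5.5, nearest odd is 5
  expect_equal(ecaKernelSize(2, 2, 1), 3L)    # t = 1.5, floored at 3
  expect_equal(ecaKernelSize(64, 2, 1), 5L)   # t = 4, tie 3/5 rounds up
  expect_error(ecaKernelSize(0), "invalid")
})

test_that("ECA weights are a sigmoid of a zero-padded 1-D convolution", {
  m <- array(1, c(4, 2, 2))
  expect_equal(ecaChannelWeights(m, c(0, 0, 0)), rep(0.5, 4))
  w <- ecaChannelWeights(m, c(1, 1, 1))
  sig <- function(x) 1 / (1 + exp(-x))
  expect_equal(w, c(sig(2), sig(3), sig(3), sig(2)))
  m2 <- randMap(5, C = 8)
  w2 <- ecaChannelWeights(m2, rnorm(3))
  expect_true(all(w2 > 0 & w2 < 1))
  expect_error(ecaChannelWeights(m2, rnorm(4)), "invalid")
})

test_that("attention operations match brute-force equation evaluation on random maps", {
  sig <- function(x) 1 / (1 + exp(-x))
  for (s in 1:20) {
    m <- randMap(s, C = 3, H = 4, W = 4)
    # squeeze / excite
    z <- vapply(1:3, function(c) sum(m[c, , ]) / 16, numeric(1))
    expect_equal(seSqueeze(m), z, tolerance = 1e-6)
    set.seed(s + 100)
    W1 <- matrix(rnorm(9), 3, 3); W2 <- matrix(rnorm(9), 3, 3)
    sOracle <- as.vector(sig(W2 %*% pmax(W1 %*% z, 0)))
    expect_equal(seExcite(z, W1, W2), sOracle, tolerance = 1e-6)
    out <- applyChannelWeights(m, sOracle)
    for (c in 1:3) for (i in 1:4) for (j in 1:4)
      expect_equal(out[c, i, j], sOracle[c] * m[c, i, j], tolerance = 1e-6)
    # CBAM channel
    zmax <- vapply(1:3, function(c) max(m[c, , ]), numeric(1))
    mcOracle <- as.vector(sig(W2 %*% pmax(W1 %*% z, 0) +
                                W2 %*% pmax(W1 %*% zmax, 0)))
    expect_equal(cbamChannelWeights(m, W1, W2), mcOracle, tolerance = 1e-6)
    # CBAM spatial, brute-force same-padded convolution
    k <- array(rnorm(18), c(3, 3, 2))
    avg <- apply(m, c(2, 3), mean); mx <- apply(m, c(2, 3), max)
    oracle <- matrix(0, 4, 4)
    for (i in 1:4) for (j in 1:4) {
      acc <- 0
      for (di in -1:1) for (dj in -1:1) {
        ii <- i + di; jj <- j + dj
        if (ii >= 1 && ii <= 4 && jj >= 1 && jj <= 4)
          acc <- acc + k[di + 2, dj + 2, 1] * avg[ii, jj] +
                 k[di + 2, dj + 2, 2] * mx[ii, jj]
      }
      oracle[i, j] <- sig(acc)
    }
    expect_equal(cbamSpatialMap(m, k)[1, , ], oracle, tolerance = 1e-6)
    # ECA, brute-force 1-D zero-padded convolution (C = 3 -> k = 3)
    ker <- rnorm(3)
    zpad <- c(0, z, 0)
    ecaOracle <- sig(vapply(1:3, function(c)
      sum(ker * zpad[c:(c + 2)]), numeric(1)))
    expect_equal(ecaChannelWeights(m, ker), ecaOracle, tolerance = 1e-6)
  }
})
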