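# Model factory, DSC blocks, profiling, and structural invariants of the
# residual networks.

test_that("DSC factorisation has the closed-form weight counts", {
  b <- buildDscBlock(64, 128, 3)
  expect_equal(unname(b$weightCounts["depthwise"]), 9 * 64)
  expect_equal(unname(b$weightCounts["pointwise"]), 64 * 128)
  expect_equal(unname(b$weightCounts["total"]), 8768)
  expect_equal(unname(b$weightCounts["standard"]), 73728)
  expect_lt(b$weightCounts["total"], b$weightCounts["standard"])
  expect_error(buildDscBlock(64, 128, 4), "odd")
})

test_that("the depthwise stage is channel-separable and shape-preserving", {
  sf <- asNamespace("seedfuse")
  b <- buildDscBlock(3, 8, 3, stride = 1)
  ini <- sf$initParams(b$layers[1], 4)  # depthwise conv alone
  set.seed(1)
  x <- array(rnorm(6 * 6 * 3 * 1), c(6, 6, 3, 1))
  y <- sf$netForward(b$layers[1], ini$params, ini$state, x)$y
  expect_equal(dim(y), c(6, 6, 3, 1))
  # zero all channels but c: channel c's output is unchanged
  for (c in 1:3) {
    x0 <- x * 0
    x0[, , c, ] <- x[, , c, ]
    y0 <- sf$netForward(b$layers[1], ini$params, ini$state, x0)$y
    expect_equal(y0[, , c, ], y[, , c, ])
  }
  # strided DSC matches the standard convolution's output shape
  b2 <- buildDscBlock(3, 8, 3, stride = 2)
  ini2 <- sf$initParams(b2$layers, 4)
  y2 <- sf$netForward(b2$layers, ini2$params, ini2$state, x, train = TRUE)$y
  expect_equal(dim(y2), c(3, 3, 8, 1))
})

test_that("the classifier outputs a softmax distribution of the right width", {
  m <- buildModel(modelConfig(depth = 18, numClasses = 8), rngSeed = 1)
  set.seed(2)
  x <- array(runif(64 * 64 * 3 * 2), c(64, 64, 3, 2))
  p <- predictSeedNet(m, x)
  expect_equal(dim(p), c(8, 2))
  expect_equal(colSums(p), c(1, 1))
  expect_true(all(p > 0))
  # global pooling absorbs a different input size (e.g. unresized 1x2 panels)
  x2 <- array(runif(32 * 64 * 3), c(32, 64, 3))
  expect_equal(nrow(predictSeedNet(m, x2)), 8)
  expect_error(buildModel(modelConfig(depth = 20)), "depth")
})

test_that("attention blocks sit after conv2 and conv3 by default, once each", {
  sf <- asNamespace("seedfuse")
  countAtt <- function(arch) sum(vapply(arch, function(d)
    d$t %in% c("se", "cbam", "eca"), logical(1)))
  arch <- sf$resnetArch(modelConfig(depth = 50, attention = "cbam"), 8)
  expect_equal(countAtt(arch), 2)
  types <- vapply(arch, function(d) d$t, character(1))
  # attention follows the last block of stages 2 and 3 (blocks 3 and 3+4)
  resIdx <- which(types == "res")
  attIdx <- which(types == "cbam")
  expect_equal(attIdx, c(resIdx[3] + 1, resIdx[7] + 1))
  arch4 <- sf$resnetArch(modelConfig(depth = 50, attention = "eca",
                                     attentionSites = c("conv2", "conv3",
                                                        "conv4", "conv5")), 8)
  expect_equal(countAtt(arch4), 4)
  expect_equal(countAtt(sf$resnetArch(modelConfig(depth = 50), 8)), 0)
})

test_that("a residual block with zero weights and identity BN is the identity on nonnegative input", {
  sf <- asNamespace("seedfuse")
  blk <- list(sf$basicBlock("r", 4, 4, 1, FALSE))  # no downsample path
  ini <- sf$initParams(blk, 1)
  params <- lapply(ini$params, function(p) p * 0)
  params$r_dbn.g <- NULL
  for (nm in names(params)) if (grepl("bn\\.g$", nm)) params[[nm]][] <- 1
  x <- array(abs(rnorm(5 * 5 * 4 * 2)), c(5, 5, 4, 2))
  y <- sf$netForward(blk, params, ini$state, x, train = FALSE)$y
  expect_equal(y, x)
})

test_that("forcing attention weights to one reproduces the unattended network", {
  for (att in c("se", "cbam", "eca")) {
    mAtt <- buildModel(modelConfig(depth = 18, attention = att,
                                   numClasses = 4), rngSeed = 3)
    mNone <- buildModel(modelConfig(depth = 18, numClasses = 4), rngSeed = 3)
    # same backbone seed: shared layers have identical weights
    common <- intersect(names(mAtt@params), names(mNone@params))
    for (nm in common) mAtt@params[[nm]] <- mNone@params[[nm]]
    set.seed(4)
    x <- array(runif(32 * 32 * 3 * 2), c(32, 32, 3, 2))
    expect_equal(predictSeedNet(mAtt, x, neutralAttention = TRUE),
                 predictSeedNet(mNone, x), tolerance = 1e-12,
                 label = paste("neutral", att))
  }
})

test_that("profiling counts parameters and MACs with the conv+FC convention", {
  # closed-form FC head count: 2048 * 1000 + 1000
  sf <- asNamespace("seedfuse")
  fcOnly <- sf$walkProfile(list(list(t = "fc", nm = "f", din = 2048,
                                     dout = 1000)), 1, 1, 2048)
  expect_equal(fcOnly$params, 2048 * 1000 + 1000)
  expect_equal(fcOnly$macs, 2048 * 1000)
  # an 8-class FC head: 2048 * 8 + 8 = 16392
  fc8 <- sf$walkProfile(list(list(t = "fc", nm = "f", din = 2048, dout = 8)),
                        1, 1, 2048)
  expect_equal(fc8$params, 16392)
  # analytic count equals the instantiated weight count (training head)
  cfg <- modelConfig(depth = 18, attention = "se", dscStages = "conv4",
                     numClasses = 8)
  m <- buildModel(cfg, rngSeed = 1)
  expect_equal(sum(vapply(m@params, length, numeric(1))),
               paramsTotal(profileModel(cfg, headClasses = 8)))
})

test_that("profile ordering matches the module cost structure at depth 50", {
  base <- profileModel(modelConfig(depth = 50))
  cbam <- profileModel(modelConfig(depth = 50, attention = "cbam"))
  dsc <- profileModel(modelConfig(depth = 50, dscStages = "conv4"))
  expect_lt(paramsTotal(dsc), paramsTotal(base))
  expect_lt(paramsTotal(base), paramsTotal(cbam))
  expect_lt(macsTotal(dsc), macsTotal(base))
  expect_lt(macsTotal(base), macsTotal(cbam))
  # any DSC stage set strictly reduces parameters
  dsc45 <- profileModel(modelConfig(depth = 50, dscStages = c("conv4",
                                                              "conv5")))
  expect_lt(paramsTotal(dsc45), paramsTotal(dsc))
})

test_that("gradients agree with central finite differences on a composite net", {
  sf <- asNamespace("seedfuse")
  set.seed(9)
  arch <- c(list(sf$convD("c1", 3, 1, 1, 3, 6), sf$bnD("b1", 6), sf$reluD,
                 list(t = "maxpool", k = 3L, s = 2L, p = 1L)),
            list(sf$basicBlock("r1", 6, 8, 2, FALSE)),
            list(sf$bottleneckBlock("r2", 8, 4, 1, TRUE)),
            list(list(t = "se", nm = "a1", c = 16, r = 4)),
            list(list(t = "cbam", nm = "a2", c = 16, r = 4, k = 3L)),
            list(list(t = "eca", nm = "a3", c = 16, k = 3L)),
            list(list(t = "gap"), list(t = "fc", nm = "f", din = 16,
                                       dout = 3)))
  ini <- sf$initParams(arch, 5)
  params <- ini$params
  x <- array(rnorm(13 * 11 * 3 * 3), c(13, 11, 3, 3))
  yIdx <- c(1, 3, 2)
  lossOf <- function(p)
    sf$softmaxLoss(sf$netForward(arch, p, ini$state, x, train = TRUE)$y,
                   yIdx)$loss
  fw <- sf$netForward(arch, params, ini$state, x, train = TRUE)
  sl <- sf$softmaxLoss(fw$y, yIdx)
  gacc <- new.env(); gacc$g <- list()
  sf$netBackward(arch, params, fw$caches, sl$dlogits, gacc)
  eps <- 1e-6
  for (nm in names(gacc$g)) {
    g <- gacc$g[[nm]]
    for (i in sample(length(g), min(2, length(g)))) {
      p2 <- params; p2[[nm]][i] <- p2[[nm]][i] + eps
      p3 <- params; p3[[nm]][i] <- p3[[nm]][i] - eps
      num <- (lossOf(p2) - lossOf(p3)) / (2 * eps)
      expect_equal(g[i], num, tolerance = 5e-4,
                   label = paste("grad", nm, i))
    }
  }
})
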