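test_that("grayscale conversion uses BT.601 luminance and validates channels", {
  g <- toGrayscale(array(100, c(2, 2, 3)))
  expect_equal(g, matrix(100, 2, 2))
  red <- array(0, c(1, 1, 3)); red[1, 1, 1] <- 255
  expect_equal(toGrayscale(red)[1, 1], 0.299 * 255)  # 76.245
  expect_error(toGrayscale(array(1, c(4, 4, 2))), "invalid")
})

test_that("automatic thresholding matches a brute-force Otsu oracle", {
  set.seed(3)
  img <- matrix(sample(c(rep(50, 60), rep(200, 40))), 10, 10)
  bin <- binarizeAuto(img)
  expect_gt(bin$threshold, 50)
  expect_lt(bin$threshold, 200)
  expect_equal(sum(bin$mask), 40)            # foreground = bright minority
  expect_true(all(img[bin$mask] == 200))
  # oracle agreement on the induced partition, over random bimodal images
  for (s in 1:5) {
    set.seed(s)
    img <- matrix(round(c(rnorm(300, 70, 10), rnorm(80, 190, 12))), 20, 19)
    img <- pmin(pmax(img, 0), 255)
    bin <- binarizeAuto(img)
    tOracle <- otsuBruteForce(img)
    expect_identical(bin$mask, img > tOracle)
    expect_lte(bin$foregroundFraction, 0.5)
  }
  expect_error(binarizeAuto(matrix(7, 5, 5)), "degenerate")
})

test_that("foreground polarity always picks the minority class", {
  img <- matrix(c(rep(20, 70), rep(230, 30)), 10, 10)
  expect_lte(binarizeAuto(img)$foregroundFraction, 0.5)
  expect_lte(binarizeAuto(255 - img)$foregroundFraction, 0.5)
  expect_identical(binarizeAuto(img)$mask, binarizeAuto(255 - img)$mask)
})

test_that("morphological cleaning removes specks, keeps large shapes, and is idempotent", {
  speck <- matrix(FALSE, 30, 30); speck[15, 15] <- TRUE
  expect_false(any(morphologicalClean(speck, 2)))
  square <- matrix(FALSE, 80, 80); square[16:65, 16:65] <- TRUE
  cleaned <- morphologicalClean(square, 2)
  # opening/closing preserve a large convex shape up to a 1-px boundary band
  expect_lte(sum(xor(cleaned, square)), 4 * 50 + 4)
  expect_gte(sum(cleaned), 50 * 50 - 4 * 50)
  once <- morphologicalClean(square, 2)
  expect_identical(morphologicalClean(once, 2), once)
  expect_error(morphologicalClean(square, 0), "invalid")
})

test_that("connected-component labeling is 8-connected", {
  m <- matrix(FALSE, 6, 6)
  m[2, 2] <- TRUE; m[3, 3] <- TRUE  # diagonal touch: one component
  lab <- seedfuse:::label8(m)
  expect_equal(max(lab), 1)
  m[5, 5] <- TRUE                    # separated: second component
  expect_equal(max(seedfuse:::label8(m)), 2)
})

test_that("crops are 224x224x3, centred on ground-truth seeds, in row-major order", {
  rb <- smallBoard(nSeeds = 6, seed = 31, size = 520)
  crops <- segmentBoard(rb$board)
  expect_length(crops, 6)
  for (cr in crops) {
    expect_s4_class(cr, "SeedCrop")
    expect_equal(dim(pixels(cr)), c(224, 224, 3))
  }
  # bijection: each crop centre within 5 px of a distinct ground-truth centre
  centers <- t(vapply(crops, function(cr) {
    bb <- sourceBbox(cr); c((bb[1] + bb[3]) / 2, (bb[2] + bb[4]) / 2)
  }, numeric(2)))
  gtc <- seedCenters(rb$groundTruth)
  matched <- integer(0)
  for (i in seq_len(nrow(centers))) {
    d <- sqrt(rowSums((gtc - matrix(centers[i, ], nrow(gtc), 2,
                                    byrow = TRUE))^2))
    j <- which.min(d)
    expect_lt(d[j], 5)
    matched <- c(matched, j)
  }
  expect_equal(sort(matched), seq_len(nrow(gtc)))
  # row-major centroid order
  expect_true(!is.unsorted(centers[, 1]))
})

test_that("an empty mask yields an empty crop list with a warning", {
  board <- array(10, c(300, 300, 3))
  mask <- matrix(FALSE, 300, 300)
  expect_warning(crops <- extractSeedCrops(board, mask), "empty")
  expect_length(crops, 0)
})

test_that("segmentation composes its stages and is deterministic", {
  rb <- smallBoard(nSeeds = 5, seed = 41, size = 520)
  gray <- toGrayscale(rb$board)
  mask <- morphologicalClean(binarizeAuto(gray)$mask, 2)
  viaStages <- extractSeedCrops(rb$board, mask)
  direct <- segmentBoard(rb$board)
  expect_equal(length(direct), length(viaStages))
  expect_identical(lapply(direct, pixels), lapply(viaStages, pixels))
  again <- segmentBoard(rb$board)
  expect_identical(lapply(direct, pixels), lapply(again, pixels))
})

test_that("a seed-free board produces no crops", {
  profs <- makeVarietyProfiles(2, rngSeed = 1)
  rb <- renderBoard(profs, BoardSpec(400, 400, nSeeds = 0, rngSeed = 2),
                    c(0, 0))
  expect_length(segmentBoard(rb$board), 0)
})

test_that("inverting board brightness leaves the crop geometry unchanged", {
  rb <- smallBoard(nSeeds = 5, seed = 51, size = 520)
  crops <- segmentBoard(rb$board)
  cropsInv <- segmentBoard(255 - rb$board)
  expect_equal(length(cropsInv), length(crops))
  expect_identical(lapply(crops, sourceBbox), lapply(cropsInv, sourceBbox))
})
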