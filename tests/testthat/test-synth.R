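test_that("variety profiles are distinct, seeded, and validated", {
  profs <- makeVarietyProfiles(8, rngSeed = 7)
  expect_length(profs, 8)
  arch <- vapply(profs, function(p) p@spectralArchetype,
                 numeric(length(wavelengthGrid())))
  d <- as.matrix(dist(t(arch)))
  expect_true(all(d[upper.tri(d)] > 0))
  cols <- t(vapply(profs, function(p) p@meanColor, numeric(3)))
  expect_equal(anyDuplicated(cols), 0)
  # fixed-seed determinism
  expect_identical(profs, makeVarietyProfiles(8, rngSeed = 7))
  expect_error(makeVarietyProfiles(0, rngSeed = 7), "invalid")
})

test_that("grouped profiles collapse the requested modality's signal", {
  profs <- makeVarietyProfiles(8, rngSeed = 3, colorGroups = 4,
                               spectralGroups = 2)
  cols <- t(vapply(profs, function(p) p@meanColor, numeric(3)))
  arch <- vapply(profs, function(p) p@spectralArchetype,
                 numeric(length(wavelengthGrid())))
  expect_equal(nrow(unique(cols)), 4)
  expect_equal(nrow(unique(t(arch))), 2)
  # the (colour, spectrum) pair still identifies each class
  key <- paste(apply(cols, 1, paste, collapse = ","),
               colSums(arch))
  expect_equal(anyDuplicated(key), 0)
})

test_that("rendered boards respect separation, record every seed, and are pure functions of the seed", {
  rb <- smallBoard(nSeeds = 8, seed = 21, size = 600)
  gt <- rb$groundTruth
  expect_equal(nrow(seedCenters(gt)), 8)
  expect_length(seedLabels(gt), 8)
  d <- dist(seedCenters(gt))
  expect_true(all(d >= 90))
  bb <- seedBboxes(gt)
  expect_true(all(bb[, 1] >= 1 & bb[, 2] >= 1 & bb[, 3] <= 600 & bb[, 4] <= 600))
  rb2 <- smallBoard(nSeeds = 8, seed = 21, size = 600)
  expect_identical(rb$board, rb2$board)
  expect_identical(seedCenters(rb$groundTruth), seedCenters(rb2$groundTruth))
})

test_that("an empty board has no seeds and no ground truth", {
  profs <- makeVarietyProfiles(2, rngSeed = 1)
  rb <- renderBoard(profs, BoardSpec(400, 400, nSeeds = 0, rngSeed = 5),
                    c(0, 0))
  expect_equal(nrow(seedCenters(rb$groundTruth)), 0)
  # background only: all pixels near the background level
  expect_lt(max(rb$board), 45)
})

test_that("infeasible packing raises a capacity error", {
  profs <- makeVarietyProfiles(2, rngSeed = 1)
  # 500 disks of radius 15 cannot fit in 200x200
  expect_error(
    renderBoard(profs, BoardSpec(200, 200, nSeeds = 500, minSeparation = 30,
                                 rngSeed = 1), c(250, 250)),
    "capacity")
})

test_that("sampled spectra follow the stated noise model", {
  profs <- makeVarietyProfiles(2, rngSeed = 9)
  p0 <- profs[[1]]
  # zero noise: the curve is exactly the archetype
  p0@spectralNoiseSd <- 0
  expect_equal(reflectance(sampleSpectrum(p0, 4)), p0@spectralArchetype)
  # determinism
  expect_identical(sampleSpectrum(profs[[2]], 3), sampleSpectrum(profs[[2]], 3))
  # Monte-Carlo: per-wavelength sd within 20% of the nominal 0.05 away
  # from the clip boundaries
  p1 <- profs[[1]]
  p1@spectralNoiseSd <- 0.05
  draws <- vapply(1:1000, function(i) reflectance(sampleSpectrum(p1, i)),
                  numeric(length(wavelengthGrid())))
  interior <- p1@spectralArchetype > 0.2 & p1@spectralArchetype < 0.8
  sds <- apply(draws[interior, ], 1, sd)
  expect_true(all(abs(sds - 0.05) < 0.2 * 0.05))
})

test_that("dataset plan and manifest carry the full class-balanced seed count", {
  profs <- makeVarietyProfiles(8, rngSeed = 2)
  # the study-scale plan: 8 x 1600 seeds in boards of 80
  plan <- boardPlan(profs, 1600, rngSeed = 42)
  expect_equal(sum(vapply(plan, function(b) sum(b$classCounts), numeric(1))),
               12800)
  expect_length(plan, 160)
  # small in-memory dataset: balanced labels, determinism
  profs2 <- makeVarietyProfiles(2, rngSeed = 2)
  ds <- generateDataset(profs2, 5, rngSeed = 1, seedsPerBoard = 10,
                        boardHeight = 700, boardWidth = 700)
  expect_equal(nrow(ds$manifest), 10)
  expect_equal(unname(table(ds$manifest$label)), c(5L, 5L),
               ignore_attr = TRUE)
  ds2 <- generateDataset(profs2, 5, rngSeed = 1, seedsPerBoard = 10,
                         boardHeight = 700, boardWidth = 700)
  expect_identical(ds$manifest, ds2$manifest)
  expect_length(ds$spectra, 10)
})

test_that("a nearest-archetype classifier separates noiseless spectra perfectly", {
  profs <- makeVarietyProfiles(8, rngSeed = 13)
  arch <- vapply(profs, function(p) p@spectralArchetype,
                 numeric(length(wavelengthGrid())))
  for (i in seq_along(profs)) {
    p <- profs[[i]]
    p@spectralNoiseSd <- 0
    r <- reflectance(sampleSpectrum(p, 1))
    d <- colSums((arch - r)^2)
    expect_equal(which.min(d), i)
  }
})
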