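# Synthetic seed boards, crops and class-structured reflectance spectra.
# The generator emulates the study conditions of the real acquisition:
# 8 varieties, 1600 seeds per variety photographed on boards of ~80
# non-touching seeds, one reflectance curve per seed on the 350-2500 nm
# grid. Class signal is placed in both modalities by default; the
# colorGroups/spectralGroups arguments collapse either modality's signal
# so fusion-benefit experiments can split the signal across modalities.

#' Generate variety profiles for the synthetic seed generator
#'
#' Builds `k` generative profiles with pairwise-distinct mean colours and
#' pairwise-distinct smooth spectral archetypes (sums of broad Gaussian
#' bumps over the standard wavelength grid plus a gentle slope).
#'
#' Class signal can be restricted to one modality: with `colorGroups < k`,
#' several varieties share a colour (appearance no longer identifies the
#' class); with `spectralGroups < k`, several share an archetype. The
#' (colour group, spectral group) pair is assigned on a grid so that with
#' `colorGroups * spectralGroups >= k` every class is jointly identifiable
#' even when neither modality identifies it alone.
#'
#' @param k Number of varieties (>= 1).
#' @param rngSeed Integer seed; the result is a pure function of it.
#' @param colorGroups,spectralGroups Number of distinct colour / spectral
#'   archetype levels (defaults `k`: fully distinct in both modalities).
#' @param spectralNoiseSd Per-wavelength reflectance noise SD (default 0.02).
#' @param textureAmp Seed texture amplitude (default 0.08).
#' @return List of [VarietyProfile-class] objects.
#' @export
#' @examples
#' profs <- makeVarietyProfiles(8, rngSeed = 7)
#' length(profs)
makeVarietyProfiles <- function(k, rngSeed, colorGroups = k,
                                spectralGroups = k,
                                spectralNoiseSd = 0.02, textureAmp = 0.08) {
  stopIfNot(is.numeric(k) && length(k) == 1 && k >= 1,
            "invalid argument: 'k' must be >= 1")
  k <- as.integer(k)
  stopIfNot(colorGroups >= 1 && spectralGroups >= 1,
            "invalid argument: group counts must be >= 1")
  stopIfNot(colorGroups * spectralGroups >= k,
            "invalid argument: colorGroups * spectralGroups must cover k classes")
  wl <- wavelengthGrid()
  withSeed(rngSeed, {
    # Distinct colours with luminance confined to [~125, ~185]: bright
    # enough that every seed pixel clears the background/seed threshold,
    # and narrow enough that the Otsu split always falls between
    # background and seeds rather than between seed classes.
    hues <- (seq_len(colorGroups) - 1) / colorGroups + runif(1, 0, 1 / (2 * colorGroups))
    sat <- runif(colorGroups, 0.15, 0.4)
    ltarget <- seq(125, 180, length.out = max(colorGroups, 2))[seq_len(colorGroups)]
    rgb1 <- t(grDevices::col2rgb(grDevices::hsv(hues %% 1, sat, 1)))
    lum1 <- as.vector(rgb1 %*% c(0.299, 0.587, 0.114))
    cols <- rgb1 * pmin(1, ltarget / lum1)
    # smooth archetypes: baseline + slope + 3 broad Gaussian bumps per group
    arch <- matrix(0, spectralGroups, length(wl))
    for (g in seq_len(spectralGroups)) {
      base <- runif(1, 0.12, 0.3)
      slope <- runif(1, -0.08, 0.12)
      a <- base + slope * (wl - 350) / 2150
      for (b in 1:3) {
        ctr <- runif(1, 450, 2300)
        wid <- runif(1, 80, 260)
        amp <- runif(1, 0.08, 0.28)
        a <- a + amp * exp(-((wl - ctr)^2) / (2 * wid^2))
      }
      arch[g, ] <- pmin(pmax(a, 0.02), 0.95)
    }
    lapply(seq_len(k), function(i) {
      cg <- ((i - 1) %% colorGroups) + 1
      # full spectral resolution: one archetype per class; otherwise a
      # mixed-radix assignment so the (colour, spectrum) pair is unique
      sg <- if (spectralGroups == k) i else
        (((i - 1) %/% colorGroups) %% spectralGroups) + 1
      new("VarietyProfile",
          name = sprintf("V%02d", i),
          meanColor = as.numeric(cols[cg, ]),
          colorSd = 6,
          axisMean = c(runif(1, 15, 22), runif(1, 10, 14)),
          axisSd = 1.2,
          textureAmp = textureAmp,
          spectralArchetype = arch[sg, ],
          spectralNoiseSd = spectralNoiseSd)
    })
  })
}

# Pixel mask of one rotated ellipse, clipped to an H x W canvas. Computed
# separately from the assignment so callers can paint their own (possibly
# large) arrays in place. Consumes RNG for the texture field.
ellipsePatch <- function(H, W, center, axes, angle, textureAmp) {
  R <- ceiling(max(axes)) + 1L
  r0 <- max(1L, floor(center[1] - R)); r1 <- min(H, ceiling(center[1] + R))
  c0 <- max(1L, floor(center[2] - R)); c1 <- min(W, ceiling(center[2] + R))
  rows <- r0:r1; cols <- c0:c1
  dy <- rows - center[1]; dx <- cols - center[2]
  ca <- cos(angle); sa <- sin(angle)
  u <- outer(dy, dx, function(y, x) (x * ca + y * sa) / axes[1])
  v <- outer(dy, dx, function(y, x) (-x * sa + y * ca) / axes[2])
  inside <- (u^2 + v^2) <= 1
  tex <- 1 + textureAmp * runif(sum(inside), -1, 1)
  ir <- if (any(inside)) range(rows[rowSums(inside) > 0]) else c(r0, r1)
  ic <- if (any(inside)) range(cols[colSums(inside) > 0]) else c(c0, c1)
  # linear indices of inside pixels per channel plane
  idx <- which(inside)
  pr <- rows[(idx - 1) %% length(rows) + 1]
  pc <- cols[(idx - 1) %/% length(rows) + 1]
  list(lin = pr + (pc - 1) * H, tex = tex,
       bbox = c(ir[1], ic[1], ir[2], ic[2]))
}


#' Render a synthetic seed board with ground truth
#'
#' Places `spec@nSeeds` seeds (rotated ellipses with per-seed colour jitter
#' and low-amplitude texture) on a dark background. Centres are rejection
#' sampled to be at least `spec@minSeparation` apart and clear of the
#' border, so seeds never touch each other or the edge. A capacity error is
#' raised if placement fails within 10,000 attempts.
#'
#' @param profiles List of [VarietyProfile-class].
#' @param spec A [BoardSpec-class].
#' @param classCounts Integer vector, one count per profile, summing to
#'   `spec@nSeeds`.
#' @return List with `board` (H x W x 3 array in \[0, 255\]) and
#'   `groundTruth` ([GroundTruth-class]).
#' @export
renderBoard <- function(profiles, spec, classCounts) {
  stopIfNot(length(classCounts) == length(profiles),
            "invalid argument: one count per profile required")
  stopIfNot(sum(classCounts) == spec@nSeeds,
            "invalid argument: sum(classCounts) must equal spec@nSeeds")
  H <- spec@height; W <- spec@width
  n <- as.integer(spec@nSeeds)
  withSeed(spec@rngSeed, {
    board <- array(rep(spec@backgroundColor, each = H * W), c(H, W, 3))
    board <- board + array(rnorm(H * W * 3, 0, 1.5), c(H, W, 3))
    board <- pmin(pmax(board, 0), 255)
    if (n == 0L)
      return(list(board = board,
                  groundTruth = new("GroundTruth",
                                    centers = matrix(numeric(0), 0, 2),
                                    labels = character(0),
                                    bboxes = matrix(numeric(0), 0, 4))))
    maxAxis <- max(vapply(profiles, function(p) max(p@axisMean) + 3 * p@axisSd,
                          numeric(1)))
    margin <- ceiling(maxAxis) + 4
    if (2 * margin >= H || 2 * margin >= W)
      stop("capacity: board too small for seed size (border margin ",
           margin, " px)", call. = FALSE)
    classIdx <- sample(rep(seq_along(profiles), times = classCounts))
    centers <- matrix(NA_real_, n, 2)
    attempts <- 0L
    for (s in seq_len(n)) {
      repeat {
        attempts <- attempts + 1L
        if (attempts > 10000L)
          stop("capacity: could not place ", n, " seeds with min_separation ",
               spec@minSeparation, " on a ", H, "x", W, " board", call. = FALSE)
        cand <- c(runif(1, margin, H - margin), runif(1, margin, W - margin))
        if (s == 1L) { centers[s, ] <- cand; break }
        d2 <- (centers[seq_len(s - 1), 1] - cand[1])^2 +
              (centers[seq_len(s - 1), 2] - cand[2])^2
        if (min(d2) >= spec@minSeparation^2) { centers[s, ] <- cand; break }
      }
    }
    bboxes <- matrix(0, n, 4)
    labels <- character(n)
    plane <- H * W
    for (s in seq_len(n)) {
      p <- profiles[[classIdx[s]]]
      axes <- pmax(p@axisMean + rnorm(2, 0, p@axisSd), 6)
      angle <- runif(1, 0, pi)
      col <- pmin(pmax(p@meanColor + rnorm(3, 0, p@colorSd), 0), 255)
      patch <- ellipsePatch(H, W, centers[s, ], axes, angle, p@textureAmp)
      for (ch in 1:3)  # in place: board is local to this frame
        board[patch$lin + (ch - 1) * plane] <-
          pmin(pmax(col[ch] * patch$tex, 0), 255)
      bboxes[s, ] <- patch$bbox
      labels[s] <- p@name
    }
    list(board = board,
         groundTruth = new("GroundTruth", centers = centers, labels = labels,
                           bboxes = bboxes))
  })
}

#' Sample one reflectance spectrum from a variety profile
#'
#' Archetype plus i.i.d. per-wavelength Gaussian noise with
#' `profile@spectralNoiseSd`, clipped to \[0, 1\].
#'
#' @param profile A [VarietyProfile-class].
#' @param rngSeed Integer seed; deterministic given the seed.
#' @return A [SpectralCurve-class] on the standard grid.
#' @export
sampleSpectrum <- function(profile, rngSeed) {
  wl <- wavelengthGrid()
  withSeed(rngSeed, {
    r <- profile@spectralArchetype +
      rnorm(length(wl), 0, profile@spectralNoiseSd)
    SpectralCurve(wl, pmin(pmax(r, 0), 1))
  })
}

#' Plan the board layout of a synthetic dataset
#'
#' Deterministically assigns `nPerClass` seeds of each variety to boards of
#' `seedsPerBoard` seeds (the last board may be smaller) and derives one
#' child seed per board, so boards can be rendered lazily one at a time.
#'
#' @inheritParams generateDataset
#' @return List of per-board entries `list(spec, classCounts)`.
#' @export
boardPlan <- function(profiles, nPerClass, rngSeed, seedsPerBoard = 80,
                      boardHeight = 1600, boardWidth = 1600,
                      minSeparation = 80) {
  stopIfNot(nPerClass >= 1, "invalid argument: nPerClass must be >= 1")
  k <- length(profiles)
  total <- k * as.integer(nPerClass)
  pool <- withSeed(childSeed(rngSeed, 0), sample(rep(seq_len(k), each = nPerClass)))
  starts <- seq(1, total, by = seedsPerBoard)
  lapply(seq_along(starts), function(b) {
    idx <- pool[starts[b]:min(starts[b] + seedsPerBoard - 1, total)]
    counts <- tabulate(idx, nbins = k)
    list(spec = BoardSpec(height = boardHeight, width = boardWidth,
                          nSeeds = length(idx), minSeparation = minSeparation,
                          rngSeed = childSeed(rngSeed, b)),
         classCounts = counts)
  })
}

#' Generate a labelled synthetic dataset (boards, spectra, manifest)
#'
#' Renders all boards of [boardPlan()], samples one spectrum per planted
#' seed, and returns a manifest linking seed identity to label and
#' spectrum. Total seeds = `nPerClass * length(profiles)`.
#'
#' @param profiles List of [VarietyProfile-class].
#' @param nPerClass Seeds per variety (>= 1).
#' @param rngSeed Integer master seed; the whole dataset is a pure function
#'   of it.
#' @param seedsPerBoard Seeds per rendered board (default 80).
#' @param boardHeight,boardWidth Board size in pixels (default 1600).
#' @param minSeparation Minimum seed-centre distance (default 80 px).
#' @param keepBoards Keep rendered boards in the result (default TRUE;
#'   set FALSE for large datasets and re-render from the plan instead).
#' @param spectra Sample per-seed spectra (default TRUE).
#' @return List with `manifest` (data frame: seed_id, board, center_row,
#'   center_col, label, spectrum_seed), `boards`, `groundTruths`,
#'   `spectra`, and `plan`.
#' @export
generateDataset <- function(profiles, nPerClass, rngSeed, seedsPerBoard = 80,
                            boardHeight = 1600, boardWidth = 1600,
                            minSeparation = 80, keepBoards = TRUE,
                            spectra = TRUE) {
  plan <- boardPlan(profiles, nPerClass, rngSeed, seedsPerBoard,
                    boardHeight, boardWidth, minSeparation)
  boards <- list(); gts <- list(); specs <- list()
  rows <- list()
  seedId <- 0L
  for (b in seq_along(plan)) {
    rb <- renderBoard(profiles, plan[[b]]$spec, plan[[b]]$classCounts)
    gt <- rb$groundTruth
    if (keepBoards) boards[[b]] <- rb$board
    gts[[b]] <- gt
    nb <- nrow(gt@centers)
    if (nb > 0) {
      ids <- seedId + seq_len(nb)
      profByName <- stats::setNames(profiles,
                                    vapply(profiles, function(p) p@name, ""))
      for (j in seq_len(nb)) {
        sseed <- childSeed(rngSeed, 1000000 + ids[j])
        if (spectra)
          specs[[ids[j]]] <- sampleSpectrum(profByName[[gt@labels[j]]], sseed)
        rows[[ids[j]]] <- data.frame(
          seed_id = sprintf("seed%05d", ids[j]),
          board = sprintf("board%04d", b),
          center_row = gt@centers[j, 1], center_col = gt@centers[j, 2],
          label = gt@labels[j], spectrum_seed = sseed,
          stringsAsFactors = FALSE)
      }
      seedId <- seedId + nb
    }
  }
  list(manifest = do.call(rbind, rows), boards = boards, groundTruths = gts,
       spectra = specs, plan = plan)
}

#' Render a single-seed crop directly (no board segmentation)
#'
#' Draws one seed of the given variety filling most of a 224x224 crop on
#' the board background, as the segmentation stage would produce. Used by
#' desk-scale classification experiments where running the full board
#' pipeline would only add time, not information.
#'
#' @param profile A [VarietyProfile-class].
#' @param rngSeed Integer seed.
#' @param background RGB background intensities (default dark board).
#' @return A [SeedCrop-class].
#' @export
renderSeedCrop <- function(profile, rngSeed, background = c(30, 30, 30)) {
  withSeed(rngSeed, {
    img <- array(rep(background, each = 224 * 224), c(224, 224, 3))
    img <- pmin(pmax(img + array(rnorm(224 * 224 * 3, 0, 1.5), dim(img)), 0), 255)
    ax <- pmax(profile@axisMean + rnorm(2, 0, profile@axisSd), 6)
    scale <- 70 / max(ax)  # seed fills ~60% of the crop, like bbox crops do
    axes <- ax * scale
    angle <- runif(1, 0, pi)
    col <- pmin(pmax(profile@meanColor + rnorm(3, 0, profile@colorSd), 0), 255)
    center <- c(112, 112) + rnorm(2, 0, 4)
    patch <- ellipsePatch(224, 224, center, axes, angle, profile@textureAmp)
    for (ch in 1:3)
      img[patch$lin + (ch - 1) * 224 * 224] <-
        pmin(pmax(col[ch] * patch$tex, 0), 255)
    new("SeedCrop", pixels = img, sourceBbox = c(1, 1, 224, 224),
        sourceBoard = "synthetic")
  })
}
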