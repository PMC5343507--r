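test_that("neutral variants give constant log2 ratios and zero slopes", {
  d <- smallDesign(seed = 3, nLibraries = 1, timepoints = 0:3)
  trueS <- matrix(0, 10, 21,
                  dimnames = list(positionInfo(d)$position, AA_CLASSES))
  cfg <- simulationConfig(timepoints = 0:3, depth = 1e4,
                          noiseModel = "none", trueS = trueS, seed = 1)
  cts <- simulateGrowthCounts(d, cfg)
  cm <- assay(cts, "counts")
  expect_true(all(abs(cm - cm[, 1]) < 1e-9))
  wt <- cm[rowData(cts)$isWT, ]
  mut <- cm[!rowData(cts)$isWT, , drop = FALSE][1, ]
  f <- rawFitness(mut, wt, 0:3)
  expect_equal(f$w, 0, tolerance = 1e-12)
})

test_that("a one-doubling advantage doubles the mutant/WT ratio per doubling", {
  d <- smallDesign(seed = 3, nLibraries = 1, timepoints = 0:3)
  trueS <- matrix(0, 10, 21,
                  dimnames = list(positionInfo(d)$position, AA_CLASSES))
  trueS[1, "F"] <- 1  # raw fitness +1 with |stopW| = 1
  cfg <- simulationConfig(timepoints = 0:3, depth = 1e4,
                          noiseModel = "none", trueS = trueS, seed = 1)
  cts <- simulateGrowthCounts(d, cfg)
  cm <- assay(cts, "counts")
  rd <- rowData(cts)
  mut <- cm[which(rd$outcome == "F" & !is.na(rd$position) &
                    rd$position == positionInfo(d)$position[1]), ]
  wt <- cm[which(rd$isWT), ]
  ratio <- (mut / wt) / (mut[1] / wt[1])
  expect_equal(unname(ratio), c(1, 2, 4, 8), tolerance = 1e-9)
})

test_that("identical configs and seeds reproduce counts and reads exactly", {
  d <- smallDesign(seed = 5)
  cfg <- simulationConfig(timepoints = c(0, 2, 4), depth = 2000, seed = 9)
  c1 <- simulateGrowthCounts(d, cfg)
  c2 <- simulateGrowthCounts(d, cfg)
  expect_identical(assay(c1, "counts"), assay(c2, "counts"))
  r1 <- emitReads(c1, d, corruption = 0.05, seed = 4)
  r2 <- emitReads(c2, d, corruption = 0.05, seed = 4)
  expect_identical(as.character(r1), as.character(r2))
  expect_identical(as.character(Biostrings::quality(r1)),
                   as.character(Biostrings::quality(r2)))
})

test_that("multinomial sampling conserves the drawn total per library", {
  d <- smallDesign(seed = 5)
  cfg <- simulationConfig(timepoints = c(0, 2, 4), depth = 12345, seed = 2)
  cts <- simulateGrowthCounts(d, cfg)
  rd <- rowData(cts)
  for (l in unique(rd$library)) {
    tot <- colSums(assay(cts, "counts")[rd$library == l, ])
    expect_true(all(tot == 12345))
  }
})

test_that("simulation rejects invalid configurations", {
  expect_error(simulationConfig(timepoints = numeric(0)), "two time points")
  expect_error(simulationConfig(timepoints = c(2, 1, 3)), "increasing")
  expect_error(simulationConfig(depth = -5), "positive")
  expect_error(simulationConfig(stopW = 0.5), "negative")
})

test_that("landscape trio profile correlations track the mixing weight", {
  # perfectly shared signal
  tr1 <- simulateLandscapeTrio(nPositions = 30, rho = 1, seed = 1)
  pa <- positionProfiles(tr1$landscapes$orthA)
  pb <- positionProfiles(tr1$landscapes$orthB)
  rs <- vapply(seq_len(nrow(pa)), function(i) cor(pa[i, ], pb[i, ]),
               numeric(1))
  expect_equal(rs, rep(1, 30), tolerance = 1e-9)

  # independence at rho = 0
  tr0 <- simulateLandscapeTrio(nPositions = 500, rho = 0, seed = 2)
  pa <- positionProfiles(tr0$landscapes$orthA)
  pb <- positionProfiles(tr0$landscapes$orthB)
  rs <- vapply(seq_len(500), function(i) cor(pa[i, ], pb[i, ]), numeric(1))
  se <- sd(rs) / sqrt(500)
  expect_lt(abs(mean(rs) - 0), 3 * se + 1e-12)

  # intermediate mixing recovers rho
  trm <- simulateLandscapeTrio(nPositions = 1000, rho = 0.36, seed = 3)
  pa <- positionProfiles(trm$landscapes$orthA)
  pb <- positionProfiles(trm$landscapes$orthB)
  rs <- vapply(seq_len(1000), function(i) cor(pa[i, ], pb[i, ]), numeric(1))
  se <- sd(rs) / sqrt(1000)
  expect_lt(abs(mean(rs) - 0.36), 3 * se)

  # monotone in rho
  means <- vapply(c(0, 0.25, 0.5, 0.75, 1), function(r) {
    tr <- simulateLandscapeTrio(nPositions = 200, rho = r, seed = 7)
    pa <- positionProfiles(tr$landscapes$orthA)
    pb <- positionProfiles(tr$landscapes$orthB)
    mean(vapply(seq_len(200), function(i) cor(pa[i, ], pb[i, ]), numeric(1)))
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("simulated MSAs converge to their column profiles", {
  aa <- AA_CLASSES[-21]
  prof <- matrix(0, 20, 3, dimnames = list(aa, NULL))
  prof["A", 1] <- 1                      # fully conserved alanine
  prof[, 2] <- 1 / 20                    # uniform
  prof["W", 3] <- 0.6                    # 60% WT tryptophan
  prof[setdiff(aa, "W"), 3] <- 0.4 / 19
  msa <- simulateMsa(prof, nSequences = 10000, seed = 4)
  m <- do.call(rbind, strsplit(as.character(msa), NULL))
  expect_equal(wtConservation(m[, 1], "A"), 1)
  expect_lte(informationContent(m[, 2]), 0.05)
  cons <- wtConservation(m[1:5000, 3], "W")
  se <- sqrt(0.6 * 0.4 / 5000)
  expect_lt(abs(cons - 0.6), 3 * se)
  expect_error(simulateMsa(prof * 2, 10), "sum to 1")
})

test_that("corrupted reads split across the three failure channels as planned", {
  d <- smallDesign(seed = 8, timepoints = c(0, 2, 4))
  cfg <- simulationConfig(timepoints = c(0, 2, 4), depth = 3400, seed = 1)
  cts <- simulateGrowthCounts(d, cfg)
  reads <- emitReads(cts, d, corruption = 0.1, seed = 12)
  n <- length(reads)
  expect_gte(n, 10000)
  truth <- metadata(reads)$truth
  p <- 0.1 / 3
  sdN <- sqrt(n * p * (1 - p))
  for (ch in c("quality", "barcode", "reference"))
    expect_lt(abs(sum(truth$channel == ch) - n * p), 3 * sdN)
  # every planted corruption is rejected for its own reason
  dec <- filterReads(reads, d)
  expect_identical(sum(dec$status == "quality"),
                   sum(truth$channel == "quality"))
  expect_identical(sum(dec$status == "barcode"),
                   sum(truth$channel == "barcode"))
  expect_identical(sum(dec$status == "reference"),
                   sum(truth$channel == "reference"))
})

test_that("a variant codon that creates the MmeI site is flagged by the filter", {
  d <- smallDesign(seed = 3, nLibraries = 1, timepoints = c(0, 2, 4))
  p <- positionInfo(d)
  # plant TCCAAC: find a position/codon whose insert carries a site
  planted <- NULL
  for (i in seq_len(nrow(p))) {
    for (cd in setdiff(names(Biostrings::GENETIC_CODE), p$wtCodon[i])) {
      ins <- empiricscan:::variantInsert(d, p$position[i], cd)
      if (containsMmeISite(ins)) { planted <- list(pos = p$position[i],
                                                   codon = cd); break }
    }
    if (!is.null(planted)) break
  }
  skip_if(is.null(planted), "no MmeI-creating codon in this design")
  bc <- timeBarcodes(d)[1]
  read <- paste0(bc, empiricscan:::variantInsert(d, planted$pos,
                                                 planted$codon))
  dec <- filterRead(read, rep(30L, nchar(read)), d)
  expect_identical(dec$status, "mmei")
})
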