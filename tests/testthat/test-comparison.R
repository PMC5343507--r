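test_that("profile correlation matches the closed-form Pearson computation", {
  aa <- AA_CLASSES[-21]
  p <- setNames(rnorm(20), aa)
  expect_equal(profileCorrelation(p, p, policy = "include_all_20"), 1)
  expect_equal(profileCorrelation(p, -p, policy = "include_all_20"), -1)

  set.seed(31)
  for (i in 1:100) {
    x <- setNames(rnorm(19), aa[1:19])
    y <- setNames(rnorm(19), aa[1:19])
    r <- profileCorrelation(x, y, policy = "include_all_20")
    # from-scratch covariance over sigma-sigma
    mx <- mean(x); my <- mean(y)
    oracle <- sum((x - mx) * (y - my)) /
      sqrt(sum((x - mx)^2) * sum((y - my)^2))
    expect_equal(r, oracle, tolerance = 1e-12)
  }
})

test_that("the WT-handling policy drops the wild-type residues of the pair", {
  aa <- AA_CLASSES[-21]
  p <- setNames(seq_len(20), aa)
  q <- setNames(20 - seq_len(20), aa)
  # make the profiles differ only at the WT entries to see the policy act
  q2 <- -p; q2[c("A", "L")] <- 1000
  rAll <- profileCorrelation(p, q2, wtP = "A", wtQ = "L",
                             policy = "include_all_20")
  rDrop <- profileCorrelation(p, q2, wtP = "A", wtQ = "L",
                              policy = "exclude_both_wt")
  expect_equal(rDrop, -1)
  expect_gt(rAll, -1)
  # degenerate inputs
  expect_true(is.na(profileCorrelation(p[1:2], q[1:2],
                                       policy = "include_all_20")))
  expect_true(is.na(profileCorrelation(setNames(rep(1, 20), aa), q,
                                       policy = "include_all_20")))
})

test_that("position sets follow their definitions and the null is a superset", {
  sA <- matrix(rnorm(60), 3, 20,
               dimnames = list(1:3, AA_CLASSES[-21]))
  sB <- sA
  A <- toyLandscape(sA, wtAA = c("A", "L", "G"))
  B <- toyLandscape(sB, wtAA = c("L", "A", "G"))
  idw <- buildPositionSet(A, B, "identical_wt")
  expect_setequal(paste(idw$posA, idw$posB), c("1 2", "2 1", "3 3"))

  map <- alignmentMap(1:3, c("A", "L", "G"), 1:3, c("L", "A", "G"))
  al <- buildPositionSet(A, B, "aligned", map = map)
  expect_identical(nrow(al), 3L)
  ani <- buildPositionSet(A, B, "aligned_nonidentical", map = map)
  expect_identical(sort(ani$posA), c(1L, 2L))  # identical-WT pair dropped
  expect_true(all(paste(ani$posA, ani$posB) %in% paste(al$posA, al$posB)))

  null <- buildPositionSet(A, B, "null_all_pairs")
  expect_identical(nrow(null), 9L)
  for (lbl in c("identical_wt", "aligned", "aligned_nonidentical")) {
    p <- buildPositionSet(A, B, lbl, map = map)
    expect_true(all(paste(p$posA, p$posB) %in% paste(null$posA, null$posB)))
  }
  expect_error(buildPositionSet(A, B, "nonsense"))
  expect_error(buildPositionSet(A, B, "aligned"), "alignment map")
})

test_that("fourfold pairing groups positions by quadrant and offset", {
  tr <- simulateLandscapeTrio(nPositions = 40, rho = 1, seed = 5)
  A <- tr$landscapes$orthA
  B <- tr$landscapes$orthB
  ff <- buildPositionSet(A, B, "fourfold")
  infoA <- positionInfo(A)
  qa <- fourfoldIndex(infoA$library, infoA$withinPos)
  for (k in seq_len(min(nrow(ff), 50))) {
    ia <- match(as.character(ff$posA[k]), rownames(infoA))
    ib <- match(as.character(ff$posB[k]), rownames(infoA))
    expect_identical(qa$quadrant[ia], qa$quadrant[ib])
    expect_identical(qa$offset[ia], qa$offset[ib])
  }
  # rho = 1: aligned-offset pairs correlate perfectly, mode at 1
  dist <- correlationDistribution(A, B, ff, "fourfold",
                                  policy = "include_all_20")
  diag <- ff$posA == ff$posB
  rDiag <- correlationDistribution(A, B, ff[diag, ], "fourfold_same",
                                   policy = "include_all_20")
  expect_equal(unname(rDiag$r), rep(1, sum(diag)), tolerance = 1e-9)
  expect_equal(dist$mode, 1, tolerance = 0.05)
})

test_that("the KS wrapper agrees with a brute-force ECDF maximum difference", {
  x <- rnorm(40); y <- rnorm(60, 0.5)
  ks <- compareDistributionsKS(x, y)
  grid <- sort(c(x, y))
  oracleD <- max(abs(vapply(grid, function(g)
    mean(x <= g) - mean(y <= g), numeric(1))))
  expect_equal(ks$D, oracleD, tolerance = 1e-12)
  expect_equal(compareDistributionsKS(x, x)$D, 0)
  expect_warning(compareDistributionsKS(rnorm(3), rnorm(10)), "fewer than 5")
})

test_that("KS p-values are valid (super-uniform) under the null", {
  set.seed(77)
  ps <- replicate(1000, {
    compareDistributionsKS(rnorm(40), rnorm(40))$p
  })
  for (alpha in c(0.01, 0.05, 0.1)) {
    se <- sqrt(alpha * (1 - alpha) / 1000)
    expect_lte(mean(ps <= alpha), alpha + 3 * se)
  }
  # and not degenerate: small p-values do occur at some rate
  expect_gt(mean(ps <= 0.1), 0.02)
})

test_that("the beneficial-fraction permutation test behaves at the extremes", {
  s <- matrix(c(0.1, -0.2, 0.3, -1), 1, 4,
              dimnames = list("1", c("A", "C", "D", "E")))
  s <- rbind(s, "2" = c(-0.5, -0.6, -0.7, -0.8))
  bf <- beneficialFractionTest(s, subset = "1", nPerm = 200, seed = 1)
  expect_equal(bf$observed, 0.5)

  # maximal separation: subset all beneficial, complement all deleterious
  sep <- rbind(matrix(0.5, 5, 19), matrix(-0.9, 45, 19))
  rownames(sep) <- 1:50
  colnames(sep) <- AA_CLASSES[1:19]
  bf2 <- beneficialFractionTest(sep, subset = as.character(1:5),
                                nPerm = 2000, seed = 2)
  expect_lte(bf2$p, 2 * (1 + 0) / 2001 + 1e-12)

  expect_error(beneficialFractionTest(sep, subset = as.character(1:50)),
               "strict subset")
  expect_error(beneficialFractionTest(sep, subset = character(0)), "empty")
})

test_that("transformative mutations are collected from non-identical aligned pairs", {
  aa <- AA_CLASSES[-21]
  sA <- matrix(rnorm(40), 2, 20, dimnames = list(1:2, aa))
  sB <- matrix(rnorm(40), 2, 20, dimnames = list(1:2, aa))
  sA["1", "V"] <- 0.1
  A <- toyLandscape(sA, wtAA = c("A", "L"), orthologue = "A")
  B <- toyLandscape(sB, wtAA = c("V", "L"), orthologue = "B")
  map <- alignmentMap(1:2, c("A", "L"), 1:2, c("V", "L"))
  ta <- suppressWarnings(transformativeAnalysis(A, B, map, nPerm = 200,
                                                seed = 1))
  fromA <- ta$set[ta$set$orthologue == "A", ]
  expect_identical(nrow(fromA), 1L)
  expect_identical(fromA$target, "V")
  expect_equal(fromA$s, 0.1)
  # identical WT everywhere: empty set
  mapSame <- alignmentMap(1:2, c("A", "L"), 1:2, c("A", "L"))
  ta2 <- suppressWarnings(transformativeAnalysis(A, B, mapSame, nPerm = 50,
                                                 seed = 1))
  expect_identical(nrow(ta2$set), 0L)
})

test_that("a planted detrimental fraction among transformative cells is recovered", {
  aa <- AA_CLASSES[-21]
  n <- 100
  set.seed(13)
  sA <- matrix(runif(n * 20, -0.3, 0.3), n, 20, dimnames = list(1:n, aa))
  wtA <- rep("A", n)
  wtB <- rep("V", n)
  # plant: mutation to B's WT residue is detrimental at exactly 31 positions
  sA[, "V"] <- 0.1
  sA[1:31, "V"] <- -0.9
  sB <- matrix(runif(n * 20, -0.3, 0.3), n, 20, dimnames = list(1:n, aa))
  sB[, "A"] <- 0.1  # reverse direction all tolerated
  A <- toyLandscape(sA, wtAA = wtA, orthologue = "A")
  B <- toyLandscape(sB, wtAA = wtB, orthologue = "B")
  map <- alignmentMap(1:n, wtA, 1:n, wtB)
  ta <- transformativeAnalysis(A, B, map, nPerm = 100, seed = 2)
  expect_identical(nrow(ta$set), 200L)
  expect_equal(ta$fracDetrimental, 31 / 200)
})

test_that("replicate self-correlation exceeds cross-orthologue correlation", {
  tr <- simulateLandscapeTrio(nPositions = 80, rho = 0.5, seed = 19)
  A <- tr$landscapes$orthA
  B <- tr$landscapes$orthB
  pa <- positionProfiles(A)
  # noisy re-estimate of A itself: high-fidelity replicate
  set.seed(20)
  repl <- sqrt(0.9) * pa + sqrt(0.1) * matrix(rnorm(length(pa)), nrow(pa))
  Ar <- toyLandscape(repl, wtAA = wtResidues(A),
                     library = positionInfo(A)$library,
                     withinPos = positionInfo(A)$withinPos)
  pairs <- data.frame(posA = rownames(pa), posB = rownames(pa))
  rRep <- correlationDistribution(A, Ar, pairs, "replicate",
                                  policy = "include_all_20")
  rCross <- correlationDistribution(A, B, pairs, "cross",
                                    policy = "include_all_20")
  expect_gt(mean(rRep$r), mean(rCross$r))
})
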