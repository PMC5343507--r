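#' Per-position amino-acid substitution profiles
#'
#' Extracts the positions-by-outcomes matrix of selection coefficients used
#' for cross-orthologue comparisons. Stop-codon outcomes are excluded by
#' default (they report expression loss, not substitution response).
#'
#' @param landscape a [FitnessLandscape].
#' @param includeStop keep the stop class (default FALSE).
#' @return numeric matrix, rows = positions, columns = amino-acid outcomes.
#' @export
positionProfiles <- function(landscape, includeStop = FALSE) {
  m <- selCoef(landscape)
  if (!includeStop && "*" %in% colnames(m))
    m <- m[, colnames(m) != "*", drop = FALSE]
  m
}

#' Pearson correlation between two position profiles
#'
#' The similarity in response to the set of amino-acid substitutions at a
#' pair of positions. Under the default policy, amino acids that are the
#' wild type at either position are dropped (leaving the 18-19 shared
#' substitutions); `include_all_20` keeps the full outcome set. Missing
#' (excluded) cells are dropped pairwise. At least 3 shared outcomes are
#' required; zero variance in either profile yields `NA`.
#'
#' @param p,q numeric profiles named by amino acid.
#' @param wtP,wtQ wild-type residues at the two positions (needed for the
#'   default policy).
#' @param policy `"exclude_both_wt"` or `"include_all_20"`.
#' @return Pearson R, or `NA` if undefined.
#' @export
profileCorrelation <- function(p, q, wtP = NULL, wtQ = NULL,
                               policy = c("exclude_both_wt",
                                          "include_all_20")) {
  policy <- match.arg(policy)
  shared <- intersect(names(p), names(q))
  if (policy == "exclude_both_wt")
    shared <- setdiff(shared, c(wtP, wtQ))
  x <- p[shared]; y <- q[shared]
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) return(NA_real_)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}

#' Build a position-pair set for landscape comparison
#'
#' The four specific sets plus the null: `identical_wt` — all cross-orthologue
#' position pairs with equal wild-type residue, irrespective of alignment;
#' `aligned` — pairs from the structural map; `aligned_nonidentical` —
#' aligned pairs whose wild-type residues differ; `fourfold` — pairs sharing
#' a (quadrant, offset) cell of the barrel's four-fold symmetry;
#' `null_all_pairs` — the full Cartesian product of positions.
#'
#' @param landscapeA,landscapeB [FitnessLandscape]s.
#' @param setLabel one of the five labels above.
#' @param map an [alignmentMap()] from A to B (required for the aligned
#'   sets).
#' @return data.frame with columns `posA`, `posB`.
#' @export
buildPositionSet <- function(landscapeA, landscapeB,
                             setLabel = c("identical_wt", "aligned",
                                          "aligned_nonidentical", "fourfold",
                                          "null_all_pairs"),
                             map = NULL) {
  setLabel <- match.arg(setLabel)
  wtA <- wtResidues(landscapeA)
  wtB <- wtResidues(landscapeB)
  posA <- as.integer(names(wtA))
  posB <- as.integer(names(wtB))
  if (setLabel %in% c("aligned", "aligned_nonidentical")) {
    if (is.null(map)) stop("an alignment map is required for '", setLabel, "'")
    pairs <- data.frame(posA = map$posA, posB = map$posB)
    if (setLabel == "aligned_nonidentical")
      pairs <- pairs[wtA[as.character(pairs$posA)] !=
                       wtB[as.character(pairs$posB)], ]
    return(pairs)
  }
  if (setLabel == "fourfold") {
    fa <- cbind(positionInfo(landscapeA),
                fourfoldIndex(positionInfo(landscapeA)$library,
                              positionInfo(landscapeA)$withinPos))
    fb <- cbind(positionInfo(landscapeB),
                fourfoldIndex(positionInfo(landscapeB)$library,
                              positionInfo(landscapeB)$withinPos))
    g <- merge(data.frame(posA = posA, quadrant = fa$quadrant,
                          offset = fa$offset),
               data.frame(posB = posB, quadrant = fb$quadrant,
                          offset = fb$offset),
               by = c("quadrant", "offset"))
    return(g[c("posA", "posB")])
  }
  grid <- expand.grid(posA = posA, posB = posB, KEEP.OUT.ATTRS = FALSE)
  if (setLabel == "identical_wt")
    grid <- grid[wtA[as.character(grid$posA)] ==
                   wtB[as.character(grid$posB)], ]
  rownames(grid) <- NULL
  grid
}

#' Distribution of profile correlations over a position-pair set
#'
#' Computes the Pearson R of the substitution profiles for every pair in the
#' set; pairs with undefined R (fewer than 3 shared outcomes, or zero
#' variance) are skipped and counted.
#'
#' @param landscapeA,landscapeB [FitnessLandscape]s.
#' @param pairs data.frame from [buildPositionSet()].
#' @param setLabel label recorded on the result.
#' @param policy,includeStop see [profileCorrelation()] and
#'   [positionProfiles()].
#' @return list of class `CorrelationDistribution`: `r` (vector of Pearson
#'   R), `setLabel`, `nPairs`, `nSkipped`, `mode` (kernel density mode),
#'   `policy`.
#' @export
correlationDistribution <- function(landscapeA, landscapeB, pairs,
                                    setLabel = "custom",
                                    policy = c("exclude_both_wt",
                                               "include_all_20"),
                                    includeStop = FALSE) {
  policy <- match.arg(policy)
  pa <- positionProfiles(landscapeA, includeStop)
  pb <- positionProfiles(landscapeB, includeStop)
  wtA <- wtResidues(landscapeA)
  wtB <- wtResidues(landscapeB)
  ia <- match(as.character(pairs$posA), rownames(pa))
  ib <- match(as.character(pairs$posB), rownames(pb))
  if (anyNA(ia) || anyNA(ib)) stop("pair refers to unknown positions")
  if (policy == "include_all_20" && !anyNA(pa) && !anyNA(pb)) {
    # full-matrix fast path: all pairwise correlations in one call
    cc <- stats::cor(t(pa), t(pb))
    r <- cc[cbind(ia, ib)]
  } else {
    r <- vapply(seq_len(nrow(pairs)), function(k)
      profileCorrelation(pa[ia[k], ], pb[ib[k], ],
                         wtA[ia[k]], wtB[ib[k]], policy), numeric(1))
  }
  skipped <- is.na(r)
  r <- r[!skipped]
  md <- if (length(r) >= 10 && stats::sd(r) > 1e-9) {
    d <- stats::density(r)
    d$x[which.max(d$y)]
  } else if (length(r) > 0 && stats::sd(r) <= 1e-9) r[1] else NA_real_
  structure(list(r = r, setLabel = setLabel, nPairs = nrow(pairs),
                 nSkipped = sum(skipped), mode = md, policy = policy),
            class = "CorrelationDistribution")
}

#' @export
print.CorrelationDistribution <- function(x, ...) {
  cat("CorrelationDistribution [", x$setLabel, "]: ", length(x$r),
      " R values (", x$nSkipped, " skipped), mode ",
      round(x$mode, 3), ", policy ", x$policy, "\n", sep = "")
  invisible(x)
}

#' Two-sample Kolmogorov-Smirnov comparison of correlation distributions
#'
#' @param dist1,dist2 `CorrelationDistribution` objects (or numeric
#'   vectors).
#' @return list: `D` (KS statistic), `p`, `n1`, `n2`.
#' @export
compareDistributionsKS <- function(dist1, dist2) {
  x <- if (inherits(dist1, "CorrelationDistribution")) dist1$r else dist1
  y <- if (inherits(dist2, "CorrelationDistribution")) dist2$r else dist2
  if (length(x) == 0 || length(y) == 0) stop("empty sample")
  if (length(x) < 5 || length(y) < 5)
    warning("fewer than 5 values in a sample; KS test is unreliable")
  kt <- suppressWarnings(stats::ks.test(x, y))
  list(D = unname(kt$statistic), p = kt$p.value,
       n1 = length(x), n2 = length(y))
}

#' Permutation test on the beneficial fraction of a position subset
#'
#' The observed statistic is the fraction of mutations with `s > 0` among the
#' subset positions. The null distribution reassigns whole per-position
#' substitution profiles to uniformly random positions `nPerm` times and
#' recomputes the subset fraction; the p-value uses the add-one correction
#' `(b + 1) / (nPerm + 1)` so it can never be exactly zero.
#'
#' @param landscape a [FitnessLandscape] or a positions-by-outcomes matrix of
#'   selection coefficients.
#' @param subset position names/indices forming the stratum of interest;
#'   must be a strict, non-empty subset of all positions.
#' @param nPerm number of permutations (10,000 by default).
#' @param alternative `"two.sided"` (default), `"greater"`, or `"less"`.
#' @param includeStop include the stop class in the fractions.
#' @param seed RNG seed.
#' @return list: `observed` (fraction), `p`, `null` (permuted fractions),
#'   `nPerm`.
#' @export
beneficialFractionTest <- function(landscape, subset, nPerm = 10000L,
                                   alternative = c("two.sided", "greater",
                                                   "less"),
                                   includeStop = FALSE, seed = 1L) {
  alternative <- match.arg(alternative)
  m <- if (is(landscape, "FitnessLandscape"))
    positionProfiles(landscape, includeStop) else as.matrix(landscape)
  pos <- rownames(m) %||% as.character(seq_len(nrow(m)))
  rownames(m) <- pos
  subset <- as.character(subset)
  if (!all(subset %in% pos)) stop("subset refers to unknown positions")
  k <- length(subset)
  if (k == 0) stop("subset is empty")
  if (k >= nrow(m)) stop("subset must be a strict subset of all positions")

  ben <- rowSums(m > 0, na.rm = TRUE)
  tot <- rowSums(!is.na(m))
  iSub <- match(subset, pos)
  observed <- sum(ben[iSub]) / sum(tot[iSub])

  set.seed(seed)
  n <- nrow(m)
  null <- vapply(seq_len(nPerm), function(b) {
    i <- sample.int(n, k)
    sum(ben[i]) / sum(tot[i])
  }, numeric(1))

  pGreater <- (1 + sum(null >= observed)) / (nPerm + 1)
  pLess <- (1 + sum(null <= observed)) / (nPerm + 1)
  p <- switch(alternative,
              greater = pGreater,
              less = pLess,
              two.sided = min(1, 2 * min(pGreater, pLess)))
  list(observed = observed, p = p, null = null, nPerm = nPerm,
       alternative = alternative)
}

#' Transformative-mutation analysis
#'
#' For each structurally aligned position pair with differing wild-type
#' residues, collects the selection coefficient of the mutation in one
#' orthologue to the other orthologue's wild-type residue (in both
#' directions): the substitutions that 'transform' one protein into the
#' other. Reports the detrimental fraction (`s < -0.5`) and compares the
#' transformative distribution against all mutations by a KS test and a
#' resampling test on the detrimental fraction.
#'
#' @param landscapeA,landscapeB [FitnessLandscape]s.
#' @param map structural [alignmentMap()] from A to B with wild-type
#'   residues on both sides.
#' @param nPerm resamples for the detrimental-fraction comparison.
#' @param seed RNG seed for the resampling comparison.
#' @return list: `set` (data.frame orthologue/position/target/s),
#'   `fracDetrimental`, `ks` (vs all mutations), `permutation`
#'   (resampling p for the detrimental fraction), `all` (all mutation s
#'   values used as the comparison distribution).
#' @export
transformativeAnalysis <- function(landscapeA, landscapeB, map,
                                   nPerm = 10000L, seed = 1L) {
  sA <- positionProfiles(landscapeA)
  sB <- positionProfiles(landscapeB)
  oA <- metadata(landscapeA)$orthologue %||% "A"
  oB <- metadata(landscapeB)$orthologue %||% "B"
  rows <- list()
  for (k in seq_len(nrow(map))) {
    aA <- map$aaA[k]; aB <- map$aaB[k]
    if (aA == aB) next
    pA <- as.character(map$posA[k]); pB <- as.character(map$posB[k])
    if (pA %in% rownames(sA) && aB %in% colnames(sA))
      rows[[length(rows) + 1]] <- data.frame(
        orthologue = oA, position = map$posA[k], target = aB,
        s = sA[pA, aB])
    if (pB %in% rownames(sB) && aA %in% colnames(sB))
      rows[[length(rows) + 1]] <- data.frame(
        orthologue = oB, position = map$posB[k], target = aA,
        s = sB[pB, aA])
  }
  set <- if (length(rows)) do.call(rbind, rows) else
    data.frame(orthologue = character(), position = integer(),
               target = character(), s = numeric())
  set <- set[!is.na(set$s), ]
  allS <- c(as.vector(sA), as.vector(sB))
  allS <- allS[!is.na(allS)]
  if (nrow(set) == 0)
    return(list(set = set, fracDetrimental = NA_real_, ks = NULL,
                permutation = NULL, all = allS))
  fracDet <- mean(set$s < -0.5)
  ks <- compareDistributionsKS(set$s, allS)
  set.seed(seed)
  nullFrac <- vapply(seq_len(nPerm), function(b)
    mean(sample(allS, nrow(set)) < -0.5), numeric(1))
  pG <- (1 + sum(nullFrac >= fracDet)) / (nPerm + 1)
  pL <- (1 + sum(nullFrac <= fracDet)) / (nPerm + 1)
  list(set = set, fracDetrimental = fracDet, ks = ks,
       permutation = list(p = min(1, 2 * min(pG, pL)), null = nullFrac),
       all = allS)
}
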