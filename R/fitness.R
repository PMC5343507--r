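#' Raw fitness: slope of log2 relative abundance versus time
#'
#' Raw fitness `w` is the ordinary-least-squares slope of
#' `log2(N_mut(t) / N_wt(t))` against time in WT doublings. Time points where
#' either count is zero are dropped (unless a pseudocount is supplied); fewer
#' than two usable time points flags the variant as low coverage with no
#' defined slope.
#'
#' @param mut,wt counts of the mutant and of the wild-type reference at each
#'   time point.
#' @param times time points in WT doublings.
#' @param pseudocount added to every count before the log ratio (default 0,
#'   i.e. zero-count time points are dropped instead).
#' @return list: `w` (slope, NA if undefined), `r2` (regression R^2),
#'   `n` (usable time points), `dropped` (indices of dropped time points),
#'   `lowCoverage` (logical).
#' @export
rawFitness <- function(mut, wt, times, pseudocount = 0) {
  stopifnot(length(mut) == length(wt), length(mut) == length(times))
  m <- mut + pseudocount
  v <- wt + pseudocount
  keep <- m > 0 & v > 0
  if (sum(keep) < 2)
    return(list(w = NA_real_, r2 = NA_real_, n = sum(keep),
                dropped = which(!keep), lowCoverage = TRUE))
  x <- times[keep]
  y <- log2(m[keep] / v[keep])
  mx <- mean(x); my <- mean(y)
  sxx <- sum((x - mx)^2)
  w <- sum((x - mx) * (y - my)) / sxx
  syy <- sum((y - my)^2)
  r2 <- if (syy > 0) (sum((x - mx) * (y - my))^2) / (sxx * syy) else NA_real_
  list(w = w, r2 = r2, n = sum(keep), dropped = which(!keep),
       lowCoverage = FALSE)
}

#' Stop-codon normalization of raw fitness
#'
#' Converts raw fitness to selection coefficients by `s = -w / wStop`, the
#' linear map with `s(0) = 0` under which the mean selection coefficient of
#' the stop-codon outcomes in a library equals -1. `wStop` is the mean raw
#' fitness over all stop-codon mutations within one 10-residue library (one
#' selection experiment).
#'
#' @param w numeric raw fitness values.
#' @param wStop mean stop-codon raw fitness of the library; must be negative
#'   (a non-negative value signals a failed selection and aborts).
#' @return selection coefficients.
#' @export
stopNormalize <- function(w, wStop) {
  if (is.na(wStop) || wStop >= 0)
    stop("library is unnormalizable: mean stop-codon raw fitness is not ",
         "negative (failed selection)")
  -w / wStop
}

#' Estimate a fitness landscape from a count time series
#'
#' Pools codon-level counts into amino-acid outcome classes, computes raw
#' fitness per `(position, outcome)` cell against the library's wild-type
#' reference, normalizes by the library's mean stop-codon raw fitness, and
#' applies the exclusion rules (cells whose variant codons all create MmeI
#' sites; cells with poor initial coverage).
#'
#' @param counts a [CountTimeSeries] (codon- or outcome-level rows).
#' @param design the matching [ScanLibraryDesign]; needed for MmeI cell
#'   exclusion and wild-type residues.
#' @param minCountT0 cells whose pooled count at the first time point is
#'   below this are excluded as `low_coverage` (default 10 reads).
#' @param pseudocount see [rawFitness()].
#' @param poolSynonymousWT if TRUE, counts in the wild-type-synonymous
#'   outcome class are added to the wild-type denominator of their position
#'   (default FALSE: they form their own outcome class only).
#' @param mmeiExclusion compute MmeI-cell exclusions from the design
#'   (default TRUE).
#' @return a [FitnessLandscape].
#' @export
estimateLandscape <- function(counts, design, minCountT0 = 10,
                              pseudocount = 0, poolSynonymousWT = FALSE,
                              mmeiExclusion = TRUE) {
  pl <- poolByOutcome(counts)
  times <- colData(counts)$time
  p <- design@positions
  nPos <- nrow(p)
  cls <- AA_CLASSES

  w <- matrix(NA_real_, nPos, length(cls),
              dimnames = list(p$position, cls))
  excl <- matrix("", nPos, length(cls), dimnames = dimnames(w))
  r2 <- w

  for (i in seq_len(nPos)) {
    lib <- p$library[i]
    wtRow <- pl$wt[paste0("L", lib), ]
    for (j in seq_along(cls)) {
      key <- paste0("L", lib, ":", p$position[i], ":", cls[j])
      mutRow <- if (key %in% rownames(pl$counts)) pl$counts[key, ]
                else rep(0, length(times))
      denom <- wtRow
      if (poolSynonymousWT && cls[j] != p$wtAA[i]) {
        synKey <- paste0("L", lib, ":", p$position[i], ":", p$wtAA[i])
        if (synKey %in% rownames(pl$counts))
          denom <- denom + pl$counts[synKey, ]
      }
      if (mutRow[1] < minCountT0) {
        excl[i, j] <- "low_coverage"
        next
      }
      f <- rawFitness(mutRow, denom, times, pseudocount)
      if (f$lowCoverage) excl[i, j] <- "low_coverage"
      w[i, j] <- f$w
      r2[i, j] <- f$r2
    }
  }

  if (mmeiExclusion) {
    mm <- mmeiExcludedCells(design)
    excl[mm] <- "mmei"  # mmei takes precedence as the first reason
  }

  libOf <- p$library
  stopMean <- vapply(sort(unique(libOf)), function(l) {
    ws <- w[libOf == l, "*"]
    ws <- ws[excl[libOf == l, "*"] == ""]
    if (length(ws) == 0) NA_real_ else mean(ws, na.rm = TRUE)
  }, numeric(1))
  names(stopMean) <- sort(unique(libOf))

  s <- w
  unnorm <- character(0)
  for (l in names(stopMean)) {
    sel <- libOf == as.integer(l)
    if (is.na(stopMean[l]) || stopMean[l] >= 0) {
      s[sel, ] <- NA_real_
      unnorm <- c(unnorm, l)
    } else {
      s[sel, ] <- -w[sel, ] / stopMean[l]
    }
  }

  fl <- newFitnessLandscape(
    s = s, w = w, library = p$library, withinPos = p$withinPos,
    wtAA = p$wtAA, positions = p$position, orthologue = design@orthologue,
    excluded = excl, r2 = r2)
  metadata(fl)$stopMean <- stopMean
  metadata(fl)$unnormalizableLibraries <- unnorm
  metadata(fl)$params <- list(minCountT0 = minCountT0,
                              pseudocount = pseudocount,
                              poolSynonymousWT = poolSynonymousWT)
  if ("trueS" %in% names(rowData(counts))) {
    rd <- as.data.frame(rowData(counts))
    rd <- rd[!rd$isWT, ]
    tm <- matrix(NA_real_, nPos, length(cls), dimnames = dimnames(w))
    tm[cbind(match(rd$position, rownames(tm)),
             match(rd$outcome, colnames(tm)))] <- rd$trueS
    assays(fl)$trueS <- tm
  }
  fl
}

# build a FitnessLandscape from parts
newFitnessLandscape <- function(s, w = s, library, withinPos, wtAA,
                                positions = rownames(s) %||%
                                  seq_len(nrow(s)),
                                orthologue = "orth", excluded = NULL,
                                r2 = NULL) {
  rn <- as.character(positions)
  dimnames(s) <- list(rn, colnames(s))
  aList <- list(s = s, w = `dimnames<-`(w, dimnames(s)))
  if (!is.null(excluded))
    aList$excluded <- `dimnames<-`(excluded, dimnames(s))
  else
    aList$excluded <- matrix("", nrow(s), ncol(s), dimnames = dimnames(s))
  if (!is.null(r2)) aList$r2 <- `dimnames<-`(r2, dimnames(s))
  se <- SummarizedExperiment(
    assays = aList,
    rowData = DataFrame(library = library, withinPos = withinPos,
                        wtAA = wtAA, row.names = rn),
    colData = DataFrame(outcome = colnames(s), row.names = colnames(s)))
  metadata(se)$orthologue <- orthologue
  new("FitnessLandscape", se)
}

# (position, outcome) cells all of whose non-WT codons create an MmeI site
mmeiExcludedCells <- function(design) {
  p <- design@positions
  cells <- matrix(FALSE, nrow(p), length(AA_CLASSES),
                  dimnames = list(p$position, AA_CLASSES))
  for (i in seq_len(nrow(p))) {
    for (j in seq_along(AA_CLASSES)) {
      cods <- setdiff(codonsFor(AA_CLASSES[j]), p$wtCodon[i])
      if (length(cods) == 0) next
      site <- vapply(cods, function(cd)
        containsMmeISite(variantInsert(design, p$position[i], cd)),
        logical(1))
      cells[i, j] <- all(site)
    }
  }
  which(cells)
}

#' Apply explicit exclusions to a landscape
#'
#' Marks cells excluded with a reason; already-excluded cells keep their
#' first reason, with `mmei` taking precedence over `low_coverage`. Excluded
#' cells keep no selection coefficient in [selCoef()] output; surviving
#' values are never altered.
#'
#' @param landscape a [FitnessLandscape].
#' @param mmei,lowCoverage data.frames with columns `position` and `outcome`
#'   naming cells to exclude (for `lowCoverage`, a `mutAA` column is accepted
#'   as an alias of `outcome`).
#' @return the landscape with its `excluded` assay updated.
#' @export
applyExclusions <- function(landscape, mmei = NULL, lowCoverage = NULL) {
  ex <- assay(landscape, "excluded")
  mark <- function(ex, cells, reason) {
    if (is.null(cells) || nrow(cells) == 0) return(ex)
    out <- cells$outcome %||% cells$mutAA
    idx <- cbind(match(as.character(cells$position), rownames(ex)),
                 match(out, colnames(ex)))
    if (anyNA(idx)) stop("exclusion refers to unknown cells")
    if (reason == "mmei") {
      ex[idx] <- "mmei"
    } else {
      cur <- ex[idx]
      ex[idx] <- ifelse(cur == "mmei", cur, reason)
    }
    ex
  }
  ex <- mark(ex, lowCoverage, "low_coverage")
  ex <- mark(ex, mmei, "mmei")
  assays(landscape)$excluded <- ex
  landscape
}

#' Count analysed (non-excluded) cells
#'
#' @param landscape a [FitnessLandscape], or a list of them.
#' @return integer count of cells with no exclusion reason.
#' @export
analysedCells <- function(landscape) {
  if (is.list(landscape))
    return(sum(vapply(landscape, analysedCells, integer(1))))
  sum(exclusionReasons(landscape) == "")
}

#' Summary statistics of a fitness landscape
#'
#' Reports the headline fractions of the distribution of fitness effects:
#' deleterious (`s < -0.75`), detrimental (`s < -0.5`), beneficial (`s > 0`),
#' together with a histogram and kernel-density modes.
#'
#' @param x a [FitnessLandscape] or a numeric vector of selection
#'   coefficients.
#' @param breaks passed to [hist()].
#' @return list: `n`, `fracDeleterious`, `fracDetrimental`,
#'   `fracBeneficial`, `histogram`, `modes`.
#' @export
landscapeStats <- function(x, breaks = seq(-2, 2, by = 0.1)) {
  s <- if (is(x, "FitnessLandscape")) as.vector(selCoef(x)) else as.numeric(x)
  s <- s[!is.na(s)]
  if (length(s) == 0) stop("no selection coefficients to summarise")
  rng <- range(c(s, breaks))
  br <- unique(sort(c(breaks, rng)))
  h <- graphics::hist(s, breaks = br, plot = FALSE)
  modes <- numeric(0)
  if (length(s) >= 10 && stats::sd(s) > 0) {
    d <- stats::density(s)
    pk <- which(diff(sign(diff(d$y))) == -2) + 1L
    modes <- d$x[pk]
  } else if (stats::sd(s) == 0) {
    modes <- s[1]
  }
  list(n = length(s),
       fracDeleterious = mean(s < -0.75),
       fracDetrimental = mean(s < -0.5),
       fracBeneficial = mean(s > 0),
       histogram = h,
       modes = modes)
}
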