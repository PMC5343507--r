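#' Configuration of a simulated bulk growth competition
#'
#' Holds the conditions of a simulated EMPIRIC selection experiment: the
#' sampling times (in WT doublings), the expected sequencing depth per time
#' point and library, the count noise model, and the true selection
#' coefficients. The per-doubling raw fitness of a variant is
#' `w = s * |stopW|`, with `stopW` the true mean raw fitness of stop-codon
#' variants; with the default calibration `stopW = -1` the per-doubling
#' log2-ratio slope of a variant equals its true selection coefficient.
#'
#' @slot timepoints sampling times in WT doublings, strictly increasing.
#' @slot depth expected total reads per library per time point.
#' @slot noiseModel `"multinomial"` (fixed total per time point, the
#'   default), `"poisson"`, or `"none"` (expected counts, noise-free).
#' @slot stopW true mean raw fitness of stop-codon variants; must be negative.
#' @slot trueS optional positions-by-outcome matrix of true selection
#'   coefficients (`NULL` draws a bimodal default distribution of fitness
#'   effects; stop codons get `s = -1`).
#' @slot seed integer RNG seed.
#' @export
setClass("SimulationConfig",
  representation(timepoints = "numeric", depth = "numeric",
                 noiseModel = "character", stopW = "numeric",
                 trueS = "ANY", seed = "integer"))

setValidity("SimulationConfig", function(object) {
  msg <- character()
  if (length(object@timepoints) < 2)
    msg <- c(msg, "at least two time points are required")
  if (is.unsorted(object@timepoints, strictly = TRUE))
    msg <- c(msg, "timepoints must be strictly increasing")
  if (!is.finite(object@depth) || object@depth <= 0)
    msg <- c(msg, "depth must be positive and finite")
  if (!object@noiseModel %in% c("multinomial", "poisson", "none"))
    msg <- c(msg, "noiseModel must be multinomial, poisson, or none")
  if (object@stopW >= 0)
    msg <- c(msg, "stopW must be negative (stop codons are deleterious)")
  if (length(msg)) msg else TRUE
})

#' @param timepoints,depth,noiseModel,stopW,trueS,seed see slots of
#'   [SimulationConfig-class].
#' @rdname SimulationConfig-class
#' @export
simulationConfig <- function(timepoints = seq(0, 4, length.out = 8),
                             depth = 1e5,
                             noiseModel = c("multinomial", "poisson", "none"),
                             stopW = -1, trueS = NULL, seed = 1L) {
  new("SimulationConfig", timepoints = as.numeric(timepoints),
      depth = as.numeric(depth), noiseModel = match.arg(noiseModel),
      stopW = as.numeric(stopW), trueS = trueS, seed = as.integer(seed))
}

# default distribution of fitness effects: bimodal, with a deleterious mode
# near the stop-codon null and a WT-like mode with a slight beneficial bias
defaultTrueS <- function(nPos, positions) {
  s <- matrix(NA_real_, nPos, length(AA_CLASSES),
              dimnames = list(positions, AA_CLASSES))
  n <- length(s)
  del <- stats::runif(n, -1.1, -0.8)
  tol <- stats::runif(n, -0.4, 0.3)
  pick <- stats::runif(n) < 0.55
  s[] <- ifelse(pick, del, tol)
  s[, "*"] <- -1
  s
}

# representative codon emitted for each (position, outcome) cell; for the
# WT-synonymous class this is a synonymous codon different from wtCodon
representativeCodon <- function(wtCodon, outcome) {
  mapply(function(wc, out) {
    cs <- codonsFor(out)
    cs <- setdiff(cs, wc)
    if (length(cs) == 0) NA_character_ else cs[1]
  }, wtCodon, outcome, USE.NAMES = FALSE)
}

#' Simulate bulk-competition count trajectories
#'
#' Emulates the growth-competition phase of an EMPIRIC scan: within each
#' library all variants (one per position and amino-acid outcome class) and
#' the wild type start at equal abundance and grow exponentially, variant
#' `i` accruing `2^(w_i * t)`-fold relative abundance after `t` WT doublings.
#' Sequencing counts at each time point are drawn from the configured noise
#' model around the expected relative abundances. The generating truth is
#' recorded in `rowData` for recovery scoring.
#'
#' @param design a [ScanLibraryDesign].
#' @param config a [SimulationConfig-class] (its `timepoints` must match the
#'   design's barcode times when reads are to be emitted).
#' @return a [CountTimeSeries].
#' @export
simulateGrowthCounts <- function(design, config = simulationConfig()) {
  validObject(config)
  set.seed(config@seed)
  p <- design@positions
  nPos <- nrow(p)
  trueS <- config@trueS %||% defaultTrueS(nPos, p$position)
  stopifnot(nrow(trueS) == nPos, ncol(trueS) == length(AA_CLASSES))
  times <- config@timepoints

  libs <- unique(p$library)
  rows <- lapply(libs, function(l) {
    pi <- p[p$library == l, ]
    data.frame(
      library = c(l, rep(pi$library, each = length(AA_CLASSES))),
      position = c(NA_integer_, rep(pi$position, each = length(AA_CLASSES))),
      withinPos = c(NA_integer_, rep(pi$withinPos, each = length(AA_CLASSES))),
      codon = c(NA_character_,
                as.vector(vapply(seq_len(nrow(pi)), function(i)
                  representativeCodon(rep(pi$wtCodon[i], length(AA_CLASSES)),
                                      AA_CLASSES), character(length(AA_CLASSES))))),
      outcome = c("WT", rep(AA_CLASSES, nrow(pi))),
      isWT = c(TRUE, rep(FALSE, nrow(pi) * length(AA_CLASSES))),
      stringsAsFactors = FALSE)
  })
  rd <- do.call(rbind, rows)
  idx <- match(rd$position, rownames(trueS))
  rd$trueS <- ifelse(rd$isWT, 0,
                     trueS[cbind(idx, match(rd$outcome, colnames(trueS)))])
  rd$trueW <- rd$trueS * abs(config@stopW)

  cm <- matrix(0, nrow(rd), length(times))
  for (l in libs) {
    sel <- which(rd$library == l)
    w <- rd$trueW[sel]
    for (j in seq_along(times)) {
      ex <- 2^(w * times[j])
      pr <- ex / sum(ex)
      cm[sel, j] <- switch(config@noiseModel,
        multinomial = stats::rmultinom(1, size = config@depth, prob = pr)[, 1],
        poisson = stats::rpois(length(pr), config@depth * pr),
        none = config@depth * pr)
    }
  }
  rn <- ifelse(rd$isWT, paste0("L", rd$library, ":WT"),
               paste0("L", rd$library, ":", rd$position, ":", rd$outcome))
  dimnames(cm) <- list(rn, paste0("t", seq_along(times)))
  se <- SummarizedExperiment(
    assays = list(counts = cm),
    rowData = DataFrame(rd, row.names = rn),
    colData = DataFrame(time = times, row.names = colnames(cm)))
  metadata(se) <- list(orthologue = design@orthologue,
                       depth = config@depth, noiseModel = config@noiseModel,
                       stopW = config@stopW, seed = config@seed)
  new("CountTimeSeries", se)
}

#' Emit barcoded FASTQ reads from a count table
#'
#' Produces one read per counted molecule: the time-stamping barcode followed
#' by the library window carrying the variant codon in its wild-type context.
#' A configurable fraction of reads is corrupted through three independent
#' failure channels (a low-quality base, an invalid barcode, mismatches
#' outside the mutagenized codon) to exercise the read filters; the planted
#' corruption per read is recorded in `metadata(reads)$truth`.
#'
#' @param counts a [CountTimeSeries] (integer counts; use multinomial or
#'   poisson noise, or round).
#' @param design the [ScanLibraryDesign] the counts were simulated from; its
#'   barcode times must cover the count time points.
#' @param corruption fraction of reads corrupted (default 0).
#' @param corruptionShares relative weights of the `quality`, `barcode`, and
#'   `reference` failure channels.
#' @param baseQuality Phred score given to clean bases (default 30).
#' @param seed RNG seed for corruption placement.
#' @return a [Biostrings::QualityScaledDNAStringSet]; per-read truth (time,
#'   source row, corruption channel) in `metadata()$truth`.
#' @export
emitReads <- function(counts, design, corruption = 0,
                      corruptionShares = c(quality = 1, barcode = 1,
                                           reference = 1),
                      baseQuality = 30L, seed = 1L) {
  stopifnot(corruption >= 0, corruption <= 1)
  if (anyDuplicated(design@barcodes)) stop("barcode collision in design")
  set.seed(seed)
  rd <- as.data.frame(rowData(counts))
  cm <- round(assay(counts, "counts"))
  times <- colData(counts)$time
  bcs <- design@barcodes[as.character(times)]
  if (anyNA(bcs)) stop("design barcodes do not cover the count time points")

  inserts <- character(nrow(rd))
  inserts[rd$isWT] <- vapply(rd$library[rd$isWT], function(l)
    wtInsert(design, l), character(1))
  vi <- which(!rd$isWT & !is.na(rd$codon))
  inserts[vi] <- vapply(vi, function(i)
    variantInsert(design, rd$position[i], rd$codon[i]), character(1))
  emittable <- rd$isWT | !is.na(rd$codon)
  if (!all(emittable))
    warning(sum(!emittable), " outcome cells have no representative codon ",
            "(no synonymous alternative) and emit no reads")

  rowIdx <- rep(rep(seq_len(nrow(rd)), ncol(cm)), as.vector(cm))
  tpIdx <- rep(rep(seq_len(ncol(cm)), each = nrow(rd)), as.vector(cm))
  keep <- emittable[rowIdx]
  rowIdx <- rowIdx[keep]; tpIdx <- tpIdx[keep]
  n <- length(rowIdx)
  seqs <- paste0(bcs[tpIdx], inserts[rowIdx])
  qual <- strrep(rawToChar(as.raw(33L + baseQuality)), design@readLength)
  quals <- rep(qual, n)

  channel <- rep("none", n)
  if (corruption > 0 && n > 0) {
    hit <- which(stats::runif(n) < corruption)
    sh <- corruptionShares / sum(corruptionShares)
    channel[hit] <- sample(names(sh), length(hit), TRUE, prob = sh)
    bq <- which(channel == "quality")
    if (length(bq)) {
      at <- sample.int(design@readLength, length(bq), replace = TRUE)
      substr(quals[bq], at, at) <- rawToChar(as.raw(33L + 10L))
    }
    bb <- which(channel == "barcode")
    if (length(bb)) {
      bad <- badBarcode(design)
      substr(seqs[bb], 1L, barcodeLength(design)) <- bad
    }
    br <- which(channel == "reference")
    if (length(br)) {
      # corrupt the two trailing context bases: mismatches outside any codon
      at <- design@readLength - 1L
      substr(seqs[br], at, at) <- chartr("ACGT", "CATG", substr(seqs[br], at, at))
      substr(seqs[br], at + 1L, at + 1L) <-
        chartr("ACGT", "CATG", substr(seqs[br], at + 1L, at + 1L))
    }
  }
  ids <- sprintf("read%06d", seq_len(n))
  reads <- Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(setNames(seqs, ids)),
    Biostrings::PhredQuality(quals))
  metadata(reads)$truth <- data.frame(
    id = ids, time = times[tpIdx], row = rownames(rd)[rowIdx],
    channel = channel, stringsAsFactors = FALSE)
  reads
}

# a barcode-length sequence guaranteed absent from the design's barcode set
badBarcode <- function(design) {
  k <- barcodeLength(design)
  pool <- vapply(1:50, function(i)
    paste(sample(c("A", "C", "G", "T"), k, TRUE), collapse = ""), character(1))
  cand <- setdiff(pool, design@barcodes)
  if (!length(cand)) stop("could not find an invalid barcode")
  cand[1]
}

#' Write / read FASTQ (Sanger Phred+33)
#'
#' Thin wrappers around Biostrings for the package's read exchange format.
#'
#' @param reads a [Biostrings::QualityScaledDNAStringSet].
#' @param path FASTQ file path (uncompressed).
#' @export
writeFastq <- function(reads, path) {
  Biostrings::writeQualityScaledXStringSet(reads, path)
  invisible(path)
}

#' @rdname writeFastq
#' @export
readFastq <- function(path) {
  withCallingHandlers(
    Biostrings::readQualityScaledDNAStringSet(path),
    warning = function(w) {
      # benign Biostrings note about dropping per-record mcols on coercion
      if (grepl("metadata columns", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
}

#' Simulate a trio of correlated fitness landscapes
#'
#' Null/alternative generator for the cross-orthologue correlation framework.
#' For each aligned position, each orthologue's 20-value amino-acid profile is
#' `sqrt(rho) * shared + sqrt(1 - rho) * independent`, with both components
#' standardized to mean 0 and unit variance across the 20 outcomes, so the
#' expected profile correlation between any two orthologues is `rho`.
#'
#' @param nPositions number of aligned positions (>= 2; 80 matches a full
#'   8-library scan).
#' @param rho shared-signal mixing weight in `[0, 1]`.
#' @param wtPolicy `"identical"` gives all orthologues the same wild-type
#'   residue per position; `"sampled"` draws them independently.
#' @param positionsPerLib positions per library used to annotate the
#'   landscapes with library/within-position indices.
#' @param seed RNG seed.
#' @return list with `landscapes` (three [FitnessLandscape]s, stop class
#'   absent), `maps` (pairwise identity [alignmentMap]s), and `rho`.
#' @export
simulateLandscapeTrio <- function(nPositions = 80L, rho = 0.5,
                                  wtPolicy = c("identical", "sampled"),
                                  positionsPerLib = 10L, seed = 1L) {
  stopifnot(nPositions >= 2, rho >= 0, rho <= 1)
  wtPolicy <- match.arg(wtPolicy)
  set.seed(seed)
  aa <- AA_CLASSES[-21]
  std <- function(v) as.numeric(scale(v))
  orth <- c("orthA", "orthB", "orthC")
  prof <- lapply(orth, function(o)
    matrix(NA_real_, nPositions, 20, dimnames = list(NULL, aa)))
  names(prof) <- orth
  for (i in seq_len(nPositions)) {
    z <- std(stats::rnorm(20))
    for (o in orth) {
      e <- std(stats::rnorm(20))
      prof[[o]][i, ] <- sqrt(rho) * z + sqrt(1 - rho) * e
    }
  }
  wt <- if (wtPolicy == "identical") {
    w <- sample(aa, nPositions, replace = TRUE)
    list(orthA = w, orthB = w, orthC = w)
  } else {
    setNames(lapply(orth, function(o) sample(aa, nPositions, TRUE)), orth)
  }
  lib <- rep(seq_len(ceiling(nPositions / positionsPerLib)),
             each = positionsPerLib)[seq_len(nPositions)]
  wp <- stats::ave(seq_len(nPositions), lib, FUN = seq_along)
  landscapes <- lapply(orth, function(o)
    newFitnessLandscape(s = prof[[o]], w = prof[[o]], library = lib,
                        withinPos = wp, wtAA = wt[[o]],
                        positions = seq_len(nPositions), orthologue = o))
  names(landscapes) <- orth
  mkMap <- function(a, b) alignmentMap(
    posA = seq_len(nPositions), aaA = wt[[a]],
    posB = seq_len(nPositions), aaB = wt[[b]], kind = "structural")
  list(landscapes = landscapes,
       maps = list(AB = mkMap("orthA", "orthB"),
                   AC = mkMap("orthA", "orthC"),
                   BC = mkMap("orthB", "orthC")),
       rho = rho)
}

#' Simulate a multiple sequence alignment from column profiles
#'
#' Sequences are drawn i.i.d. per column from the stated amino-acid
#' distributions; empirical column frequencies converge to the profiles as
#' the number of sequences grows.
#'
#' @param columnProfiles numeric matrix, rows named by residues (20 amino
#'   acids, optionally `"-"` for a gap fraction), one column per alignment
#'   column; each column must sum to 1.
#' @param nSequences number of sequences to draw.
#' @param seed RNG seed.
#' @return a [Biostrings::AAStringSet].
#' @export
simulateMsa <- function(columnProfiles, nSequences, seed = 1L) {
  stopifnot(is.matrix(columnProfiles), nSequences >= 1)
  if (any(abs(colSums(columnProfiles) - 1) > 1e-8))
    stop("each column profile must sum to 1")
  if (any(columnProfiles < 0))
    stop("column profiles must be non-negative")
  set.seed(seed)
  res <- rownames(columnProfiles)
  m <- vapply(seq_len(ncol(columnProfiles)), function(j)
    sample(res, nSequences, replace = TRUE, prob = columnProfiles[, j]),
    character(nSequences))
  if (nSequences == 1) m <- matrix(m, nrow = 1)
  seqs <- apply(m, 1, paste, collapse = "")
  Biostrings::AAStringSet(setNames(seqs, sprintf("seq%05d", seq_len(nSequences))))
}
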