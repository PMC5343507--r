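#' Empirical maximum solvent-accessible surface areas
#'
#' Per-residue maximum ASA values (Angstrom^2) from the empirical
#' Gly-X-Gly scale of Tien and colleagues, used to convert absolute to
#' relative solvent accessibility. Supplied as data so an alternative scale
#' can be passed to [rsaFromAsa()].
#'
#' @export
maxASAEmpirical <- c(
  A = 121, R = 265, N = 187, D = 187, C = 148, E = 214, Q = 214, G = 97,
  H = 216, I = 195, L = 191, K = 230, M = 203, F = 228, P = 154, S = 143,
  T = 163, W = 264, Y = 255, V = 165)

#' Kyte-Doolittle hydropathy scale
#'
#' Default hydrophobicity scale for wild-type residues; any named numeric
#' vector over the 20 amino acids can be used in its place.
#'
#' @export
kyteDoolittle <- c(
  A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, E = -3.5, Q = -3.5,
  G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
  P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2)

#' Four-fold symmetry index of a library position
#'
#' The TIM barrel's four-fold (beta-alpha-beta-alpha) symmetry groups the
#' eight libraries into pairs of consecutive odd/even strands: quadrant
#' `ceil(library / 2)`, with offsets 1-10 for the odd library of the pair and
#' 11-20 for the even one. The mapping is a bijection from the 80
#' `(library, position)` slots onto the 4 x 20 grid.
#'
#' @param library library index, 1-8.
#' @param withinPos position inside the library window, 1-10.
#' @return data.frame with columns `quadrant` and `offset`.
#' @export
fourfoldIndex <- function(library, withinPos) {
  library <- as.integer(library)
  withinPos <- as.integer(withinPos)
  if (any(library < 1 | library > 8, na.rm = TRUE))
    stop("library must be in 1..8")
  if (any(withinPos < 1 | withinPos > 10, na.rm = TRUE))
    stop("withinPos must be in 1..10")
  data.frame(quadrant = (library + 1L) %/% 2L,
             offset = withinPos + 10L * (1L - library %% 2L))
}

#' Relative solvent accessibility from absolute ASA
#'
#' `rsa = min(asa / maxASA(residue), cap)`.
#'
#' @param asa absolute solvent-accessible surface area (Angstrom^2, >= 0).
#' @param residue single-letter wild-type residue(s).
#' @param maxASA named maximum-ASA table (default [maxASAEmpirical]).
#' @param cap upper cap on RSA (default 1; `Inf` disables capping).
#' @return relative solvent accessibility.
#' @export
rsaFromAsa <- function(asa, residue, maxASA = maxASAEmpirical, cap = 1) {
  stopifnot(all(asa >= 0, na.rm = TRUE))
  mx <- maxASA[residue]
  if (anyNA(mx)) stop("unknown residue(s): ",
                      paste(unique(residue[is.na(mx)]), collapse = ", "))
  pmin(asa / unname(mx), cap)
}

# character matrix (sequences x columns) from an AAStringSet alignment
msaMatrix <- function(msa) {
  if (is(msa, "AAStringSet")) msa <- as.character(msa)
  do.call(rbind, strsplit(msa, NULL))
}

#' Wild-type conservation of an alignment column
#'
#' Fraction of non-gap sequences carrying the wild-type residue.
#'
#' @param column character vector of residues (one per sequence); `-` and `.`
#'   are gaps.
#' @param wtResidue the wild-type residue.
#' @return fraction in `[0, 1]`; `NA` with a warning for an all-gap column.
#' @export
wtConservation <- function(column, wtResidue) {
  keep <- !column %in% c("-", ".")
  if (!any(keep)) {
    warning("all-gap column: conservation undefined")
    return(NA_real_)
  }
  mean(column[keep] == wtResidue)
}

#' Shannon information content of an alignment column
#'
#' `IC = log2(20) - H` bits, where `H` is the Shannon entropy of the
#' (optionally pseudocounted) amino-acid frequencies; gaps are excluded.
#'
#' @param column character vector of residues; `-` and `.` are gaps.
#' @param pseudocount count added to every amino acid before normalization
#'   (default 0).
#' @return information content in bits, in `[0, log2(20)]`; `NA` with a
#'   warning for an all-gap column.
#' @export
informationContent <- function(column, pseudocount = 0) {
  aa <- AA_CLASSES[-21]
  keep <- column %in% aa
  if (!any(keep) && pseudocount == 0) {
    warning("all-gap column: information content undefined")
    return(NA_real_)
  }
  cnt <- table(factor(column[keep], levels = aa)) + pseudocount
  f <- cnt / sum(cnt)
  f <- f[f > 0]
  log2(20) + sum(f * log2(f))
}

#' Per-position conservation and information content from an MSA
#'
#' @param msa a [Biostrings::AAStringSet] alignment.
#' @param columns alignment column indices for the library positions.
#' @param wtResidues wild-type residues, one per requested column.
#' @param pseudocount see [informationContent()].
#' @return data.frame with `column`, `wtConservation`, `informationContent`.
#' @export
msaConservation <- function(msa, columns, wtResidues, pseudocount = 0) {
  stopifnot(length(columns) == length(wtResidues))
  m <- msaMatrix(msa)
  if (any(columns > ncol(m))) stop("column index beyond alignment width")
  data.frame(
    column = columns,
    wtConservation = vapply(seq_along(columns), function(i)
      wtConservation(m[, columns[i]], wtResidues[i]), numeric(1)),
    informationContent = vapply(columns, function(j)
      informationContent(m[, j], pseudocount), numeric(1)))
}

#' Position-correspondence map between two orthologues
#'
#' Ordered pairs of aligned positions with the wild-type residues on both
#' sides; `kind` records how the correspondence was derived (structural or
#' sequence alignment, or the barrel's four-fold symmetry). Each position
#' appears at most once per map, and maps are involutive under
#' [invertAlignmentMap()].
#'
#' @param posA,posB aligned positions in the two constructs' numbering.
#' @param aaA,aaB wild-type residues on each side.
#' @param kind `"structural"`, `"sequence"`, or `"fourfold"`.
#' @return data.frame of class `AlignmentMap` with columns `posA`, `aaA`,
#'   `posB`, `aaB` and a `kind` attribute.
#' @export
alignmentMap <- function(posA, aaA, posB, aaB,
                         kind = c("structural", "sequence", "fourfold")) {
  kind <- match.arg(kind)
  m <- data.frame(posA = as.integer(posA), aaA = as.character(aaA),
                  posB = as.integer(posB), aaB = as.character(aaB),
                  stringsAsFactors = FALSE)
  if (anyDuplicated(m$posA) || anyDuplicated(m$posB))
    stop("each position may appear at most once per map")
  attr(m, "kind") <- kind
  class(m) <- c("AlignmentMap", "data.frame")
  m
}

#' @rdname alignmentMap
#' @param map an `AlignmentMap`.
#' @export
invertAlignmentMap <- function(map) {
  alignmentMap(map$posB, map$aaB, map$posA, map$aaA, attr(map, "kind"))
}

#' Read / write alignment maps as TSV
#'
#' Columns: `pos_a`, `aa_a`, `pos_b`, `aa_b`, `kind`.
#'
#' @param map an [alignmentMap()].
#' @param path TSV path.
#' @export
writeAlignmentMap <- function(map, path) {
  utils::write.table(
    data.frame(pos_a = map$posA, aa_a = map$aaA, pos_b = map$posB,
               aa_b = map$aaB, kind = attr(map, "kind")),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeAlignmentMap
#' @export
readAlignmentMap <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  alignmentMap(d$pos_a, d$aa_a, d$pos_b, d$aa_b, kind = d$kind[1])
}

#' Assemble a per-position annotation table
#'
#' Merges structural annotation (secondary-structure element, layer,
#' side-chain orientation, ASA, b-factor) with derived quantities: RSA from
#' ASA, four-fold quadrant/offset from the library layout, wild-type
#' hydrophobicity, and MSA conservation / information content when an
#' alignment is given.
#'
#' @param landscape a [FitnessLandscape] (supplies positions, libraries,
#'   wild-type residues).
#' @param structure optional data.frame with `position` plus any of
#'   `element`, `layer`, `orientation`, `asa`, `bFactor`.
#' @param msa,msaColumns optional alignment and the alignment column of each
#'   landscape position.
#' @param hydrophobicity named scale (default [kyteDoolittle]).
#' @param maxASA see [rsaFromAsa()].
#' @return data.frame, one row per position.
#' @export
annotatePositions <- function(landscape, structure = NULL, msa = NULL,
                              msaColumns = NULL,
                              hydrophobicity = kyteDoolittle,
                              maxASA = maxASAEmpirical) {
  info <- positionInfo(landscape)
  ann <- data.frame(position = as.integer(rownames(info)),
                    library = info$library, withinPos = info$withinPos,
                    wtAA = info$wtAA, stringsAsFactors = FALSE)
  ff <- fourfoldIndex(ann$library, ann$withinPos)
  ann$quadrant <- ff$quadrant
  ann$offset <- ff$offset
  ann$wtHydrophobicity <- unname(hydrophobicity[ann$wtAA])
  if (!is.null(structure)) {
    ann <- merge(ann, structure, by = "position", all.x = TRUE, sort = FALSE)
    ann <- ann[order(ann$position), ]
    if ("asa" %in% names(ann))
      ann$rsa <- rsaFromAsa(ann$asa, ann$wtAA, maxASA)
  }
  if (!is.null(msa)) {
    stopifnot(length(msaColumns) == nrow(ann))
    cons <- msaConservation(msa, msaColumns, ann$wtAA)
    ann$wtConservation <- cons$wtConservation
    ann$informationContent <- cons$informationContent
  }
  rownames(ann) <- ann$position
  ann
}
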