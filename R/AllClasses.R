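#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @import SummarizedExperiment
NULL

#' The 21 amino-acid outcome classes
#'
#' Single-letter codes for the 20 amino acids plus `"*"` for stop codons.
#' Every mutagenized position has one outcome cell per class; the class equal
#' to the wild-type residue collects synonymous and missense-to-WT codons.
#'
#' @export
AA_CLASSES <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y", "*")

#' Saturation-mutagenesis library design
#'
#' Describes one orthologue's EMPIRIC construct: the reference gene sequence,
#' the mutagenized windows (libraries of consecutive positions, 10 by
#' default), the wild-type codon and residue at each position, and the
#' time-stamping barcodes used to multiplex sampling time points on one lane.
#'
#' @slot orthologue single orthologue name.
#' @slot reference reference gene nucleotide sequence (character, ACGT).
#' @slot positions data.frame with columns `library`, `position` (residue
#'   number), `withinPos` (1-based index inside the library window),
#'   `wtCodon`, `wtAA`, `codonStart` (1-based nucleotide offset of the codon
#'   in `reference`).
#' @slot barcodes named character vector mapping time point (name, in WT
#'   doublings) to barcode sequence.
#' @slot readLength read length the sequencing run produces.
#'
#' @export
setClass("ScanLibraryDesign",
  representation(
    orthologue = "character",
    reference  = "character",
    positions  = "data.frame",
    barcodes   = "character",
    readLength = "integer"
  )
)

setValidity("ScanLibraryDesign", function(object) {
  msg <- character()
  p <- object@positions
  need <- c("library", "position", "withinPos", "wtCodon", "wtAA", "codonStart")
  if (!all(need %in% names(p)))
    msg <- c(msg, paste("positions must have columns:",
                        paste(need, collapse = ", ")))
  else {
    if (anyDuplicated(p$position))
      msg <- c(msg, "positions must be unique")
    if (!all(p$wtAA %in% AA_CLASSES[-21]))
      msg <- c(msg, "wtAA must be one of the 20 amino acids")
    if (!all(translateCodon(p$wtCodon) == p$wtAA))
      msg <- c(msg, "wtCodon must translate to wtAA")
  }
  if (grepl("[^ACGT]", object@reference))
    msg <- c(msg, "reference must contain only A, C, G, T")
  if (anyDuplicated(object@barcodes))
    msg <- c(msg, "barcodes must be distinct")
  if (length(unique(nchar(object@barcodes))) > 1)
    msg <- c(msg, "barcodes must share a common length")
  if (length(msg)) msg else TRUE
})

#' Per-variant count trajectories from a bulk growth competition
#'
#' A [SummarizedExperiment::SummarizedExperiment] whose rows are sequence
#' variants (one row per `(library, position, codon)` plus one wild-type
#' reference row per library) and whose columns are sampling time points in
#' wild-type doublings. The single assay `counts` holds read counts.
#' Simulated objects carry the generating truth (`trueW`, `trueS`) in
#' `rowData` so estimator recovery can be scored.
#'
#' @export
setClass("CountTimeSeries", contains = "SummarizedExperiment")

setValidity("CountTimeSeries", function(object) {
  msg <- character()
  if (!"counts" %in% assayNames(object))
    msg <- c(msg, "assay 'counts' is required")
  else if (any(assay(object, "counts") < 0, na.rm = TRUE))
    msg <- c(msg, "counts must be non-negative")
  rd <- rowData(object)
  need <- c("library", "position", "codon", "outcome", "isWT")
  if (!all(need %in% names(rd)))
    msg <- c(msg, paste("rowData must have columns:",
                        paste(need, collapse = ", ")))
  if (!"time" %in% names(colData(object)))
    msg <- c(msg, "colData must have a 'time' column (WT doublings)")
  else if (is.unsorted(colData(object)$time, strictly = TRUE))
    msg <- c(msg, "time points must be strictly increasing")
  if (length(msg)) msg else TRUE
})

#' Position-by-outcome fitness landscape
#'
#' A [SummarizedExperiment::SummarizedExperiment] with one row per mutagenized
#' position and one column per amino-acid outcome class. Assays: `w` (raw
#' fitness, the per-doubling slope of log2 mutant/WT abundance), `s`
#' (stop-normalized selection coefficient), and `excluded` (character matrix:
#' `""` for analysed cells, otherwise the exclusion reason, e.g. `"mmei"` or
#' `"low_coverage"`). `rowData` carries `library`, `withinPos`, `wtAA`;
#' `metadata` records the orthologue, the per-library mean stop-codon raw
#' fitness used for normalization, and processing parameters.
#'
#' @export
setClass("FitnessLandscape", contains = "SummarizedExperiment")

setValidity("FitnessLandscape", function(object) {
  msg <- character()
  if (!"s" %in% assayNames(object))
    msg <- c(msg, "assay 's' is required")
  if (!all(colnames(object) %in% AA_CLASSES))
    msg <- c(msg, "column names must be amino-acid outcome classes")
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, "outcome classes must be unique")
  rd <- rowData(object)
  need <- c("library", "withinPos", "wtAA")
  if (!all(need %in% names(rd)))
    msg <- c(msg, paste("rowData must have columns:",
                        paste(need, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

setMethod("show", "ScanLibraryDesign", function(object) {
  p <- object@positions
  cat("ScanLibraryDesign for", object@orthologue, "\n")
  cat(" ", length(unique(p$library)), "libraries,", nrow(p), "positions,",
      nchar(object@reference), "nt reference\n")
  cat(" ", length(object@barcodes), "time barcodes (",
      nchar(object@barcodes[1]), "nt ), read length",
      object@readLength, "\n")
})

setMethod("show", "CountTimeSeries", function(object) {
  cat("CountTimeSeries:", nrow(object), "variants x", ncol(object),
      "time points (", paste(signif(colData(object)$time, 3), collapse = ", "),
      "doublings )\n")
  cat("  total reads:", sum(assay(object, "counts")), "\n")
})

setMethod("show", "FitnessLandscape", function(object) {
  cat("FitnessLandscape:", nrow(object), "positions x", ncol(object),
      "outcome classes\n")
  ex <- if ("excluded" %in% assayNames(object))
    sum(assay(object, "excluded") != "") else 0L
  nc <- prod(dim(object))
  cat("  analysed cells:", nc - ex, "of", nc, "(", ex, "excluded )\n")
  sm <- metadata(object)$stopMean
  if (!is.null(sm))
    cat("  per-library stop-mean raw fitness:",
        paste(signif(sm, 3), collapse = ", "), "\n")
})
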