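#' Accessors for scan objects
#'
#' `selCoef()` returns the position-by-outcome matrix of selection
#' coefficients, `rawFitnessMatrix()` the matrix of raw fitness slopes,
#' `exclusionReasons()` the character matrix of exclusion reasons (`""` means
#' analysed), `wtResidues()` the wild-type residue per position, and
#' `positionInfo()` the per-position metadata as a data.frame.
#'
#' @param object a [FitnessLandscape] (or, for `positionInfo`, a
#'   [ScanLibraryDesign]).
#' @return see details per accessor.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("selCoef", function(object) standardGeneric("selCoef"))

#' @rdname accessors
#' @export
setGeneric("rawFitnessMatrix",
           function(object) standardGeneric("rawFitnessMatrix"))

#' @rdname accessors
#' @export
setGeneric("exclusionReasons",
           function(object) standardGeneric("exclusionReasons"))

#' @rdname accessors
#' @export
setGeneric("wtResidues", function(object) standardGeneric("wtResidues"))

#' @rdname accessors
#' @export
setGeneric("positionInfo", function(object) standardGeneric("positionInfo"))

#' @rdname accessors
#' @export
setMethod("selCoef", "FitnessLandscape", function(object) {
  m <- assay(object, "s")
  if ("excluded" %in% assayNames(object))
    m[assay(object, "excluded") != ""] <- NA_real_
  m
})

#' @rdname accessors
#' @export
setMethod("rawFitnessMatrix", "FitnessLandscape", function(object) {
  assay(object, "w")
})

#' @rdname accessors
#' @export
setMethod("exclusionReasons", "FitnessLandscape", function(object) {
  if ("excluded" %in% assayNames(object)) assay(object, "excluded")
  else matrix("", nrow(object), ncol(object), dimnames = dimnames(object))
})

#' @rdname accessors
#' @export
setMethod("wtResidues", "FitnessLandscape", function(object) {
  setNames(as.character(rowData(object)$wtAA), rownames(object))
})

#' @rdname accessors
#' @export
setMethod("positionInfo", "FitnessLandscape", function(object) {
  as.data.frame(rowData(object))
})

#' @rdname accessors
#' @export
setMethod("positionInfo", "ScanLibraryDesign", function(object) {
  object@positions
})

#' @rdname accessors
#' @export
setMethod("wtResidues", "ScanLibraryDesign", function(object) {
  setNames(object@positions$wtAA, object@positions$position)
})

#' Reference sequence and barcodes of a design
#'
#' @param object a [ScanLibraryDesign].
#' @return `referenceSeq()`: the reference nucleotide sequence as a single
#'   character string; `timeBarcodes()`: named character vector, names are
#'   sampling times in WT doublings.
#' @export
setGeneric("referenceSeq", function(object) standardGeneric("referenceSeq"))

#' @rdname referenceSeq
#' @export
setGeneric("timeBarcodes", function(object) standardGeneric("timeBarcodes"))

#' @rdname referenceSeq
#' @export
setMethod("referenceSeq", "ScanLibraryDesign", function(object) {
  object@reference
})

#' @rdname referenceSeq
#' @export
setMethod("timeBarcodes", "ScanLibraryDesign", function(object) {
  object@barcodes
})
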