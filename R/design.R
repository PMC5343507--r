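#' Construct a saturation-mutagenesis library design
#'
#' @param orthologue orthologue name.
#' @param reference reference gene nucleotide sequence (single string, ACGT).
#' @param positions data.frame with columns `library`, `position`,
#'   `withinPos`, `wtCodon`, `wtAA`, `codonStart`.
#' @param barcodes named character vector; names are sampling times in WT
#'   doublings, values the time-stamping barcode sequences.
#' @param readLength sequencing read length (default 36, single-end).
#' @return a [ScanLibraryDesign].
#' @export
scanLibraryDesign <- function(orthologue, reference, positions, barcodes,
                              readLength = 36L) {
  new("ScanLibraryDesign",
      orthologue = as.character(orthologue),
      reference = toupper(as.character(reference)),
      positions = as.data.frame(positions),
      barcodes = barcodes,
      readLength = as.integer(readLength))
}

barcodeLength <- function(design) nchar(design@barcodes[[1]])

insertLength <- function(design) design@readLength - barcodeLength(design)

positionsPerLibrary <- function(design) {
  max(design@positions$withinPos)
}

# 1-based nucleotide start of a library's sequenced window in the reference
libraryWindowStart <- function(design, lib) {
  p <- design@positions
  min(p$codonStart[p$library == lib])
}

# WT sequence of the read insert (window + trailing context) for a library
wtInsert <- function(design, lib) {
  s <- libraryWindowStart(design, lib)
  substr(design@reference, s, s + insertLength(design) - 1L)
}

# insert with one position's codon substituted
variantInsert <- function(design, position, codon) {
  p <- design@positions
  i <- match(position, p$position)
  if (is.na(i)) stop("unknown position: ", position)
  lib <- p$library[i]
  off <- p$codonStart[i] - libraryWindowStart(design, lib)
  ins <- wtInsert(design, lib)
  substr(ins, off + 1L, off + 3L) <- codon
  ins
}

#' Generate a random library design
#'
#' Builds a synthetic EMPIRIC construct: contiguous mutagenized windows of
#' `positionsPerLibrary` consecutive residues, a random reference sequence
#' free of MmeI recognition sites in every wild-type read, and distinct
#' random time-stamping barcodes. Wild-type codons are drawn from amino acids
#' with at least two synonymous codons so the wild-type-synonymous outcome
#' class is always realisable.
#'
#' @param nLibraries number of 10-residue windows (8 per orthologue in a full
#'   design).
#' @param positionsPerLibrary residues per window (default 10).
#' @param orthologue orthologue name.
#' @param timepoints sampling times in WT doublings (strictly increasing; the
#'   default spans 4 doublings over 8 time points).
#' @param firstResidue residue number of the first mutagenized position.
#' @param readLength,barcodeLen read geometry; the insert
#'   (`readLength - barcodeLen`) must cover the window plus at least two
#'   trailing context bases.
#' @param forceWT optional named character vector `position -> amino acid`
#'   forcing the wild-type residue at given positions.
#' @param seed RNG seed.
#' @return a [ScanLibraryDesign].
#' @export
randomScanDesign <- function(nLibraries = 8L, positionsPerLibrary = 10L,
                             orthologue = "orthA",
                             timepoints = seq(0, 4, length.out = 8),
                             firstResidue = 1L, readLength = 36L,
                             barcodeLen = 4L, forceWT = NULL, seed = 1L) {
  stopifnot(nLibraries >= 1, positionsPerLibrary >= 1,
            !is.unsorted(timepoints, strictly = TRUE))
  if (readLength - barcodeLen < 3L * positionsPerLibrary + 2L)
    stop("read length too short for the library window plus context")
  set.seed(seed)
  nPos <- nLibraries * positionsPerLibrary
  code <- Biostrings::GENETIC_CODE
  aaTab <- table(code[code != "*"])
  okCodons <- names(code)[code %in% names(aaTab)[aaTab >= 2] & code != "*"]
  flankLeft <- 3L
  flankRight <- (readLength - barcodeLen) - 3L * positionsPerLibrary + 3L

  for (attempt in 1:200) {
    wtCodon <- sample(okCodons, nPos, replace = TRUE)
    if (!is.null(forceWT)) {
      idx <- as.integer(names(forceWT)) - firstResidue + 1L
      stopifnot(all(idx >= 1 & idx <= nPos))
      wtCodon[idx] <- vapply(forceWT, function(a) {
        cs <- setdiff(codonsFor(a), character())
        cs[1]
      }, character(1))
    }
    flL <- paste(sample(c("A", "C", "G", "T"), flankLeft, TRUE), collapse = "")
    flR <- paste(sample(c("A", "C", "G", "T"), flankRight, TRUE), collapse = "")
    reference <- paste0(flL, paste(wtCodon, collapse = ""), flR)
    barcodes <- character(0)
    while (length(unique(barcodes)) < length(timepoints))
      barcodes <- vapply(seq_along(timepoints), function(i)
        paste(sample(c("A", "C", "G", "T"), barcodeLen, TRUE), collapse = ""),
        character(1))
    names(barcodes) <- as.character(timepoints)

    positions <- data.frame(
      library = rep(seq_len(nLibraries), each = positionsPerLibrary),
      position = seq(firstResidue, length.out = nPos),
      withinPos = rep(seq_len(positionsPerLibrary), nLibraries),
      wtCodon = wtCodon,
      wtAA = translateCodon(wtCodon),
      codonStart = flankLeft + 3L * (seq_len(nPos) - 1L) + 1L,
      stringsAsFactors = FALSE)

    d <- scanLibraryDesign(orthologue, reference, positions, barcodes,
                           readLength)
    clean <- !any(containsMmeISite(wtInsert(d, seq_len(nLibraries)))) &&
      !any(containsMmeISite(as.vector(outer(barcodes,
        wtInsert(d, seq_len(nLibraries)), paste0))))
    if (clean) return(d)
  }
  stop("could not generate an MmeI-free reference; try another seed")
}

#' Write / read a library design as plain-text files
#'
#' The design is exchanged as a positions TSV, a barcode TSV
#' (columns `time`, `barcode`) and the reference as FASTA.
#'
#' @param design a [ScanLibraryDesign].
#' @param prefix file path prefix; writes `<prefix>_design.tsv`,
#'   `<prefix>_barcodes.tsv` and `<prefix>_reference.fasta`.
#' @return `writeDesign()`: the three paths, invisibly; `readDesign()`: a
#'   [ScanLibraryDesign].
#' @export
writeDesign <- function(design, prefix) {
  pd <- file.path(paste0(prefix, "_design.tsv"))
  pb <- file.path(paste0(prefix, "_barcodes.tsv"))
  pf <- file.path(paste0(prefix, "_reference.fasta"))
  pos <- cbind(orthologue = design@orthologue, design@positions,
               readLength = design@readLength)
  utils::write.table(pos, pd, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(time = names(design@barcodes), barcode = design@barcodes),
    pb, sep = "\t", quote = FALSE, row.names = FALSE)
  ref <- Biostrings::DNAStringSet(design@reference)
  names(ref) <- design@orthologue
  Biostrings::writeXStringSet(ref, pf)
  invisible(c(design = pd, barcodes = pb, reference = pf))
}

#' @rdname writeDesign
#' @export
readDesign <- function(prefix) {
  pos <- utils::read.delim(paste0(prefix, "_design.tsv"),
                           stringsAsFactors = FALSE)
  bc <- utils::read.delim(paste0(prefix, "_barcodes.tsv"),
                          colClasses = "character")
  ref <- Biostrings::readDNAStringSet(paste0(prefix, "_reference.fasta"))
  scanLibraryDesign(pos$orthologue[1], as.character(ref[[1]]),
                    pos[setdiff(names(pos), c("orthologue", "readLength"))],
                    setNames(bc$barcode, bc$time),
                    readLength = pos$readLength[1])
}
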