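#' Translate codons with the standard genetic code
#'
#' @param codon character vector of 3-nt codons (ACGT).
#' @return single-letter amino acids, `"*"` for stop codons.
#' @export
translateCodon <- function(codon) {
  code <- Biostrings::GENETIC_CODE
  aa <- unname(code[toupper(codon)])
  if (anyNA(aa)) stop("invalid codon(s): ",
                      paste(codon[is.na(aa)], collapse = ", "))
  aa
}

# all 64 codons, ordered; computed once at load
allCodons <- function() {
  names(Biostrings::GENETIC_CODE)
}

# codons encoding a given amino-acid class ("*" for stop)
codonsFor <- function(aa) {
  code <- Biostrings::GENETIC_CODE
  names(code)[code == aa]
}

reverseComplement <- function(x) {
  chartr("ACGT", "TGCA",
         vapply(strsplit(x, NULL), function(b) paste(rev(b), collapse = ""),
                character(1)))
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# deterministic child seed; keeps derived seeds in 32-bit integer range
childSeed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + k * 104729) %% .Machine$integer.max)
}
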