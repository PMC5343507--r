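#' The seven poor-coverage mutations removed from the IGPS analysis
#'
#' Variants under-represented in the mutagenesis libraries of the three IGPS
#' orthologues (SsIGPS, TmIGPS, TtIGPS) that are excluded from analysis in
#' addition to the MmeI-creating mutations. Shipped as a plain-text table;
#' positions are in each construct's residue numbering.
#'
#' @return data.frame with columns `orthologue`, `position`, `wt_aa`,
#'   `mut_aa`.
#' @export
poorCoverageMutations <- function() {
  utils::read.delim(system.file("extdata", "poor_coverage_mutations.tsv",
                                package = "empiricscan"),
                    stringsAsFactors = FALSE)
}

#' Synthetic designs for the three IGPS orthologues
#'
#' Builds one 8-library, 80-position design per orthologue with the study's
#' library layout (10 residues per library, 21 outcome classes per position)
#' and residue numbering chosen so the positions named in
#' [poorCoverageMutations()] exist with the recorded wild-type residues. The
#' reference gene sequences are synthetic stand-ins — the layout, not the
#' sequence, is what downstream accounting depends on.
#'
#' @param seed RNG seed for the synthetic references.
#' @return named list of three [ScanLibraryDesign]s.
#' @export
igpsScanDesigns <- function(seed = 1L) {
  pc <- poorCoverageMutations()
  firstRes <- c(SsIGPS = 131L, TmIGPS = 111L, TtIGPS = 78L)
  out <- lapply(names(firstRes), function(o) {
    tab <- pc[pc$orthologue == o, ]
    force <- setNames(tab$wt_aa[!duplicated(tab$position)],
                      tab$position[!duplicated(tab$position)])
    randomScanDesign(nLibraries = 8L, positionsPerLibrary = 10L,
                     orthologue = o, firstResidue = firstRes[[o]],
                     forceWT = force, seed = childSeed(seed, match(o, names(firstRes))))
  })
  names(out) <- names(firstRes)
  out
}
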