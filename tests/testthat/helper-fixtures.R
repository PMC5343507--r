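suppressPackageStartupMessages({
  library(SummarizedExperiment)
  library(S4Vectors)
})

# compact two-library design with matching simulation timepoints
smallDesign <- function(seed = 3, nLibraries = 2, timepoints = c(0, 2, 4)) {
  randomScanDesign(nLibraries = nLibraries, timepoints = timepoints,
                   seed = seed)
}

# landscape built directly from an s matrix (positions x outcomes)
toyLandscape <- function(s, wtAA = NULL, orthologue = "toy",
                         library = NULL, withinPos = NULL) {
  n <- nrow(s)
  if (is.null(colnames(s))) colnames(s) <- AA_CLASSES[seq_len(ncol(s))]
  if (is.null(wtAA)) wtAA <- rep("A", n)
  if (is.null(library)) library <- rep(1L, n)
  if (is.null(withinPos)) withinPos <- seq_len(n)
  empiricscan:::newFitnessLandscape(
    s = s, library = library, withinPos = withinPos, wtAA = wtAA,
    positions = rownames(s) %||% seq_len(n), orthologue = orthologue)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# independent brute-force MmeI scan: slide a window and compare against the
# IUPAC degenerate site TCCRAC on both strands
bruteForceMmeI <- function(seq) {
  iupacMatch <- function(window, pat) {
    all(mapply(function(w, p) {
      allowed <- switch(p, R = c("A", "G"), p)
      w %in% allowed
    }, strsplit(window, NULL)[[1]], strsplit(pat, NULL)[[1]]))
  }
  rc <- function(x) chartr("ACGT", "TGCA",
                           paste(rev(strsplit(x, NULL)[[1]]), collapse = ""))
  n <- nchar(seq)
  if (n < 6) return(FALSE)
  for (i in 1:(n - 5)) {
    win <- substr(seq, i, i + 5)
    if (iupacMatch(win, "TCCRAC") || iupacMatch(rc(win), "TCCRAC"))
      return(TRUE)
  }
  FALSE
}
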