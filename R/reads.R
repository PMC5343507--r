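#' Detect an MmeI recognition site on either strand
#'
#' The MmeI recognition sequence is TCCRAC (R = A or G); a sequence carries a
#' site if TCCAAC, TCCGAC, or either reverse complement (GTTGGA, GTCGGA)
#' occurs as a substring.
#'
#' @param sequence character vector of nucleotide sequences over A, C, G, T.
#' @return logical vector.
#' @export
containsMmeISite <- function(sequence) {
  sequence <- toupper(sequence)
  if (any(grepl("[^ACGT]", sequence)))
    stop("sequences must contain only A, C, G, T")
  grepl("TCCAAC|TCCGAC|GTTGGA|GTCGGA", sequence)
}

# classify unique inserts against every library window; returns a data.frame
# with status in {WT, variant, ambiguous} and, for variants, the locus
classifyInserts <- function(inserts, design) {
  libs <- unique(design@positions$library)
  ppl <- positionsPerLibrary(design)
  wins <- vapply(libs, function(l) wtInsert(design, l), character(1))
  il <- insertLength(design)
  n <- length(inserts)
  out <- data.frame(status = rep("ambiguous", n),
                    library = rep(NA_integer_, n),
                    position = rep(NA_integer_, n),
                    codon = rep(NA_character_, n),
                    outcome = rep(NA_character_, n),
                    stringsAsFactors = FALSE)
  insMat <- matrix("", length(inserts), il)
  ok <- nchar(inserts) == il
  if (any(ok))
    insMat[ok, ] <- do.call(rbind, strsplit(inserts[ok], NULL))
  for (i in which(ok)) {
    hits <- list()
    for (k in seq_along(libs)) {
      wchars <- strsplit(wins[k], NULL)[[1]]
      mm <- which(insMat[i, ] != wchars)
      if (length(mm) == 0) {
        hits[[length(hits) + 1]] <- list(status = "WT", library = libs[k])
      } else if (all(mm <= 3L * ppl)) {
        cod <- unique((mm - 1L) %/% 3L)  # 0-based codon index in window
        if (length(cod) == 1) {
          pos <- design@positions$position[
            design@positions$library == libs[k] &
              design@positions$withinPos == cod + 1L]
          codon <- substr(inserts[i], 3L * cod + 1L, 3L * cod + 3L)
          hits[[length(hits) + 1]] <- list(
            status = "variant", library = libs[k], position = pos,
            codon = codon, outcome = translateCodon(codon))
        }
      }
    }
    if (length(hits) == 1) {
      h <- hits[[1]]
      out$status[i] <- h$status
      out$library[i] <- h$library
      if (h$status == "variant") {
        out$position[i] <- h$position
        out$codon[i] <- h$codon
        out$outcome[i] <- h$outcome
      }
    }
  }
  out
}

#' Filter and classify reads by the four stringent criteria
#'
#' A read is accepted iff it passes, in fixed order: (1) quality — Phred
#' score of at least `minPhred` at every base; (2) barcode — its leading
#' bases match a known time-stamping barcode; (3) reference — the insert
#' matches a library's wild-type window exactly or differs in exactly one
#' codon of the mutagenized window (anticipated single-codon mutations);
#' (4) MmeI — the insert carries no MmeI recognition site on either strand.
#' The first failing criterion is recorded as the rejection reason.
#'
#' @param reads a [Biostrings::QualityScaledDNAStringSet] (e.g. from
#'   [readFastq()] or [emitReads()]).
#' @param design a [ScanLibraryDesign].
#' @param minPhred minimum acceptable Phred score at every base (default 20,
#'   an error probability of 0.01).
#' @return data.frame with one row per read: `status` (`"pass"` or the
#'   rejection reason `"quality"`, `"barcode"`, `"reference"`, `"mmei"`),
#'   `time`, `library`, `position`, `codon`, `outcome`, `isWT`.
#' @export
filterReads <- function(reads, design, minPhred = 20L) {
  n <- length(reads)
  seqs <- as.character(reads)
  minQ <- min(methods::as(Biostrings::quality(reads), "IntegerList"))
  bl <- barcodeLength(design)
  status <- rep("pass", n)

  status[minQ < minPhred] <- "quality"

  bc <- substr(seqs, 1L, bl)
  bcOK <- bc %in% design@barcodes & nchar(seqs) >= bl
  status[status == "pass" & !bcOK] <- "barcode"

  inserts <- substr(seqs, bl + 1L, nchar(seqs))
  live <- which(status == "pass")
  uin <- unique(inserts[live])
  cls <- classifyInserts(uin, design)
  cls$mmei <- vapply(uin, function(x)
    if (grepl("[^ACGT]", x)) TRUE else containsMmeISite(x), logical(1),
    USE.NAMES = FALSE)
  m <- match(inserts[live], uin)

  refBad <- cls$status[m] == "ambiguous"
  status[live[refBad]] <- "reference"
  live <- live[!refBad]
  m <- m[!refBad]
  status[live[cls$mmei[m]]] <- "mmei"
  live <- live[!cls$mmei[m]]
  m <- m[!cls$mmei[m]]

  res <- data.frame(status = status, time = NA_real_, library = NA_integer_,
                    position = NA_integer_, codon = NA_character_,
                    outcome = NA_character_, isWT = NA,
                    stringsAsFactors = FALSE)
  tmap <- setNames(as.numeric(names(design@barcodes)), design@barcodes)
  res$time[live] <- tmap[bc[live]]
  res$library[live] <- cls$library[m]
  res$position[live] <- cls$position[m]
  res$codon[live] <- cls$codon[m]
  res$outcome[live] <- cls$outcome[m]
  res$isWT[live] <- cls$status[m] == "WT"
  res
}

#' Filter a single read
#'
#' Convenience wrapper around [filterReads()] for one record.
#'
#' @param sequence read sequence (character).
#' @param qualities integer Phred scores, one per base.
#' @param design a [ScanLibraryDesign].
#' @param minPhred quality threshold.
#' @return one-row data.frame as in [filterReads()].
#' @export
filterRead <- function(sequence, qualities, design, minPhred = 20L) {
  if (nchar(sequence) == 0) stop("empty read")
  q <- Biostrings::PhredQuality(
    paste(rawToChar(as.raw(33L + as.integer(qualities))), collapse = ""))
  r <- Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(sequence), q)
  filterReads(r, design, minPhred)
}

#' Tabulate accepted reads into a count time series
#'
#' Aggregates accepted classified reads per `(library, position, codon,
#' time)`; synonymous codons remain distinguishable at the codon level and
#' pool into the same amino-acid outcome class downstream. Reads matching
#' the wild-type reference exactly count as the wild-type reference of their
#' library at every position (one `WT` row per library). Returns the counts
#' together with a filter report whose totals are conserved.
#'
#' @param decisions data.frame from [filterReads()].
#' @param design a [ScanLibraryDesign].
#' @param timepoints times (WT doublings) to tabulate; defaults to the
#'   design's barcode times.
#' @return list with `counts` (a [CountTimeSeries]) and `report` (list:
#'   `total`, `passed`, `rejected` named by reason).
#' @export
tabulateReads <- function(decisions, design,
                          timepoints = as.numeric(names(design@barcodes))) {
  stopifnot(!is.unsorted(timepoints, strictly = TRUE))
  acc <- decisions[decisions$status == "pass", ]
  if (any(!acc$time %in% timepoints))
    stop("internal error: accepted read with unknown barcode time")
  key <- ifelse(acc$isWT, paste0("L", acc$library, ":WT"),
                paste0("L", acc$library, ":", acc$position, ":", acc$codon))
  tab <- table(factor(key), factor(acc$time, levels = timepoints))

  meta <- acc[!duplicated(key), c("library", "position", "codon", "outcome",
                                  "isWT")]
  rownames(meta) <- key[!duplicated(key)]
  meta <- meta[rownames(tab), , drop = FALSE]
  p <- design@positions
  meta$withinPos <- p$withinPos[match(meta$position, p$position)]
  meta$outcome[meta$isWT] <- "WT"

  cm <- matrix(as.integer(tab), nrow(tab), ncol(tab),
               dimnames = list(rownames(tab), paste0("t", seq_along(timepoints))))
  se <- SummarizedExperiment(
    assays = list(counts = cm),
    rowData = DataFrame(meta[c("library", "position", "withinPos", "codon",
                               "outcome", "isWT")], row.names = rownames(cm)),
    colData = DataFrame(time = timepoints,
                        row.names = paste0("t", seq_along(timepoints))))
  metadata(se) <- list(orthologue = design@orthologue)
  report <- filterReport(decisions)
  list(counts = new("CountTimeSeries", se), report = report)
}

#' Summarise filtering decisions
#'
#' @param decisions data.frame from [filterReads()].
#' @return list with `total`, `passed`, and `rejected` (named integer vector
#'   over the reasons quality, barcode, reference, mmei); `passed +
#'   sum(rejected) == total` always holds.
#' @export
filterReport <- function(decisions) {
  reasons <- c("quality", "barcode", "reference", "mmei")
  rej <- vapply(reasons, function(r) sum(decisions$status == r), integer(1))
  list(total = nrow(decisions),
       passed = sum(decisions$status == "pass"),
       rejected = rej)
}

#' Process FASTQ files into counts
#'
#' End-to-end convenience: read FASTQ, filter by the four criteria, classify,
#' and tabulate.
#'
#' @param files FASTQ paths.
#' @param design a [ScanLibraryDesign].
#' @param minPhred quality threshold.
#' @return as [tabulateReads()].
#' @export
processFastq <- function(files, design, minPhred = 20L) {
  dec <- do.call(rbind, lapply(files, function(f)
    filterReads(readFastq(f), design, minPhred)))
  tabulateReads(dec, design)
}

#' Pool codon-level counts into amino-acid outcome classes
#'
#' @param counts a [CountTimeSeries] with codon-level rows.
#' @return matrix-backed list: `counts` (rows = `(library, position,
#'   outcome)`, columns = time points), `rowInfo` data.frame, `wt` matrix of
#'   per-library wild-type reference counts.
#' @export
poolByOutcome <- function(counts) {
  rd <- as.data.frame(rowData(counts))
  cm <- assay(counts, "counts")
  mut <- !rd$isWT & !is.na(rd$position)
  key <- paste0("L", rd$library, ":", rd$position, ":", rd$outcome)[mut]
  pooled <- rowsum(cm[mut, , drop = FALSE], key)
  info <- rd[mut, c("library", "position", "withinPos", "outcome")]
  info <- info[!duplicated(key), ]
  rownames(info) <- key[!duplicated(key)]
  info <- info[rownames(pooled), ]
  wt <- cm[rd$isWT, , drop = FALSE]
  rownames(wt) <- paste0("L", rd$library[rd$isWT], recycle0 = TRUE)
  list(counts = pooled, rowInfo = info, wt = wt)
}
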