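#' Write / read a fitness landscape as tidy TSV
#'
#' The canonical exchange format: one row per `(position, outcome)` cell with
#' columns `orthologue`, `library`, `position`, `within_pos`, `wt_aa`,
#' `outcome`, `w`, `s`, `excluded`.
#'
#' @param landscape a [FitnessLandscape].
#' @param path TSV path.
#' @export
writeLandscapeTsv <- function(landscape, path) {
  info <- positionInfo(landscape)
  long <- expand.grid(position = rownames(landscape),
                      outcome = colnames(landscape),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  i <- match(long$position, rownames(landscape))
  j <- match(long$outcome, colnames(landscape))
  d <- data.frame(
    orthologue = metadata(landscape)$orthologue %||% "orth",
    library = info$library[i],
    position = long$position,
    within_pos = info$withinPos[i],
    wt_aa = info$wtAA[i],
    outcome = long$outcome,
    w = assay(landscape, "w")[cbind(i, j)],
    s = assay(landscape, "s")[cbind(i, j)],
    excluded = exclusionReasons(landscape)[cbind(i, j)])
  d <- d[order(d$library, as.integer(d$position)), ]
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeLandscapeTsv
#' @export
readLandscapeTsv <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE,
                         na.strings = c("NA", ""))
  d$excluded[is.na(d$excluded)] <- ""
  pos <- unique(d$position)
  outs <- unique(d$outcome)
  mk <- function(col, fill) {
    m <- matrix(fill, length(pos), length(outs),
                dimnames = list(pos, outs))
    m[cbind(match(d$position, pos), match(d$outcome, outs))] <- d[[col]]
    m
  }
  first <- d[!duplicated(d$position), ]
  fl <- newFitnessLandscape(
    s = mk("s", NA_real_), w = mk("w", NA_real_),
    library = first$library, withinPos = first$within_pos,
    wtAA = first$wt_aa, positions = pos,
    orthologue = d$orthologue[1],
    excluded = mk("excluded", ""))
  fl
}

#' Write / read a count time series as tidy TSV
#'
#' Columns: `orthologue`, `library`, `position`, `within_pos`, `outcome`,
#' `codon`, `timepoint`, `count` (wild-type reference rows carry outcome
#' `WT` and empty position).
#'
#' @param counts a [CountTimeSeries].
#' @param path TSV path.
#' @export
writeCountsTsv <- function(counts, path) {
  rd <- as.data.frame(rowData(counts))
  cm <- assay(counts, "counts")
  times <- colData(counts)$time
  long <- do.call(rbind, lapply(seq_along(times), function(j)
    data.frame(orthologue = metadata(counts)$orthologue %||% "orth",
               library = rd$library, position = rd$position,
               within_pos = rd$withinPos, outcome = rd$outcome,
               codon = rd$codon, timepoint = times[j], count = cm[, j])))
  utils::write.table(long, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writeCountsTsv
#' @export
readCountsTsv <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE,
                         na.strings = c("NA", ""))
  times <- as.numeric(sort(unique(d$timepoint)))
  d$isWT <- d$outcome == "WT"
  key <- ifelse(d$isWT, paste0("L", d$library, ":WT"),
                paste0("L", d$library, ":", d$position, ":", d$outcome))
  rows <- unique(key)
  cm <- matrix(0L, length(rows), length(times),
               dimnames = list(rows, paste0("t", seq_along(times))))
  cm[cbind(match(key, rows), match(d$timepoint, times))] <- d$count
  first <- d[!duplicated(key), ]
  se <- SummarizedExperiment(
    assays = list(counts = cm),
    rowData = DataFrame(library = first$library, position = first$position,
                        withinPos = first$within_pos, codon = first$codon,
                        outcome = first$outcome, isWT = first$isWT,
                        row.names = rows),
    colData = DataFrame(time = times,
                        row.names = paste0("t", seq_along(times))))
  metadata(se) <- list(orthologue = d$orthologue[1])
  new("CountTimeSeries", se)
}

#' Write a filter report as JSON
#'
#' @param report list from [filterReport()].
#' @param path JSON path.
#' @export
writeFilterReport <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a multiple sequence alignment in FASTA
#'
#' @param path FASTA path.
#' @return a [Biostrings::AAStringSet].
#' @export
readMsaFasta <- function(path) {
  Biostrings::readAAStringSet(path)
}

#' @rdname readMsaFasta
#' @param msa a [Biostrings::AAStringSet].
#' @export
writeMsaFasta <- function(msa, path) {
  Biostrings::writeXStringSet(msa, path)
  invisible(path)
}
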