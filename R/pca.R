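#' Principal component analysis of a mutational-scan matrix
#'
#' PCA of a positions-by-outcomes score matrix (selection coefficients or
#' log-frequencies). Two normalizations are offered: `per_column_center`
#' (default) centers each outcome column, so the first component of a matrix
#' dominated by between-position mean differences is collinear with the
#' average fitness of the position; `per_position_z` standardizes every
#' position (row) to mean 0 and unit s.d. before the column-centered
#' decomposition. Component signs follow a fixed convention: each loading
#' vector sums to a non-negative value.
#'
#' @param m numeric matrix, rows = positions, columns = outcomes; no missing
#'   values (see [imputeRowMean()]).
#' @param normalization `"per_column_center"` or `"per_position_z"`.
#' @return list of class `ScanPCA`: `scores` (rows x components), `loadings`
#'   (columns x components), `varFrac` (variance fractions summing to 1),
#'   `normalization`, `normalized` (the matrix decomposed).
#' @export
scanPCA <- function(m, normalization = c("per_column_center",
                                         "per_position_z")) {
  normalization <- match.arg(normalization)
  m <- as.matrix(m)
  if (anyNA(m)) stop("missing values; impute first (imputeRowMean)")
  if (nrow(m) < 2 || ncol(m) < 2) stop("need at least 2 rows and 2 columns")
  x <- m
  if (normalization == "per_position_z") {
    sds <- apply(x, 1, stats::sd)
    if (any(sds == 0)) stop("constant row(s); per_position_z undefined")
    x <- (x - rowMeans(x)) / sds
  }
  x <- scale(x, center = TRUE, scale = FALSE)
  if (all(abs(x) < 1e-12)) stop("constant matrix: no variance to decompose")
  pc <- stats::prcomp(x, center = FALSE, scale. = FALSE)
  flip <- ifelse(colSums(pc$rotation) < 0, -1, 1)
  scores <- sweep(pc$x, 2, flip, `*`)
  loadings <- sweep(pc$rotation, 2, flip, `*`)
  varFrac <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(scores = scores, loadings = loadings, varFrac = varFrac,
                 normalization = normalization, normalized = x),
            class = "ScanPCA")
}

#' @export
print.ScanPCA <- function(x, ...) {
  cat("ScanPCA (", x$normalization, "): ", nrow(x$scores), " rows, ",
      length(x$varFrac), " components\n", sep = "")
  cat("  variance fractions:",
      paste(sprintf("PC%d %.1f%%", seq_len(min(4, length(x$varFrac))),
                    100 * x$varFrac[seq_len(min(4, length(x$varFrac)))]),
            collapse = ", "), "...\n")
  invisible(x)
}

#' Impute excluded cells by the row mean
#'
#' PCA needs complete matrices; excluded landscape cells are filled with the
#' mean of the remaining values at the same position.
#'
#' @param m numeric matrix with possible `NA`s.
#' @return completed matrix; rows that are entirely `NA` raise an error.
#' @export
imputeRowMean <- function(m) {
  m <- as.matrix(m)
  bad <- which(is.na(m), arr.ind = TRUE)
  if (nrow(bad) == 0) return(m)
  rm <- rowMeans(m, na.rm = TRUE)
  if (anyNA(rm[unique(bad[, 1])]) || any(is.nan(rm[unique(bad[, 1])])))
    stop("row(s) with no observed values cannot be imputed")
  m[bad] <- rm[bad[, 1]]
  m
}

#' Amino-acid log-frequency matrix from an alignment
#'
#' Extracts per-column amino-acid frequencies (gaps excluded) at the library
#' positions, adds a pseudocount, and log-transforms — the evolutionary
#' counterpart of the experimental score matrix, ready for [scanPCA()].
#'
#' @param msa a [Biostrings::AAStringSet] alignment.
#' @param columns alignment column indices of the 80 library positions.
#' @param pseudocount added to each amino-acid count; default
#'   `1 / (nSequences + 20)` of a count, ensuring no `-Inf` entries.
#' @return positions-by-20 matrix of log-frequencies.
#' @export
frequencyMatrix <- function(msa, columns, pseudocount = NULL) {
  m <- msaMatrix(msa)
  if (any(columns > ncol(m) | columns < 1))
    stop("unmapped positions: columns ",
         paste(columns[columns > ncol(m) | columns < 1], collapse = ", "),
         " outside the alignment")
  aa <- AA_CLASSES[-21]
  pseudocount <- pseudocount %||% (1 / (nrow(m) + 20))
  freq <- t(vapply(columns, function(j) {
    col <- m[, j]
    cnt <- table(factor(col[col %in% aa], levels = aa)) + pseudocount
    as.numeric(cnt / sum(cnt))
  }, numeric(20)))
  dimnames(freq) <- list(columns, aa)
  log(freq)
}

#' Correlation of principal-component scores with a position feature
#'
#' Pearson R between the scores of one component and a per-position feature
#' (hydrophobicity, conservation, information content, ASA/RSA, b-factor,
#' ...). When a grouping is given (e.g. orthologue), per-group correlations
#' are reported alongside the pooled value, since pooling across orthologues
#' can change conclusions.
#'
#' @param pca a `ScanPCA` result.
#' @param component component index.
#' @param feature numeric feature on the same positions (pairwise-complete).
#' @param groups optional factor of the same length for per-group values.
#' @return list: `r` (pooled Pearson R), `n`, `byGroup` (named vector, if
#'   grouped).
#' @export
pcFeatureCorrelation <- function(pca, component, feature, groups = NULL) {
  sc <- pca$scores[, component]
  stopifnot(length(feature) == length(sc))
  if (stats::sd(feature, na.rm = TRUE) == 0 || all(is.na(feature))) {
    warning("zero-variance feature: correlation undefined")
    return(list(r = NA_real_, n = sum(!is.na(feature)), byGroup = NULL))
  }
  r <- stats::cor(sc, feature, use = "pairwise.complete.obs")
  byGroup <- NULL
  if (!is.null(groups)) {
    byGroup <- vapply(split(seq_along(sc), groups), function(i) {
      if (length(i) < 3 || stats::sd(feature[i], na.rm = TRUE) %in% c(0, NA))
        return(NA_real_)
      stats::cor(sc[i], feature[i], use = "pairwise.complete.obs")
    }, numeric(1))
  }
  list(r = r, n = sum(stats::complete.cases(sc, feature)), byGroup = byGroup)
}

#' Average a per-position series over the four-fold symmetry
#'
#' Means over the 4 quadrants at each of the 20 four-fold offsets. If a
#' second series is given, also reports the Pearson R between the two
#' averaged series.
#'
#' @param values numeric per-position values.
#' @param library,withinPos the positions' library (1-8) and within-library
#'   index (1-10).
#' @param second optional second per-position series to average and
#'   correlate with.
#' @return list: `offset` (1-20), `mean` (four-fold average), `n` (quadrants
#'   contributing per offset), and with `second`: `mean2`, `r`.
#' @export
fourfoldAverage <- function(values, library, withinPos, second = NULL) {
  ff <- fourfoldIndex(library, withinPos)
  avg <- function(v) {
    tapply(v, factor(ff$offset, levels = 1:20),
           function(x) mean(x, na.rm = TRUE))
  }
  m1 <- avg(values)
  n <- tapply(!is.na(values), factor(ff$offset, levels = 1:20), sum)
  out <- list(offset = 1:20, mean = as.numeric(m1), n = as.integer(n))
  if (!is.null(second)) {
    m2 <- avg(second)
    out$mean2 <- as.numeric(m2)
    out$r <- stats::cor(out$mean, out$mean2, use = "complete.obs")
  }
  out
}
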