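# Preprocessing chain for count matrices: low-count gene filtering,
# median-of-ratios (DESeq-style) size factors, and per-gene truncation of
# extreme values at median + 3 IQR.

#' Remove genes with uniformly low counts
#'
#' Drops genes whose maximum count across samples does not exceed
#' \code{max_threshold} (default 10): such genes show almost no expression.
#' A gene with a single count of 11 is retained; a gene whose largest
#' count is 10 is removed.
#'
#' @param x a \code{\link{count_matrix}}.
#' @param max_threshold genes with \code{max(counts) <= max_threshold}
#'   are removed.
#' @return The filtered \code{count_matrix}, with removed gene ids in
#'   attribute \code{"removed"}.
#' @export
filter_low_counts <- function(x, max_threshold = 10) {
  if (max_threshold < 0) stop_invalid("max_threshold must be >= 0")
  mx <- apply(x$counts, 1, max)
  keep <- mx > max_threshold
  if (!any(keep))
    stop_invalid("all %d genes fall at or below the low-count threshold %g",
                 nrow(x$counts), max_threshold)
  out <- count_matrix(x$counts[keep, , drop = FALSE],
                      x$genes[keep, , drop = FALSE],
                      colnames(x$counts))
  attr(out, "removed") <- x$genes$gene_id[!keep]
  out
}

#' Median-of-ratios size factors
#'
#' Per-sample normalization factors after Anders & Huber: each sample's
#' factor is the median over genes of the ratio of its count to the
#' per-gene geometric mean, using only genes with all-positive counts
#' (the geometric-mean reference is undefined otherwise).
#'
#' @param x a \code{\link{count_matrix}} or a plain counts matrix
#'   (genes x samples).
#' @return Numeric vector of positive per-sample factors, with the
#'   per-gene geometric means of the reference genes as attribute
#'   \code{"reference"}.
#' @export
size_factors <- function(x) {
  counts <- if (inherits(x, "count_matrix")) x$counts else as.matrix(x)
  allpos <- rowSums(counts <= 0) == 0
  if (!any(allpos))
    stop_invalid("normalization failure: no gene has all-positive counts")
  ref <- exp(rowMeans(log(counts[allpos, , drop = FALSE])))
  ratios <- counts[allpos, , drop = FALSE] / ref
  sf <- apply(ratios, 2, stats::median)
  names(sf) <- colnames(counts)
  structure(sf, reference = ref)
}

#' Normalize counts by size factors
#'
#' @param x a \code{\link{count_matrix}} or counts matrix.
#' @param sf size factors; computed by \code{\link{size_factors}} when
#'   missing.
#' @return Numeric matrix of normalized counts (genes x samples).
#' @export
normalize_counts <- function(x, sf = NULL) {
  counts <- if (inherits(x, "count_matrix")) x$counts else as.matrix(x)
  if (is.null(sf)) sf <- size_factors(counts)
  sweep(counts, 2, sf, "/")
}

#' Truncate per-gene extreme values
#'
#' Replaces, gene by gene, every value above \code{median + 3 IQR} by that
#' bound (quartiles by linear interpolation between order statistics,
#' i.e. \code{stats::quantile} type 7).
#'
#' @param x numeric matrix, genes in rows.
#' @return The truncated matrix, with the number of modified entries in
#'   attribute \code{"n_truncated"}.
#' @export
truncate_extremes <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) < 4)
    stop_invalid("truncation needs at least 4 samples per gene")
  med <- apply(x, 1, stats::median)
  q1 <- apply(x, 1, stats::quantile, probs = 0.25, names = FALSE)
  q3 <- apply(x, 1, stats::quantile, probs = 0.75, names = FALSE)
  bound <- med + 3 * (q3 - q1)
  over <- x > bound
  out <- pmin(x, bound)
  attr(out, "n_truncated") <- sum(over)
  out
}

#' Full preprocessing chain
#'
#' Applies the low-count filter, median-of-ratios normalization, and
#' per-gene truncation in order, returning the normalized truncated
#' matrix together with the surviving gene metadata.
#'
#' @param x a \code{\link{count_matrix}}.
#' @param max_threshold low-count filter threshold (see
#'   \code{\link{filter_low_counts}}).
#' @param truncate apply the extreme-value truncation (default TRUE).
#' @return List with \code{x} (normalized matrix, genes x samples),
#'   \code{genes} (metadata of retained genes), \code{size_factors},
#'   \code{removed} (filtered gene ids) and \code{n_truncated}.
#' @export
preprocess_counts <- function(x, max_threshold = 10, truncate = TRUE) {
  filt <- filter_low_counts(x, max_threshold)
  sf <- size_factors(filt)
  norm <- normalize_counts(filt, sf)
  n_trunc <- 0L
  if (truncate) {
    norm <- truncate_extremes(norm)
    n_trunc <- attr(norm, "n_truncated")
  }
  list(x = norm, genes = filt$genes, size_factors = sf,
       removed = attr(filt, "removed"), n_truncated = n_trunc)
}
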