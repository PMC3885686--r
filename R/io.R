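# Plain-text readers/writers for the package's tabular formats: counts and
# transformed matrices as TSV (genes in rows, header = sample ids), gene
# metadata / outcomes / clinical tables as TSV, run manifests as JSON.

#' Write a count matrix and its gene metadata as TSV
#'
#' @param x a \code{\link{count_matrix}}.
#' @param counts_file path of the counts TSV (genes in rows, first column
#'   \code{gene_id}, remaining columns one per sample).
#' @param genes_file optional path of the gene-metadata TSV.
#' @return Invisibly, the counts file path.
#' @export
write_counts_tsv <- function(x, counts_file, genes_file = NULL) {
  df <- data.frame(gene_id = rownames(x$counts), x$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, counts_file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(genes_file))
    utils::write.table(x$genes, genes_file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(counts_file)
}

#' Read a count matrix written by \code{\link{write_counts_tsv}}
#'
#' @param counts_file counts TSV path.
#' @param genes_file optional gene-metadata TSV path; when absent, lengths
#'   default to 1000 bp and moments are estimated from the counts.
#' @return A \code{\link{count_matrix}}.
#' @export
read_counts_tsv <- function(counts_file, genes_file = NULL) {
  df <- utils::read.table(counts_file, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  genes <- if (!is.null(genes_file)) {
    utils::read.table(genes_file, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
  } else {
    data.frame(gene_id = rownames(m), length_bp = 1000L,
               base_mean = pmax(rowMeans(m), 1e-8),
               dispersion = 0, stringsAsFactors = FALSE)
  }
  count_matrix(m, genes, colnames(m))
}

#' Write a count matrix in MatrixMarket form with id side files
#'
#' @param x a \code{\link{count_matrix}}.
#' @param mtx_file path of the \code{.mtx} file; gene and sample ids are
#'   written next to it as \code{<stem>.genes.txt} / \code{<stem>.samples.txt}.
#' @return Invisibly, the mtx path.
#' @export
write_counts_mtx <- function(x, mtx_file) {
  if (!requireNamespace("Matrix", quietly = TRUE))
    stop_invalid("the Matrix package is required for MatrixMarket output")
  Matrix::writeMM(Matrix::Matrix(x$counts, sparse = TRUE), mtx_file)
  stem <- sub("\\.mtx$", "", mtx_file)
  writeLines(rownames(x$counts), paste0(stem, ".genes.txt"))
  writeLines(colnames(x$counts), paste0(stem, ".samples.txt"))
  invisible(mtx_file)
}

#' Write a run manifest as JSON
#'
#' Records seeds, parameters, and the package's numerical conventions
#' (SNR definition, quantile type, SD denominator, Blom constant, ...) so
#' a run can be reproduced and its conventions audited.
#'
#' @param params named list of run parameters.
#' @param path output JSON path.
#' @return Invisibly, the path.
#' @export
write_manifest <- function(params, path) {
  conventions <- list(
    snr_definition = "latent scale: var(eta) / (pi^2/3); alternative: var(eta) / mean(pi*(1-pi))",
    quantile_type = 7L,
    sd_denominator = "n - 1",
    blom_constant = 0.375,
    boxcox_shift = 1,
    boxcox_grid = seq(-2, 2, by = 0.25),
    tie_noise = "sd = 1e-4 * (gene IQR + 1), applied pre-rank when ties exist",
    vst = "w(x) = (2/sqrt(alpha)) * asinh(sqrt(alpha * x)), alpha from moment regression",
    penalty_from_nu = "lambda = (1/nu - 1) * sum of working weights at null fit",
    ipcw = "Kaplan-Meier censoring distribution on training data, floor 1e-3",
    baseline_hazard = "Breslow estimator on training data",
    ipec_upper_limit = "0.95 quantile of observed times",
    added_value = "1 - IPEC_combined / IPEC_clinical")
  jsonlite::write_json(list(parameters = params, conventions = conventions),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write per-sample outcome tables as TSV
#'
#' @param sample_ids character vector of sample ids.
#' @param outcome list with either \code{y} (binary) or \code{time} and
#'   \code{event} (survival).
#' @param path output TSV path.
#' @return Invisibly, the path.
#' @export
write_outcome_tsv <- function(sample_ids, outcome, path) {
  df <- if (!is.null(outcome$y))
    data.frame(sample_id = sample_ids, y = outcome$y)
  else
    data.frame(sample_id = sample_ids, time = outcome$time,
               event = outcome$event)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
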