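#' Convert methylation beta values to M values
#'
#' The M value is the logit2 of the beta value, `log2(beta / (1 - beta))`.
#' Betas are clamped into `[eps, 1 - eps]` first so that boundary values 0
#' and 1 map to large finite M values rather than infinities.
#'
#' @param beta Numeric vector (or matrix) of beta values in \[0, 1\].
#' @param eps Clamping margin, must lie in (0, 0.5). Default `1e-6`.
#' @return Object of the same shape as `beta`, on the M scale.
#' @seealso [m_to_beta()]
#' @export
#' @examples
#' beta_to_m(c(0.5, 0.8)) # 0, 2
beta_to_m <- function(beta, eps = 1e-6) {
  stopifnot(is.numeric(beta), eps > 0, eps < 0.5)
  if (any(beta < 0 | beta > 1, na.rm = TRUE)) {
    stop("beta values must lie in [0, 1]")
  }
  b <- pmin(pmax(beta, eps), 1 - eps)
  log2(b / (1 - b))
}

#' Convert M values back to beta values
#'
#' Inverse of [beta_to_m()]: `2^m / (2^m + 1)`. Always strictly inside (0, 1)
#' for finite input.
#'
#' @param m Numeric vector or matrix of M values.
#' @return Beta values in (0, 1).
#' @export
m_to_beta <- function(m) {
  stopifnot(is.numeric(m))
  # equivalent to 2^m/(2^m+1) but stable for large |m|
  1 / (1 + 2^(-m))
}

#' Quantile-normalize the columns of a matrix
#'
#' Forces every sample (column) onto the same empirical distribution: the
#' reference distribution is the row-wise mean of the column-sorted matrix,
#' and ties within a column receive the mean of their reference quantiles.
#'
#' @param x Numeric matrix with at least 2 columns and finite entries.
#' @return Matrix of the same dimensions (and dimnames) with normalized
#'   columns.
#' @export
quantile_normalize <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) < 2) stop("quantile normalization needs at least 2 columns")
  if (!all(is.finite(x))) stop("non-finite entries in matrix")
  out <- limma::normalizeQuantiles(x, ties = TRUE)
  dimnames(out) <- dimnames(x)
  out
}

#' Average probe- or CpG-level rows into gene-level rows
#'
#' Each gene's row is the unweighted mean, per sample, of the rows mapped to
#' it. Features mapping to several genes contribute to every target gene's
#' average (a warning reports how many). Genes with no mapped feature are
#' absent from the output.
#'
#' @param x Numeric matrix with feature ids as rownames.
#' @param mapping Data frame with columns `feature_id` and `gene_id`; one row
#'   per (feature, gene) pair.
#' @return Numeric matrix, rows = genes (sorted), columns as in `x`.
#' @export
aggregate_to_gene <- function(x, mapping) {
  x <- as.matrix(x)
  stopifnot(!is.null(rownames(x)),
            all(c("feature_id", "gene_id") %in% names(mapping)))
  mapping <- mapping[mapping$feature_id %in% rownames(x), , drop = FALSE]
  if (nrow(mapping) == 0L) stop("no mapped features present in matrix")
  multi <- unique(mapping$feature_id[duplicated(mapping$feature_id)])
  if (length(multi) > 0L) {
    warning(sprintf("%d feature(s) map to multiple genes; included in every target gene's average",
                    length(multi)))
  }
  sub <- x[mapping$feature_id, , drop = FALSE]
  sums <- rowsum(sub, group = mapping$gene_id)
  counts <- as.vector(table(mapping$gene_id)[rownames(sums)])
  out <- sums / counts
  out[order(rownames(out)), , drop = FALSE]
}

#' Intersect the gene sets of several gene-level matrices
#'
#' Keeps only genes present in every dataset and filters each matrix down to
#' that sorted common list, so downstream correlation tables are comparable
#' across cohorts.
#'
#' @param datasets Named or unnamed list of matrices with gene rownames.
#' @return List with `genes` (sorted character vector) and `datasets` (the
#'   input matrices subset and row-ordered to `genes`).
#' @export
intersect_genes <- function(datasets) {
  stopifnot(is.list(datasets), length(datasets) >= 1L)
  common <- Reduce(intersect, lapply(datasets, rownames))
  if (length(common) == 0L) stop("empty gene intersection across datasets")
  common <- sort(common)
  list(genes = common,
       datasets = lapply(datasets, function(m) m[common, , drop = FALSE]))
}

#' Robust coefficient of variation (IQR / median)
#'
#' A robust CV replacing the standard deviation with the interquartile range
#' and the mean with the median: `100 * IQR(x) / median(x)`. Quartiles use
#' linear interpolation between order statistics (type 7).
#'
#' @param values Numeric vector of length >= 4 with non-zero median.
#' @return The robust CV in percent.
#' @export
robust_cv <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 4L) stop("robust_cv needs at least 4 values")
  med <- stats::median(values)
  if (med == 0) stop("robust_cv undefined: median is zero")
  100 * stats::IQR(values, type = 7) / med
}

# ---- tabular I/O -----------------------------------------------------------

#' Read a feature-by-sample matrix from TSV
#'
#' Expects a tab-delimited file with a header of sample ids and the feature
#' id in the first column.
#'
#' @param path File path.
#' @return Numeric matrix with feature rownames and sample colnames.
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' Write a feature-by-sample matrix as TSV
#'
#' @param x Matrix with rownames (feature ids) and colnames (sample ids).
#' @param path Output file path.
#' @param id_col Name for the first (feature id) column.
#' @export
write_matrix_tsv <- function(x, path, id_col = "feature_id") {
  df <- data.frame(rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read/write a plain data frame as TSV
#'
#' Thin wrappers used for annotation, group and truth tables.
#' @param path File path.
#' @export
read_table_tsv <- function(path) {
  utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
}

#' @rdname read_table_tsv
#' @param df Data frame to write.
#' @export
write_table_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write BED intervals (0-based, half-open)
#'
#' Minimal BED3+name support for segment sets used by the overlap tests.
#' Columns map to `chrom`, `start` (0-based), `end` (exclusive) and, when
#' present, `label`.
#'
#' @param path File path.
#' @return Data frame with columns chrom, start, end and optionally label.
#' @export
read_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  names(df)[1:3] <- c("chrom", "start", "end")
  if (ncol(df) >= 4) names(df)[4] <- "label"
  df
}

#' @rdname read_bed
#' @param segments Data frame with chrom, start, end and optionally label.
#' @export
write_bed <- function(segments, path) {
  cols <- intersect(c("chrom", "start", "end", "label"), names(segments))
  utils::write.table(segments[, cols, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Preprocess a methylation matrix for correlation analysis
#'
#' Runs the standard normalization path: beta to M conversion (if needed),
#' then quantile normalization across all samples of the dataset jointly
#' (tumor and normal together) or separately per group.
#'
#' @param meth Matrix of methylation values (CpGs x samples).
#' @param scale Either `"beta"` (values converted to M first) or `"m"`.
#' @param groups Optional data frame (`sample_id`, `group`) used only when
#'   `joint = FALSE`.
#' @param joint Normalize all samples together (default) or per group.
#' @param eps Beta clamping margin passed to [beta_to_m()].
#' @return Matrix on the M scale, quantile normalized.
#' @export
preprocess_methylation <- function(meth, scale = c("beta", "m"),
                                   groups = NULL, joint = TRUE, eps = 1e-6) {
  scale <- match.arg(scale)
  m <- if (scale == "beta") beta_to_m(meth, eps = eps) else as.matrix(meth)
  if (joint || is.null(groups)) {
    quantile_normalize(m)
  } else {
    out <- m
    for (g in unique(groups$group)) {
      ids <- intersect(colnames(m), groups$sample_id[groups$group == g])
      out[, ids] <- quantile_normalize(m[, ids, drop = FALSE])
    }
    out
  }
}
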