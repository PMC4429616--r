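#' Correlation between two vectors
#'
#' Pearson product-moment or Spearman rank correlation (average ranks for
#' ties). Degenerate (constant) vectors yield `NA` rather than an error so
#' callers can flag and exclude the record.
#'
#' @param x,y Numeric vectors of equal length >= 4.
#' @param method `"pearson"` or `"spearman"`.
#' @return Correlation in \[-1, 1\], or `NA` if either vector is constant.
#' @export
correlate <- function(x, y, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  stopifnot(length(x) == length(y), length(x) >= 4)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y, method = method)
}

#' Fisher z-transform of a correlation
#'
#' `atanh(rho)` after clamping `|rho|` to `clamp`, so perfect correlations
#' map to large finite z values. On the z scale correlation estimates are
#' approximately normal with variance `1/(n-3)`.
#'
#' @param rho Correlation(s) in \[-1, 1\].
#' @param clamp Clamping bound, strictly below 1. Default `0.999999`.
#' @return z value(s).
#' @export
fisher_z <- function(rho, clamp = 0.999999) {
  stopifnot(clamp > 0, clamp < 1)
  atanh(pmin(pmax(rho, -clamp), clamp))
}

# Row-wise average ranks of a matrix (ties get the mean rank). O(ncol^2)
# vectorized column comparisons: fast for the short sample dimension used
# here, and much faster than apply(., 1, rank) inside resampling loops.
.row_ranks <- function(m) {
  n <- ncol(m)
  r <- matrix(1, nrow(m), n)
  for (j in seq_len(n)) {
    xj <- m[, j]
    for (k in seq_len(n)) {
      if (k == j) next
      xk <- m[, k]
      r[, j] <- r[, j] + (xk < xj) + 0.5 * (xk == xj)
    }
  }
  dimnames(r) <- dimnames(m)
  r
}

# Row-wise correlation between two conformable matrices (samples in
# columns). Spearman = Pearson on row ranks. Constant rows yield NA.
.row_correlations <- function(a, b, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  stopifnot(all(dim(a) == dim(b)))
  if (method == "spearman") {
    a <- .row_ranks(a)
    b <- .row_ranks(b)
  }
  n <- ncol(a)
  a <- a - rowMeans(a)
  b <- b - rowMeans(b)
  sa <- sqrt(rowSums(a^2))
  sb <- sqrt(rowSums(b^2))
  r <- rowSums(a * b) / (sa * sb)
  r[sa == 0 | sb == 0] <- NA_real_
  pmin(pmax(r, -1), 1)
}

# Split sample ids by group, validated against the matrices involved.
.group_samples <- function(samples, groups) {
  stopifnot(all(c("sample_id", "group") %in% names(groups)))
  groups <- groups[groups$sample_id %in% samples, , drop = FALSE]
  normal <- groups$sample_id[groups$group == "normal"]
  tumor <- groups$sample_id[groups$group == "tumor"]
  if (length(normal) == 0 || length(tumor) == 0) {
    stop("both tumor and normal groups must be present among the samples")
  }
  list(normal = normal, tumor = tumor)
}

#' Per-gene methylation-expression correlations in each group
#'
#' For every gene present in both matrices, computes the correlation of
#' gene-averaged methylation with expression across samples, separately in
#' tumor and normal groups, together with Fisher z values and per-group
#' sample sizes. Genes whose expression or methylation is constant in
#' either group are excluded (a message reports how many).
#'
#' @param expr Gene-level expression matrix (genes x samples).
#' @param meth_gene Gene-level methylation matrix, samples as in `expr`.
#' @param groups Data frame with `sample_id` and `group` (tumor/normal).
#' @param method Correlation method, Spearman by default.
#' @return Data frame with gene_id, rho_normal, rho_tumor, n_normal,
#'   n_tumor, z_normal, z_tumor, method.
#' @export
gene_correlations <- function(expr, meth_gene, groups,
                              method = c("spearman", "pearson")) {
  method <- match.arg(method)
  genes <- intersect(rownames(expr), rownames(meth_gene))
  if (length(genes) == 0L) stop("no genes shared by expression and methylation")
  samples <- intersect(colnames(expr), colnames(meth_gene))
  gs <- .group_samples(samples, groups)
  if (length(gs$normal) < 4 || length(gs$tumor) < 4) {
    stop("each group needs at least 4 samples")
  }
  e <- expr[genes, , drop = FALSE]
  m <- meth_gene[genes, , drop = FALSE]
  rho_n <- .row_correlations(m[, gs$normal, drop = FALSE],
                             e[, gs$normal, drop = FALSE], method)
  rho_t <- .row_correlations(m[, gs$tumor, drop = FALSE],
                             e[, gs$tumor, drop = FALSE], method)
  out <- data.frame(gene_id = genes,
                    rho_normal = rho_n, rho_tumor = rho_t,
                    n_normal = length(gs$normal), n_tumor = length(gs$tumor),
                    z_normal = fisher_z(rho_n), z_tumor = fisher_z(rho_t),
                    method = method, stringsAsFactors = FALSE,
                    row.names = NULL)
  bad <- is.na(out$rho_normal) | is.na(out$rho_tumor)
  if (any(bad)) {
    message(sprintf("excluding %d gene(s) with undefined correlation", sum(bad)))
    out <- out[!bad, , drop = FALSE]
  }
  out
}

#' Per-CpG methylation vs gene-expression correlations in each group
#'
#' Each CpG is correlated with the expression of its annotated gene,
#' separately per group. The returned table carries the absolute TSS
#' distance and CpG position so downstream distance-stratified analyses
#' (GAM, Mantel) can consume it directly.
#'
#' @param expr Gene-level expression matrix.
#' @param meth_cpg CpG-level methylation matrix (M or beta scale).
#' @param annot CpG annotation with cpg_id, gene_id, pos, abs_tss_dist.
#' @param groups Sample-group table.
#' @param method Correlation method, Spearman by default.
#' @return Data frame with cpg_id, gene_id, pos, abs_tss_dist, rho_normal,
#'   rho_tumor, n_normal, n_tumor, z_normal, z_tumor, method.
#' @export
cpg_correlations <- function(expr, meth_cpg, annot, groups,
                             method = c("spearman", "pearson")) {
  method <- match.arg(method)
  stopifnot(all(c("cpg_id", "gene_id", "abs_tss_dist") %in% names(annot)))
  annot <- annot[annot$cpg_id %in% rownames(meth_cpg) &
                   annot$gene_id %in% rownames(expr), , drop = FALSE]
  if (nrow(annot) == 0L) stop("no annotated CpGs match the matrices")
  samples <- intersect(colnames(expr), colnames(meth_cpg))
  gs <- .group_samples(samples, groups)
  if (length(gs$normal) < 4 || length(gs$tumor) < 4) {
    stop("each group needs at least 4 samples")
  }
  m <- meth_cpg[annot$cpg_id, , drop = FALSE]
  e <- expr[annot$gene_id, , drop = FALSE]
  rho_n <- .row_correlations(m[, gs$normal, drop = FALSE],
                             e[, gs$normal, drop = FALSE], method)
  rho_t <- .row_correlations(m[, gs$tumor, drop = FALSE],
                             e[, gs$tumor, drop = FALSE], method)
  out <- data.frame(cpg_id = annot$cpg_id, gene_id = annot$gene_id,
                    pos = if ("pos" %in% names(annot)) annot$pos else NA_integer_,
                    abs_tss_dist = annot$abs_tss_dist,
                    rho_normal = rho_n, rho_tumor = rho_t,
                    n_normal = length(gs$normal), n_tumor = length(gs$tumor),
                    z_normal = fisher_z(rho_n), z_tumor = fisher_z(rho_t),
                    method = method, stringsAsFactors = FALSE,
                    row.names = NULL)
  bad <- is.na(out$rho_normal) | is.na(out$rho_tumor)
  if (any(bad)) {
    message(sprintf("excluding %d CpG(s) with undefined correlation", sum(bad)))
    out <- out[!bad, , drop = FALSE]
  }
  out
}
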