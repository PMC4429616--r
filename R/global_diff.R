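#' Paired Wilcoxon signed-rank test with Hodges-Lehmann estimate
#'
#' Two-sided by default; exact when the number of non-zero differences is at
#' most 25 and there are no tied absolute differences, otherwise the normal
#' approximation with continuity correction. The location estimate is the
#' Hodges-Lehmann pseudomedian of the differences `x - y`, with a 95% CI.
#' If all differences are zero the test is degenerate: p = 1, estimate 0.
#'
#' @param x,y Paired numeric vectors; `y` may be omitted to test a single
#'   sample of differences against zero.
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`.
#' @param conf_int Compute the Hodges-Lehmann estimate and CI (default TRUE).
#' @return List with `estimate`, `p`, `ci` (length-2), `n` (non-zero pairs).
#' @export
wilcoxon_signed_rank <- function(x, y = NULL, alternative = "two.sided",
                                 conf_int = TRUE) {
  d <- if (is.null(y)) x else x - y
  d <- d[!is.na(d)]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    return(list(estimate = 0, p = 1, ci = c(0, 0), n = 0L))
  }
  exact <- n <= 25 && !any(duplicated(abs(d)))
  wt <- suppressWarnings(stats::wilcox.test(
    d, alternative = alternative, exact = exact, correct = TRUE,
    conf.int = conf_int, conf.level = 0.95))
  list(estimate = if (conf_int) unname(wt$estimate) else NA_real_,
       p = wt$p.value,
       ci = if (conf_int) unname(wt$conf.int) else c(NA_real_, NA_real_),
       n = n)
}

#' Genome-wide signed correlation comparison
#'
#' Paired Wilcoxon signed-rank test of per-gene correlations, normal minus
#' tumor, across all genes of one dataset.
#'
#' @param records Output of [gene_correlations()].
#' @return One-row data frame in the [global_comparison()] layout with
#'   `mode = "signed"`, `n_reps = 1`.
#' @export
global_signed_comparison <- function(records) {
  wt <- wilcoxon_signed_rank(records$rho_normal, records$rho_tumor)
  data.frame(method = records$method[1], mode = "signed",
             estimate = wt$estimate, ci_lo = wt$ci[1], ci_hi = wt$ci[2],
             p_value = wt$p, n_reps = 1L, n_genes = nrow(records),
             stringsAsFactors = FALSE)
}

#' Genome-wide absolute correlation comparison with subsampling
#'
#' Compares per-gene absolute correlations between groups. Unequal group
#' sizes bias absolute correlations (the larger group's estimates are less
#' noisy), so the larger group is repeatedly subsampled without replacement
#' to the smaller group's size, per-gene correlations are recomputed on each
#' subsample, and the paired Wilcoxon signed-rank test on
#' `|rho_normal| - |rho_tumor|` is run per replicate. The reported p and
#' estimate are the means over replicates (medians are also returned).
#' With equal group sizes the machinery collapses to a single direct test
#' on the full data, bit-identical to [wilcoxon_signed_rank()] on the
#' absolute correlation pairs.
#'
#' @param expr Gene-level expression matrix.
#' @param meth_gene Gene-level methylation matrix (analysis scale).
#' @param groups Sample-group table.
#' @param method Correlation method.
#' @param n_reps Number of subsampling replicates (1000 in full runs).
#' @param seed Integer seed for the subsampling.
#' @return One-row data frame as in [global_signed_comparison()] with
#'   `mode = "absolute"` and additionally `p_median`.
#' @export
subsampled_abs_comparison <- function(expr, meth_gene, groups,
                                      method = c("spearman", "pearson"),
                                      n_reps = 1000L, seed = 1L) {
  method <- match.arg(method)
  stopifnot(n_reps >= 1)
  samples <- intersect(colnames(expr), colnames(meth_gene))
  gs <- .group_samples(samples, groups)
  recs <- gene_correlations(expr, meth_gene, groups, method)
  if (length(gs$normal) == length(gs$tumor)) {
    wt <- wilcoxon_signed_rank(abs(recs$rho_normal), abs(recs$rho_tumor))
    return(data.frame(method = method, mode = "absolute",
                      estimate = wt$estimate, ci_lo = wt$ci[1],
                      ci_hi = wt$ci[2], p_value = wt$p, p_median = wt$p,
                      n_reps = 1L, n_genes = nrow(recs),
                      stringsAsFactors = FALSE))
  }
  small_is_normal <- length(gs$normal) < length(gs$tumor)
  big <- if (small_is_normal) gs$tumor else gs$normal
  small <- if (small_is_normal) gs$normal else gs$tumor
  genes <- recs$gene_id
  e_big <- expr[genes, big, drop = FALSE]
  m_big <- meth_gene[genes, big, drop = FALSE]
  rho_small <- if (small_is_normal) recs$rho_normal else recs$rho_tumor

  set.seed(seed)
  ps <- est <- lo <- hi <- numeric(n_reps)
  for (r in seq_len(n_reps)) {
    idx <- sample.int(length(big), length(small))
    rho_sub <- .row_correlations(m_big[, idx, drop = FALSE],
                                 e_big[, idx, drop = FALSE], method)
    keep <- !is.na(rho_sub)
    # orientation: normal - tumor, as in the signed comparison
    if (small_is_normal) {
      wt <- wilcoxon_signed_rank(abs(rho_small[keep]), abs(rho_sub[keep]))
    } else {
      wt <- wilcoxon_signed_rank(abs(rho_sub[keep]), abs(rho_small[keep]))
    }
    ps[r] <- wt$p; est[r] <- wt$estimate; lo[r] <- wt$ci[1]; hi[r] <- wt$ci[2]
  }
  data.frame(method = method, mode = "absolute",
             estimate = mean(est), ci_lo = mean(lo), ci_hi = mean(hi),
             p_value = mean(ps), p_median = stats::median(ps),
             n_reps = as.integer(n_reps), n_genes = nrow(recs),
             stringsAsFactors = FALSE)
}

#' Full genome-wide comparison table for one dataset
#'
#' Runs the signed and absolute comparisons for Pearson and Spearman
#' correlations, mirroring the per-dataset layout of the study's
#' genome-wide results table.
#'
#' @inheritParams subsampled_abs_comparison
#' @param methods Correlation methods to run.
#' @return Data frame with one row per (method, mode).
#' @export
global_comparison <- function(expr, meth_gene, groups,
                              methods = c("pearson", "spearman"),
                              n_reps = 1000L, seed = 1L) {
  rows <- lapply(methods, function(me) {
    signed <- global_signed_comparison(
      gene_correlations(expr, meth_gene, groups, me))
    absr <- subsampled_abs_comparison(expr, meth_gene, groups, me,
                                      n_reps = n_reps, seed = seed)
    absr$p_median <- NULL
    rbind(signed, absr)
  })
  do.call(rbind, rows)
}

#' Benjamini-Hochberg q-values across datasets
#'
#' Step-up FDR adjustment applied to a vector of per-dataset p-values.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return q-values, same length and order as `p`.
#' @export
fdr_across_datasets <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  stats::p.adjust(p, method = "BH")
}
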