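#' Per-feature, per-group descriptive summaries
#'
#' Mean, standard deviation (denominator n-1) and robust CV
#' ([robust_cv()], IQR/median) for every feature in each group, optionally
#' stratified into promoter (< 1 kb absolute TSS distance) and non-promoter
#' CpGs. For methylation the matrix should be on the beta scale, the scale
#' robust CVs are conventionally reported on.
#'
#' @param x Feature-by-sample matrix.
#' @param groups Sample-group table.
#' @param annot Optional CpG annotation (needed when `stratify = TRUE`).
#' @param stratify Add a promoter/non-promoter stratum column.
#' @param promoter_bp Promoter boundary on absolute TSS distance (bp).
#' @return Data frame: feature_id, group, n, mean, sd, cv_iqr, stratum.
#' @export
summarize_features <- function(x, groups, annot = NULL, stratify = FALSE,
                               promoter_bp = 1000) {
  samples <- intersect(colnames(x), groups$sample_id)
  gs <- .group_samples(samples, groups)
  per_group <- function(gname) {
    sub <- x[, gs[[gname]], drop = FALSE]
    n <- ncol(sub)
    if (n < 2) warning(sprintf("group %s has n < 2: SD undefined", gname))
    mu <- rowMeans(sub)
    sdv <- sqrt(rowSums((sub - mu)^2) / (n - 1))
    cv <- apply(sub, 1, function(v) {
      med <- stats::median(v)
      if (med == 0) NA_real_ else 100 * stats::IQR(v, type = 7) / med
    })
    data.frame(feature_id = rownames(x), group = gname, n = n,
               mean = mu, sd = sdv, cv_iqr = cv,
               stringsAsFactors = FALSE, row.names = NULL)
  }
  out <- rbind(per_group("normal"), per_group("tumor"))
  if (stratify) {
    stopifnot(!is.null(annot), "abs_tss_dist" %in% names(annot))
    dist <- annot$abs_tss_dist[match(out$feature_id, annot$cpg_id)]
    out$stratum <- ifelse(is.na(dist), NA_character_,
                          ifelse(dist < promoter_bp, "promoter",
                                 "non_promoter"))
  } else {
    out$stratum <- "all"
  }
  out
}

#' Compare two sets of per-feature values
#'
#' Paired features (the same CpGs or genes in tumor vs normal) are compared
#' by the Wilcoxon signed-rank test; disjoint sets (e.g. a called gene set
#' vs background) by the two-sample rank-sum test. Both report the
#' Hodges-Lehmann location estimate with a 95% CI.
#'
#' @param a,b Numeric vectors; equal length required when `paired = TRUE`.
#' @param paired Use the signed-rank test on a - b.
#' @return Data frame row: test, estimate, ci_lo, ci_hi, p.
#' @export
compare_sets <- function(a, b, paired = FALSE) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) == 0 || length(b) == 0) stop("empty set in comparison")
  if (paired) {
    stopifnot(length(a) == length(b))
    wt <- wilcoxon_signed_rank(a, b)
    data.frame(test = "wilcoxon_signed", estimate = wt$estimate,
               ci_lo = wt$ci[1], ci_hi = wt$ci[2], p = wt$p,
               stringsAsFactors = FALSE)
  } else {
    exact <- length(a) <= 25 && length(b) <= 25 &&
      !any(duplicated(c(a, b)))
    wt <- suppressWarnings(stats::wilcox.test(a, b, conf.int = TRUE,
                                              exact = exact))
    data.frame(test = "wilcoxon_ranksum", estimate = unname(wt$estimate),
               ci_lo = wt$conf.int[1], ci_hi = wt$conf.int[2],
               p = wt$p.value, stringsAsFactors = FALSE)
  }
}

#' Compare a per-gene covariate between a called set and the background
#'
#' Rank-sum comparison of a covariate (GC content, CpG count, expression
#' level, ...) between a called gene set and the remaining background.
#' Genes in the called set are removed from the background first (a
#' message reports how many overlapped).
#'
#' @param gene_set Character vector of called gene ids.
#' @param background Character vector of background gene ids.
#' @param covariate Named numeric vector (names = gene ids).
#' @return Data frame row as in [compare_sets()].
#' @export
compare_covariates <- function(gene_set, background, covariate) {
  overlap <- intersect(gene_set, background)
  if (length(overlap) > 0) {
    message(sprintf("removing %d called gene(s) from background", length(overlap)))
    background <- setdiff(background, gene_set)
  }
  a <- covariate[intersect(gene_set, names(covariate))]
  b <- covariate[intersect(background, names(covariate))]
  if (length(a) == 0 || length(b) == 0) stop("covariate missing for a set")
  if (stats::sd(c(a, b)) == 0) {
    return(data.frame(test = "wilcoxon_ranksum", estimate = 0,
                      ci_lo = 0, ci_hi = 0, p = 1, stringsAsFactors = FALSE))
  }
  compare_sets(a, b, paired = FALSE)
}

#' Diagnostic: do gene-level p-values track CpG coverage?
#'
#' Spearman correlation of `-log10(p_two_sided)` with the number of CpGs
#' per gene, overall and per direction. A combination that merely
#' accumulates evidence with coverage would show a positive correlation
#' here.
#'
#' @param dcg_results [call_dcgs()] output.
#' @return Data frame: direction, spearman_rho, p_value, n_genes.
#' @export
pval_cpg_count_diagnostic <- function(dcg_results) {
  one <- function(df, lab) {
    if (nrow(df) < 4 || stats::sd(df$n_cpgs) == 0) {
      return(data.frame(direction = lab, spearman_rho = NA_real_,
                        p_value = NA_real_, n_genes = nrow(df),
                        stringsAsFactors = FALSE))
    }
    ct <- suppressWarnings(stats::cor.test(-log10(pmax(df$p_two_sided, 1e-300)),
                                           df$n_cpgs, method = "spearman"))
    data.frame(direction = lab, spearman_rho = unname(ct$estimate),
               p_value = ct$p.value, n_genes = nrow(df),
               stringsAsFactors = FALSE)
  }
  rbind(one(dcg_results, "all"),
        one(dcg_results[dcg_results$direction == "pos_in_cancer", ], "pos_in_cancer"),
        one(dcg_results[dcg_results$direction == "neg_in_cancer", ], "neg_in_cancer"))
}
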