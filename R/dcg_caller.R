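#' Fisher z-test for the difference between two correlations
#'
#' Tests `H0: rho1 = rho2` from two independent samples via the Fisher
#' transform: `z = (atanh(rho1) - atanh(rho2)) / sqrt(1/(n1-3) + 1/(n2-3))`
#' referred to the standard normal. With `spearman_var = TRUE` the variance
#' term uses `1.06/(n-3)`, the classical adjustment for Spearman
#' correlations.
#'
#' @param rho1,rho2 Correlations (clamped via [fisher_z()]).
#' @param n1,n2 Sample sizes (>= 4).
#' @param spearman_var Use the 1.06/(n-3) variance variant. Default FALSE.
#' @return List with `z_stat`, `p_two`, `p_greater` (H1: rho1 > rho2) and
#'   `p_less`.
#' @export
#' @examples
#' # a strongly discordant gene: rho 0.25 in one group, -0.66 in the other
#' fisher_corr_diff_test(0.25, 57, -0.66, 57)
fisher_corr_diff_test <- function(rho1, n1, rho2, n2, spearman_var = FALSE) {
  stopifnot(n1 >= 4, n2 >= 4)
  k <- if (spearman_var) 1.06 else 1
  se <- sqrt(k / (n1 - 3) + k / (n2 - 3))
  z <- (fisher_z(rho1) - fisher_z(rho2)) / se
  list(z_stat = z,
       p_two = 2 * stats::pnorm(-abs(z)),
       p_greater = stats::pnorm(z, lower.tail = FALSE),
       p_less = stats::pnorm(z))
}

#' Stouffer combination of one-tailed p-values
#'
#' Meta-analytic pooling: `Z = sum(qnorm(1 - p_i)) / sqrt(k)`, returned as
#' `1 - pnorm(Z)`. Unweighted. Sensitive to consistent departures from the
#' null (in contrast to Fisher's product method, which reacts to occasional
#' extreme components). Boundary p-values are clamped into
#' `[1e-300, 1 - 1e-16]` with a warning.
#'
#' @param p Vector of one-tailed p-values in (0, 1), length >= 1.
#' @return Combined one-tailed p-value.
#' @export
stouffer_combine <- function(p) {
  stopifnot(length(p) >= 1, all(!is.na(p)))
  if (any(p <= 0 | p >= 1)) {
    warning("p-values at 0 or 1 clamped before Stouffer combination")
    p <- pmin(pmax(p, 1e-300), 1 - 1e-16)
  }
  z <- sum(stats::qnorm(p, lower.tail = FALSE)) / sqrt(length(p))
  stats::pnorm(z, lower.tail = FALSE)
}

#' Call differentially correlated genes
#'
#' Two modes matching the two array designs:
#' \describe{
#'   \item{`single_corr`}{one correlation per gene and group (gene-averaged
#'     methylation, 27K-style): one Fisher z-test per gene.}
#'   \item{`stouffer`}{many CpGs per gene (450K-style): per CpG, one-tailed
#'     Fisher p-values in both directions; per gene, each direction's
#'     p-vector is Stouffer-combined, the gene-level two-sided p is
#'     `min(1, 2 * min(tails))` and the direction is the smaller tail.}
#' }
#' For a single-CpG gene the two modes coincide exactly. BH q-values and
#' Bonferroni-adjusted p-values are computed across all tested genes.
#'
#' @param records [gene_correlations()] output (`single_corr`) or
#'   [cpg_correlations()] output (`stouffer`).
#' @param mode `"single_corr"` or `"stouffer"`.
#' @param alpha_fdr FDR threshold recorded in the `significant` column.
#' @param spearman_var Passed to [fisher_corr_diff_test()].
#' @return Data frame sorted by q then p: gene_id, n_cpgs,
#'   p_pos_in_cancer, p_neg_in_cancer, p_two_sided, q_value, bonferroni,
#'   direction, significant, mode.
#' @export
call_dcgs <- function(records, mode = c("single_corr", "stouffer"),
                      alpha_fdr = 0.05, spearman_var = FALSE) {
  mode <- match.arg(mode)
  if (mode == "single_corr") {
    ft <- fisher_corr_diff_test(records$rho_tumor, records$n_tumor,
                                records$rho_normal, records$n_normal,
                                spearman_var = spearman_var)
    out <- data.frame(gene_id = records$gene_id, n_cpgs = 1L,
                      p_pos_in_cancer = ft$p_greater,
                      p_neg_in_cancer = ft$p_less,
                      stringsAsFactors = FALSE)
  } else {
    stopifnot("cpg_id" %in% names(records))
    ft <- fisher_corr_diff_test(records$rho_tumor, records$n_tumor,
                                records$rho_normal, records$n_normal,
                                spearman_var = spearman_var)
    sp <- split(seq_len(nrow(records)), records$gene_id)
    # tails this extreme are machine-rounded to 0/1 by pnorm; clamp before
    # combining so the Stouffer quantiles stay finite
    p_gr <- pmin(pmax(ft$p_greater, 1e-300), 1 - 1e-16)
    p_le <- pmin(pmax(ft$p_less, 1e-300), 1 - 1e-16)
    out <- data.frame(gene_id = names(sp),
                      n_cpgs = lengths(sp),
                      p_pos_in_cancer = vapply(sp, function(i)
                        stouffer_combine(p_gr[i]), numeric(1)),
                      p_neg_in_cancer = vapply(sp, function(i)
                        stouffer_combine(p_le[i]), numeric(1)),
                      stringsAsFactors = FALSE, row.names = NULL)
  }
  out$p_two_sided <- pmin(1, 2 * pmin(out$p_pos_in_cancer,
                                      out$p_neg_in_cancer))
  out$q_value <- stats::p.adjust(out$p_two_sided, method = "BH")
  out$bonferroni <- stats::p.adjust(out$p_two_sided, method = "bonferroni")
  out$direction <- ifelse(out$p_pos_in_cancer <= out$p_neg_in_cancer,
                          "pos_in_cancer", "neg_in_cancer")
  out$significant <- out$q_value < alpha_fdr
  out$mode <- mode
  out[order(out$q_value, out$p_two_sided, out$gene_id), , drop = FALSE]
}

# all permutations of 1..n (n small), one per row
.permutations <- function(n) {
  if (n == 1L) return(matrix(1L))
  sub <- .permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[sub], nrow(sub)))
  }))
}

# Pearson correlation of the lower triangles of two symmetric matrices
.mantel_r <- function(a, b) {
  ia <- a[lower.tri(a)]
  ib <- b[lower.tri(b)]
  if (stats::sd(ia) == 0 || stats::sd(ib) == 0) return(NA_real_)
  stats::cor(ia, ib)
}

#' Mantel permutation test between two distance matrices
#'
#' Mantel r is the Pearson correlation between the lower triangles; the
#' one-sided p-value comes from permuting the rows/columns of the second
#' matrix: `p = (1 + #\{r_perm >= r_obs\}) / (1 + n_perm)`. When the number
#' of objects is small enough (`factorial(n) <= n_perm`) all permutations
#' are enumerated and the p-value is exact.
#'
#' @param d1,d2 Symmetric numeric matrices of the same dimension (>= 3).
#' @param n_perm Number of random permutations (ignored if enumerating).
#' @param seed Integer seed for the random permutations.
#' @return List with `r`, `p`, `n_perm_used`, `exact`.
#' @export
mantel_test <- function(d1, d2, n_perm = 999L, seed = 1L) {
  n <- nrow(d1)
  stopifnot(n >= 3, all(dim(d1) == dim(d2)))
  r_obs <- .mantel_r(d1, d2)
  if (is.na(r_obs)) {
    return(list(r = NA_real_, p = NA_real_, n_perm_used = 0L, exact = FALSE))
  }
  if (factorial(n) <= n_perm) {
    perms <- .permutations(n)
    rs <- apply(perms, 1, function(pm) .mantel_r(d1, d2[pm, pm]))
    # identity permutation is among the enumerated ones
    p <- mean(rs >= r_obs - 1e-12)
    return(list(r = r_obs, p = p, n_perm_used = nrow(perms), exact = TRUE))
  }
  set.seed(seed)
  hits <- 0L
  for (i in seq_len(n_perm)) {
    pm <- sample.int(n)
    if (.mantel_r(d1, d2[pm, pm]) >= r_obs - 1e-12) hits <- hits + 1L
  }
  list(r = r_obs, p = (1 + hits) / (1 + n_perm), n_perm_used = n_perm,
       exact = FALSE)
}

#' Mantel autocorrelation diagnostics for the Stouffer combination
#'
#' Spatial autocorrelation among a gene's CpG-level correlation differences
#' would violate the independence the Stouffer combination assumes and
#' inflate its Type I error. Per gene and TSS-distance stratum (within
#' 200 bp, 200-1000 bp, beyond 1000 bp by default) this runs a Mantel test
#' between the pairwise genomic-distance matrix `|pos_i - pos_j|` and the
#' dissimilarity of correlation changes `|dz_i - dz_j|`, where
#' `dz = z_tumor - z_normal` per CpG. q-values are BH-adjusted within each
#' stratum.
#'
#' @param cpg_records [cpg_correlations()] output (needs `pos`).
#' @param strata_bp Breakpoints (bp) splitting absolute TSS distance into
#'   strata; default `c(200, 1000)`.
#' @param n_perm Permutations per Mantel test.
#' @param seed Integer seed.
#' @param min_cpgs Minimum CpGs per gene and stratum (>= 3).
#' @param pooled If TRUE, run one Mantel test per stratum pooling CpGs
#'   across genes (capped at 300 CpGs per stratum for tractability).
#' @return Data frame with gene_id (or "pooled"), stratum, n_cpgs,
#'   mantel_r, p_value, q_value.
#' @export
mantel_autocorrelation <- function(cpg_records, strata_bp = c(200, 1000),
                                   n_perm = 999L, seed = 1L, min_cpgs = 3L,
                                   pooled = FALSE) {
  stopifnot(min_cpgs >= 3, all(c("pos", "abs_tss_dist") %in% names(cpg_records)))
  breaks <- c(-Inf, strata_bp, Inf)
  labs <- c(sprintf("within_%dbp", strata_bp[1]),
            if (length(strata_bp) > 1)
              sprintf("bp%d_%d", strata_bp[-length(strata_bp)],
                      strata_bp[-1]),
            sprintf("beyond_%dbp", strata_bp[length(strata_bp)]))
  stratum <- cut(cpg_records$abs_tss_dist, breaks, labels = labs)
  dz <- cpg_records$z_tumor - cpg_records$z_normal
  rows <- list()
  for (s in labs) {
    in_s <- which(stratum == s)
    if (length(in_s) < min_cpgs) next
    units <- if (pooled) list(pooled = in_s)
             else split(in_s, cpg_records$gene_id[in_s])
    for (g in names(units)) {
      i <- units[[g]]
      if (length(i) < min_cpgs) next
      if (pooled && length(i) > 300L) {
        set.seed(seed)
        i <- sort(sample(i, 300L))
      }
      dgeo <- abs(outer(cpg_records$pos[i], cpg_records$pos[i], "-"))
      ddz <- abs(outer(dz[i], dz[i], "-"))
      mt <- mantel_test(dgeo, ddz, n_perm = n_perm, seed = seed)
      if (is.na(mt$r)) next
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = g, stratum = s, n_cpgs = length(i),
        mantel_r = mt$r, p_value = mt$p, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(gene_id = character(), stratum = character(),
                      n_cpgs = integer(), mantel_r = numeric(),
                      p_value = numeric(), q_value = numeric()))
  }
  out <- do.call(rbind, rows)
  out$q_value <- stats::ave(out$p_value, out$stratum,
                            FUN = function(p) stats::p.adjust(p, "BH"))
  row.names(out) <- NULL
  out
}
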