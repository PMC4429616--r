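# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own code paths (and stats::wilcox.test) so they can
# serve as ground truth for small instances.

# One-tailed (greater) signed-rank p by enumerating all 2^n sign patterns
# of the absolute differences. Assumes no zero differences.
enum_signed_rank_p_greater <- function(d) {
  stopifnot(all(d != 0))
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_null <- as.vector(signs %*% r)
  mean(w_null >= w_obs)
}

# Exact rank-sum p for sample a vs b by enumerating all C(n1+n2, n1)
# assignments of the pooled ranks to group a.
enum_rank_sum_p <- function(a, b, alternative = c("less", "greater", "two.sided")) {
  alternative <- match.arg(alternative)
  pooled <- c(a, b)
  r <- rank(pooled)
  n1 <- length(a)
  w_obs <- sum(r[seq_len(n1)])
  combs <- utils::combn(length(pooled), n1)
  w_null <- apply(combs, 2, function(i) sum(r[i]))
  p_less <- mean(w_null <= w_obs)
  p_greater <- mean(w_null >= w_obs)
  switch(alternative,
         less = p_less, greater = p_greater,
         two.sided = min(1, 2 * min(p_less, p_greater)))
}

# Exhaustive Mantel p: correlation between off-diagonal entries under every
# relabeling of the second matrix. Implemented independently of the
# package's permutation machinery (upper triangle, explicit loops).
enum_mantel <- function(d1, d2) {
  n <- nrow(d1)
  perms <- gtools_permutations(n)
  tri <- upper.tri(d1)
  r_obs <- stats::cor(d1[tri], d2[tri])
  rs <- apply(perms, 1, function(pm) stats::cor(d1[tri], d2[pm, pm][tri]))
  list(r = r_obs, p = mean(rs >= r_obs - 1e-12))
}

# all permutations of 1..n by inserting n into every slot of each
# permutation of 1..(n-1)
gtools_permutations <- function(n) {
  if (n == 1) return(matrix(1L))
  sub <- gtools_permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(pos) {
    t(apply(sub, 1, function(p) append(p, n, after = pos - 1)))
  }))
}

# Exact preferential-overlap p over all case-label assignments, with a
# hand-rolled interval intersection (no GenomicRanges).
enum_overlap_p <- function(segments, track, n_case) {
  bp_overlap <- function(s1, e1) {
    tot <- 0
    for (i in seq_len(nrow(track))) {
      tot <- tot + max(0, min(e1, track$end[i]) - max(s1, track$start[i]))
    }
    tot
  }
  per_seg <- mapply(bp_overlap, segments$start, segments$end)
  obs <- sum(per_seg[segments$label == "case"])
  combs <- utils::combn(nrow(segments), n_case)
  stats_null <- apply(combs, 2, function(i) sum(per_seg[i]))
  mean(stats_null >= obs)
}

# Small simulated cohort shared by several tests (held in a lazy cache so
# expensive fixtures build once per test run).
.fixture_env <- new.env(parent = emptyenv())
fixture_cohort <- function() {
  if (is.null(.fixture_env$cohort)) {
    cfg <- simulation_config(n_genes = 300, n_tumor = 20, n_normal = 20,
                             seed = 42)
    ds <- simulate_dataset(cfg)
    meth_m <- preprocess_methylation(ds$methylation_beta)
    map <- data.frame(feature_id = ds$annotation$cpg_id,
                      gene_id = ds$annotation$gene_id,
                      stringsAsFactors = FALSE)
    .fixture_env$cohort <- list(
      ds = ds, meth_m = meth_m,
      meth_gene = aggregate_to_gene(meth_m, map),
      cpg_recs = cpg_correlations(ds$expression, meth_m, ds$annotation,
                                  ds$groups))
  }
  .fixture_env$cohort
}
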