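test_that("Fisher z-test for two correlations matches its closed form", {
  eq <- fisher_corr_diff_test(0.3, 20, 0.3, 50)
  expect_equal(eq$z_stat, 0)
  expect_equal(eq$p_two, 1)

  # strongly discordant correlations, n = 57 per group
  ft <- fisher_corr_diff_test(0.25, 57, -0.66, 57)
  z_want <- (atanh(0.25) - atanh(-0.66)) / sqrt(2 / 54)
  expect_equal(ft$z_stat, z_want)
  expect_equal(ft$z_stat, 5.447, tolerance = 1e-3)
  expect_equal(ft$p_two, 5.13e-8, tolerance = 1e-2)
  expect_equal(ft$p_greater + ft$p_less, 1, tolerance = 1e-12)

  # variance variant for Spearman correlations
  ftv <- fisher_corr_diff_test(0.25, 57, -0.66, 57, spearman_var = TRUE)
  expect_equal(ftv$z_stat, z_want / sqrt(1.06))
})

test_that("Fisher z-test holds its nominal type-I error", {
  # 20000 null replicates at n = 50 per group, common rho = 0.3
  n <- 50
  nsim <- 20000
  rho <- 0.3
  simcor <- function() {
    a <- matrix(rnorm(n * nsim), n)
    b <- rho * a + sqrt(1 - rho^2) * matrix(rnorm(n * nsim), n)
    ac <- sweep(a, 2, colMeans(a)); bc <- sweep(b, 2, colMeans(b))
    colSums(ac * bc) / sqrt(colSums(ac^2) * colSums(bc^2))
  }
  set.seed(77)
  r1 <- simcor()
  r2 <- simcor()
  z <- (atanh(r1) - atanh(r2)) / sqrt(2 / (n - 3))
  rate <- mean(2 * pnorm(-abs(z)) < 0.05)
  expect_gte(rate, 0.04)
  expect_lte(rate, 0.06)
})

test_that("Stouffer combination matches normal-quantile arithmetic", {
  expect_equal(stouffer_combine(0.37), 0.37)
  expect_equal(stouffer_combine(c(0.5, 0.5)), 0.5)
  # qnorm(0.95) = 1.6449, Z = 2.3263 = qnorm(0.99)
  expect_equal(stouffer_combine(c(0.05, 0.05)), 0.0100, tolerance = 1e-3)
  expect_equal(stouffer_combine(c(0.05, 0.05)),
               pnorm(2 * qnorm(0.95) / sqrt(2), lower.tail = FALSE))
  expect_warning(p0 <- stouffer_combine(c(0, 0.5)), "clamped")
  expect_true(p0 > 0 && p0 < 1)
  # monotone: decreasing any component decreases the combination
  base <- c(0.2, 0.4, 0.6)
  expect_lt(stouffer_combine(c(0.1, 0.4, 0.6)), stouffer_combine(base))
})

test_that("single-CpG stouffer mode coincides exactly with single_corr mode", {
  co <- fixture_cohort()
  recs <- co$cpg_recs
  # keep exactly one CpG per gene so each gene's Stouffer stack has k = 1
  sub <- recs[!duplicated(recs$gene_id), ][1:50, ]
  st <- call_dcgs(sub, mode = "stouffer")
  sc <- call_dcgs(data.frame(gene_id = sub$gene_id,
                             rho_normal = sub$rho_normal,
                             rho_tumor = sub$rho_tumor,
                             n_normal = sub$n_normal,
                             n_tumor = sub$n_tumor),
                  mode = "single_corr")
  st <- st[order(st$gene_id), ]
  sc <- sc[order(sc$gene_id), ]
  expect_equal(st$p_two_sided, sc$p_two_sided, tolerance = 1e-12)
  expect_equal(st$direction, sc$direction)
})

test_that("DCG calls are invariant to CpG order and have coherent tails", {
  co <- fixture_cohort()
  recs <- co$cpg_recs
  dc1 <- call_dcgs(recs, mode = "stouffer")
  set.seed(5)
  dc2 <- call_dcgs(recs[sample(nrow(recs)), ], mode = "stouffer")
  rownames(dc1) <- rownames(dc2) <- NULL
  expect_equal(dc1, dc2, tolerance = 1e-12)
  expect_true(all(dc1$p_two_sided ==
                    pmin(1, 2 * pmin(dc1$p_pos_in_cancer,
                                     dc1$p_neg_in_cancer))))
  # single-corr tails are complementary
  g <- gene_correlations(co$ds$expression, co$meth_gene, co$ds$groups)
  sc <- call_dcgs(g, mode = "single_corr")
  expect_equal(sc$p_pos_in_cancer + sc$p_neg_in_cancer, rep(1, nrow(sc)),
               tolerance = 1e-12)
})

test_that("planted DCGs are recovered with matching directions", {
  co <- fixture_cohort() # 10% planted, 20 vs 20, delta 0.8 symmetric
  dc <- call_dcgs(co$cpg_recs, mode = "stouffer")
  tt <- co$ds$truth
  called <- dc$gene_id[dc$significant]
  tp <- intersect(called, tt$gene_id[tt$is_dcg])
  expect_gt(length(tp) / sum(tt$is_dcg), 0.7)
  m <- merge(dc[dc$gene_id %in% tp, ], tt, by = "gene_id")
  expect_true(all(m$direction == m$direction_true))
})

test_that("Mantel statistic and permutation p behave as specified", {
  # identical matrices: maximal statistic, minimal p
  set.seed(12)
  pts <- cumsum(runif(8, 1, 10))
  d <- abs(outer(pts, pts, "-"))
  mt <- mantel_test(d, d, n_perm = 199, seed = 1)
  expect_equal(mt$r, 1)
  expect_equal(mt$p, 1 / (1 + 199))

  # 4 objects: exact enumeration over 4! = 24 relabelings
  set.seed(13)
  v1 <- runif(4)
  v2 <- runif(4)
  a <- abs(outer(v1, v1, "-"))
  b <- abs(outer(v2, v2, "-"))
  mt4 <- mantel_test(a, b, n_perm = 999)
  oracle <- enum_mantel(a, b)
  expect_true(mt4$exact)
  expect_equal(mt4$r, oracle$r, tolerance = 1e-12)
  expect_equal(mt4$p, oracle$p)

  # constant matrix: undefined statistic, flagged
  flat <- matrix(1, 4, 4) - diag(4)
  expect_true(is.na(mantel_test(flat, b, n_perm = 99)$r))

  # agreement with an established implementation on a larger instance
  skip_if_not_installed("vegan")
  set.seed(14)
  x <- as.matrix(dist(matrix(rnorm(20), 10)))
  y <- as.matrix(dist(matrix(rnorm(20), 10)))
  ours <- mantel_test(x, y, n_perm = 9999, seed = 2)
  ref <- vegan::mantel(as.dist(x), as.dist(y), permutations = 9999)
  expect_equal(ours$r, unname(ref$statistic), tolerance = 1e-12)
  expect_lt(abs(ours$p - ref$signif), 0.05)
})

test_that("per-gene Mantel diagnostics stratify by TSS distance and stay null", {
  co <- fixture_cohort()
  recs <- co$cpg_recs[co$cpg_recs$gene_id %in%
                        unique(co$cpg_recs$gene_id)[1:40], ]
  mt <- mantel_autocorrelation(recs, n_perm = 199, seed = 3)
  expect_true(all(mt$n_cpgs >= 3))
  expect_true(all(mt$p_value > 0 & mt$p_value <= 1))
  expect_true(all(mt$stratum %in% c("within_200bp", "bp200_1000",
                                    "beyond_1000bp")))
  # CpG correlation differences are independent here: no stratum should
  # light up at 10% FDR
  expect_lt(mean(mt$q_value < 0.10), 0.05 + 1e-9)
  # pooled variant runs and returns one row per populated stratum
  mp <- mantel_autocorrelation(recs, n_perm = 99, seed = 3, pooled = TRUE)
  expect_true(all(mp$gene_id == "pooled"))
})
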