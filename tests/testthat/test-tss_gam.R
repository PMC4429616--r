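test_that("smooth fit degenerates to a flat line on constant-mean data", {
  set.seed(41)
  d <- runif(600, 0, 50000)
  z <- rnorm(600, mean = 0.3, sd = 0.2)
  fit <- fit_smooth(z, d, k = 10)
  expect_lt(fit$edf, 2)
  pr <- predict_smooth(fit, seq(1000, 49000, length.out = 20))
  expect_true(all(abs(pr$fitted - 0.3) < 2.5 * pr$se + 0.05))
})

test_that("smooth fit tracks a linear trend within 2 SE of OLS", {
  set.seed(42)
  d <- runif(800, 0, 10000)
  z <- 0.5 - d / 10000 + rnorm(800, sd = 0.15)
  fit <- fit_smooth(z, d, k = 10)
  ols <- lm(z ~ d)
  grid <- seq(500, 9500, length.out = 30)
  pr <- predict_smooth(fit, grid)
  ols_pr <- predict(ols, data.frame(d = grid), se.fit = TRUE)
  expect_true(all(abs(pr$fitted - ols_pr$fit) <
                    2 * pmax(pr$se, ols_pr$se.fit)))
})

test_that("smooth fit recovers a sinusoid with small RMSE", {
  set.seed(43)
  n <- 5000
  d <- runif(n, 0, 50000)
  truth <- sin(d / 5000)
  z <- truth + rnorm(n, sd = 0.3)
  fit <- fit_smooth(z, d, k = 20)
  pr <- predict_smooth(fit, d)
  expect_lt(sqrt(mean((pr$fitted - truth)^2)), 0.05)
})

test_that("fitted values are invariant under distance rescaling", {
  set.seed(44)
  d <- runif(500, 0, 20000)
  z <- sin(d / 4000) + rnorm(500, sd = 0.2)
  f1 <- fit_smooth(z, d, k = 12)
  f2 <- fit_smooth(z, d * 3.7, k = 12)
  g <- seq(1000, 19000, length.out = 25)
  expect_equal(predict_smooth(f1, g)$fitted,
               predict_smooth(f2, g * 3.7)$fitted, tolerance = 1e-6)
})

test_that("basis-adequacy k-index is near 1 for clean fits and drops under unmodeled trend", {
  set.seed(45)
  d <- runif(800, 0, 30000)
  # residual-like noise, independent of distance
  fit0 <- fit_smooth(rnorm(800, sd = 0.3), d, k = 8)
  chk0 <- basis_adequacy_check(fit0, n_shuffles = 500, seed = 1)
  expect_lt(abs(chk0$k_index - 1), 0.15)
  expect_gt(chk0$p, 0.05)

  # strong unmodeled smooth structure: feed residuals with leftover trend
  r_trend <- sin(d / 1500) + rnorm(800, sd = 0.1)
  chk1 <- basis_adequacy_check(fit0, n_shuffles = 500, seed = 2,
                               residuals = r_trend, abs_dist = d)
  expect_lt(chk1$p, 0.01)

  # shuffle-count stability
  chk2 <- basis_adequacy_check(fit0, n_shuffles = 1000, seed = 3)
  expect_lt(abs(chk2$p - chk0$p), 0.1)
  expect_warning(basis_adequacy_check(fit0, n_shuffles = 50), "100")
})

test_that("region comparison is null for identical groups and detects ratio shifts", {
  set.seed(46)
  n <- 60
  z <- rnorm(n)
  recs <- data.frame(cpg_id = paste0("cg", 1:n), gene_id = "g",
                     abs_tss_dist = c(seq(100, 4900, length.out = n / 2),
                                      seq(6000, 40000, length.out = n / 2)),
                     rho_normal = tanh(z), rho_tumor = tanh(z),
                     z_normal = z, z_tumor = z)
  rc <- region_comparison(recs)
  expect_equal(rc$t_within$p, 1)
  expect_equal(rc$t_outside$p, 1)
  expect_equal(rc$sign_shift_within, rc$sign_shift_outside)
  expect_true(rc$t_within$ci[1] <= 0 && rc$t_within$ci[2] >= 0)

  # ratio shift: z_normal/z_tumor near 1 inside, near 2 outside, 5 + 5 CpGs
  zt <- rep(1, 10)
  ratios <- c(1.00, 1.01, 1.02, 1.03, 1.04, 2.00, 2.01, 2.02, 2.03, 2.04)
  recs2 <- data.frame(cpg_id = paste0("cg", 1:10), gene_id = "g",
                      abs_tss_dist = rep(c(1000, 9000), each = 5),
                      rho_normal = tanh(ratios), rho_tumor = tanh(zt),
                      z_normal = ratios, z_tumor = zt)
  rc2 <- region_comparison(recs2)
  p_oracle <- enum_rank_sum_p(ratios[1:5], ratios[6:10], "two.sided")
  expect_equal(rc2$ratio$wilcoxon_p, p_oracle)
  expect_equal(p_oracle, 2 / choose(10, 5))

  # sign-shift definition
  recs3 <- recs2
  recs3$rho_normal <- c(rep(0.5, 5), rep(0.5, 5))
  recs3$rho_tumor <- c(rep(0.5, 5), rep(-0.5, 5))
  rc3 <- region_comparison(recs3)
  expect_equal(rc3$sign_shift_within, 0)
  expect_equal(rc3$sign_shift_outside, 1)
})

test_that("rank-sum exact p matches enumeration on the canonical separated case", {
  expect_equal(enum_rank_sum_p(c(1, 2, 3), c(4, 5, 6), "less"), 1 / 20)
  got <- compare_sets(c(1, 2, 3), c(4, 5, 6))
  expect_equal(got$p, 2 / 20)
})

test_that("two-group TSS fits reproduce the near-TSS negative / distal positive pattern", {
  # simulator default correlation profile; deeper run lives in acceptance
  cfg <- simulation_config(n_genes = 250, n_tumor = 25, n_normal = 25,
                           dcg_fraction = 0, seed = 47)
  ds <- simulate_dataset(cfg)
  meth_m <- preprocess_methylation(ds$methylation_beta)
  recs <- cpg_correlations(ds$expression, meth_m, ds$annotation, ds$groups)
  fits <- tss_gam_both_groups(recs, k = 15)
  near <- predict_smooth(fits$fits$normal, c(200, 800, 1500))
  far <- predict_smooth(fits$fits$normal, c(10000, 30000, 60000))
  expect_true(all(near$fitted < 0))
  expect_true(all(far$fitted > 0))
  near_t <- predict_smooth(fits$fits$tumor, c(200, 800, 1500))
  far_t <- predict_smooth(fits$fits$tumor, c(10000, 30000, 60000))
  expect_true(all(near_t$fitted < 0))
  expect_true(all(far_t$fitted > 0))
})
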