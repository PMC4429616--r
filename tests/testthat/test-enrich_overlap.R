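test_that("hypergeometric enrichment matches the closed-form tail sum", {
  # background 100, annotation 10, called 20, overlap 5
  bg <- paste0("g", 1:100)
  annot <- bg[1:10]
  called <- c(bg[1:5], bg[51:65])
  res <- hypergeometric_enrichment(called, annot, bg)
  expect_equal(res$overlap, 5)
  p_want <- sum(sapply(5:10, function(k)
    choose(10, k) * choose(90, 20 - k) / choose(100, 20)))
  expect_equal(res$p, p_want, tolerance = 1e-12)

  # annotation = background: overlap = |called|, p = 1
  res2 <- hypergeometric_enrichment(called, bg, bg)
  expect_equal(res2$overlap, 20)
  expect_equal(res2$p, 1)

  # disjoint tiny annotation: p near 1
  res3 <- hypergeometric_enrichment(bg[90:95], bg[1:2], bg)
  expect_equal(res3$overlap, 0)
  expect_gt(res3$p, 0.85)
  expect_error(hypergeometric_enrichment(called, "not_there", bg),
               "no genes in background")
})

test_that("MC overlap p converges to the exhaustive label-permutation p", {
  set.seed(61)
  segments <- data.frame(chrom = "chr1",
                         start = c(0, 2000, 4000, 6000, 8000, 10000),
                         end = c(1000, 3000, 5000, 7000, 9000, 11000),
                         label = c("case", "case", "case",
                                   "control", "control", "control"))
  track <- data.frame(chrom = "chr1",
                      start = c(100, 2100, 6100), end = c(600, 2600, 6400))
  p_exact <- enum_overlap_p(segments, track, n_case = 3)
  res <- mc_overlap_test(segments, track, n_mc = 20000, seed = 2)
  expect_lt(abs(res$mc_p - p_exact), 0.02)
  expect_gte(res$mc_p, 1 / (1 + 20000))
  expect_equal(res$observed_stat, 1000) # 500 + 500 bp inside case segments

  # track covering everything: all label assignments tie, p = 1
  cover <- data.frame(chrom = "chr1", start = 0, end = 12000)
  res_all <- mc_overlap_test(segments, cover, n_mc = 200, seed = 1)
  expect_equal(res_all$mc_p, 1)
  expect_equal(res_all$observed_stat, 3000)

  # empty track is flagged with p = 1
  res_empty <- mc_overlap_test(segments, track[0, ], n_mc = 200, seed = 1)
  expect_equal(res_empty$mc_p, 1)
  expect_equal(res_empty$flag, "empty_track")
})

test_that("overlap p is invariant to segment order and chromosome names", {
  st <- simulate_segment_tracks(15, 15, 0.9, 0.2, seed = 5)
  r1 <- mc_overlap_test(st$segments, st$track, n_mc = 500, seed = 9)
  shuffled <- st$segments[sample(nrow(st$segments)), ]
  renamed <- within(shuffled, chrom <- "chrZ")
  track2 <- within(st$track, chrom <- "chrZ")
  # same seed, same case/control composition of overlap amounts
  r2 <- mc_overlap_test(renamed[order(renamed$start), ], track2,
                        n_mc = 500, seed = 9)
  expect_equal(r1$mc_p, r2$mc_p)
  expect_equal(r1$observed_stat, r2$observed_stat)
  expect_lt(r1$mc_p, 0.05) # planted 0.9 vs 0.2 rates are detectable
})

test_that("null tracks give uniform-ish p and replicate merging delegates to Stouffer", {
  ps <- vapply(1:40, function(s) {
    st <- simulate_segment_tracks(20, 20, 0.5, 0.5, seed = 100 + s)
    mc_overlap_test(st$segments, st$track, n_mc = 200, seed = s)$mc_p
  }, numeric(1))
  expect_gt(mean(ps > 0.2), 0.5)
  expect_lt(mean(ps < 0.05), 0.2)
  expect_equal(merge_replicate_tracks(c(0.05, 0.05)),
               stouffer_combine(c(0.05, 0.05)))
})

test_that("batched FDR adjusts within batches only", {
  res <- data.frame(track_id = c("t1", "t2", "t3", "t4"),
                    mc_p = c(0.01, 0.02, 0.03, 0.04))
  one <- batched_fdr(res, setNames(rep("b1", 4), res$track_id))
  expect_equal(one$q, p.adjust(res$mc_p, "BH"))
  two <- batched_fdr(res, setNames(c("b1", "b1", "b2", "b2"), res$track_id))
  expect_equal(two$q[1:2], p.adjust(res$mc_p[1:2], "BH"))
  expect_equal(two$q[3:4], p.adjust(res$mc_p[3:4], "BH"))
  singles <- batched_fdr(res[1:2, ], setNames(c("b1", "b2"), c("t1", "t2")))
  expect_equal(singles$q, singles$mc_p)
  expect_error(batched_fdr(res, setNames("b1", "t1")), "without batch")
})

test_that("the overlap suite merges replicates and labels gene segments", {
  st <- simulate_segment_tracks(20, 20, 0.9, 0.1, seed = 7)
  st2 <- simulate_segment_tracks(20, 20, 0.9, 0.1, seed = 8)
  tracks <- list(tfA_rep1 = st$track, tfA_rep2 = st2$track,
                 tfB = st$track)
  suite <- run_overlap_suite(
    st$segments, tracks,
    batch = c(tfA = "tf", tfB = "tf"),
    replicate_of = c(tfA_rep1 = "tfA", tfA_rep2 = "tfA"),
    n_mc = 300, seed = 3)
  expect_setequal(suite$track_id, c("tfA", "tfB"))
  expect_true(all(suite$q >= suite$merged_p - 1e-12))

  coords <- data.frame(gene_id = c("g1", "g2"), chrom = "chr1",
                       start = c(0, 5000), end = c(2000, 8000))
  seg <- label_gene_segments(coords, "g2")
  expect_equal(seg$label, c("control", "case"))
})
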