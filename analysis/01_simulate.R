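#!/usr/bin/env Rscript
# Step 1: generate the synthetic tumor/normal cohort the analysis runs on.
#
# The cohort emulates a 450K-style breast-cancer design: 8 normal vs 57
# tumor samples, 6000 genes, 3-12 CpGs per gene with signed TSS distances,
# methylation-expression correlation negative near the TSS and mildly
# positive distally, and 10% of genes planted as differentially correlated
# (DCGs). Matrices are written as plain TSV under scratch/cohort/ for the
# later steps; the truth table records the planted ground truth.

library(dcgscan)

out_dir <- "scratch/cohort"
cfg <- simulation_config(n_genes = 6000, n_tumor = 57, n_normal = 8,
                         platform_mode = "k450", dcg_fraction = 0.1,
                         dcg_delta = 0.8, seed = 20260921)
ds <- simulate_dataset(cfg)
write_dataset(ds, out_dir)

cat(sprintf("cohort: %d genes, %d CpGs, %d normal + %d tumor samples\n",
            nrow(ds$expression), nrow(ds$methylation_beta),
            sum(ds$groups$group == "normal"), sum(ds$groups$group == "tumor")))
cat(sprintf("planted DCGs: %d (%.1f%%), split %s by delta = %.1f\n",
            sum(ds$truth$is_dcg), 100 * mean(ds$truth$is_dcg),
            cfg$dcg_split, cfg$dcg_delta))
cat("wrote", out_dir, "\n")
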