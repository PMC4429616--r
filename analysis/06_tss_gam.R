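#!/usr/bin/env Rscript
# Step 6: correlation as a function of TSS distance.
#
# Fisher-z Spearman correlations per CpG are regressed on absolute TSS
# distance with a penalized cubic regression spline (k = 20, GCV), per
# group. The basis-adequacy shuffle check guards against an undersized
# basis. The 5-kb regional comparison contrasts promoter-proximal and
# distal correlation structure: paired t-tests on z differences, the
# correlation ratio z_normal/z_tumor, and sign-shift fractions.

library(dcgscan)

cpg_recs <- read_table_tsv("scratch/cohort/cpg_correlations.tsv")

fits <- tss_gam_both_groups(cpg_recs, k = 20)
print(fits$fits$normal)
print(fits$fits$tumor)
write_table_tsv(fits$grid, "results/tss_gam_grid.tsv")

for (g in c("normal", "tumor")) {
  chk <- basis_adequacy_check(fits$fits[[g]], n_shuffles = 20000,
                              seed = 20260924)
  cat(sprintf("%s basis check: k-index = %.3f, p = %.3f\n",
              g, chk$k_index, chk$p))
}

rc <- region_comparison(cpg_recs, boundary_bp = 5000)
print(rc)
write_table_tsv(
  data.frame(boundary_bp = rc$boundary_bp,
             t_p_within = rc$t_within$p, t_p_outside = rc$t_outside$p,
             ratio_mean_within = rc$ratio$mean_within,
             ratio_mean_outside = rc$ratio$mean_outside,
             ratio_wilcoxon_p = rc$ratio$wilcoxon_p,
             sign_shift_within = rc$sign_shift_within,
             sign_shift_outside = rc$sign_shift_outside),
  "results/region_comparison.tsv")
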