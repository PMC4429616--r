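#!/usr/bin/env Rscript
# Step 2: normalize the methylation data and build gene-level matrices.
#
# Betas are converted to M values (the analysis scale) and quantile
# normalized jointly across all samples of the dataset; CpG-level M values
# are then averaged per gene for the gene-level correlation analyses.

library(dcgscan)

dir.create("results", showWarnings = FALSE)
beta <- read_matrix_tsv("scratch/cohort/methylation.tsv")
annot <- read_table_tsv("scratch/cohort/annotation.tsv")

meth_m <- preprocess_methylation(beta, scale = "beta", joint = TRUE)
write_matrix_tsv(meth_m, "scratch/cohort/methylation_m_qnorm.tsv",
                 id_col = "cpg_id")

map <- data.frame(feature_id = annot$cpg_id, gene_id = annot$gene_id)
meth_gene <- aggregate_to_gene(meth_m, map)
write_matrix_tsv(meth_gene, "scratch/cohort/methylation_gene_avg.tsv",
                 id_col = "gene_id")

# robust variability of methylation per CpG, on the beta scale
cv <- apply(beta, 1, function(v) robust_cv(v))
cat(sprintf("normalized %d CpGs; gene-level matrix: %d genes\n",
            nrow(meth_m), nrow(meth_gene)))
cat(sprintf("median robust CV of beta values: %.1f%%\n",
            median(cv, na.rm = TRUE)))
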