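#!/usr/bin/env Rscript
# Step 3: per-gene and per-CpG methylation-expression correlations.
#
# Spearman correlations are computed within each group: gene-averaged
# methylation vs expression (for the genome-wide tests) and each CpG vs its
# gene's expression (for the Stouffer DCG calling and the TSS-distance
# regression). Fisher z transforms ride along in the tables.

library(dcgscan)

expr <- read_matrix_tsv("scratch/cohort/expression.tsv")
meth_gene <- read_matrix_tsv("scratch/cohort/methylation_gene_avg.tsv")
meth_m <- read_matrix_tsv("scratch/cohort/methylation_m_qnorm.tsv")
annot <- read_table_tsv("scratch/cohort/annotation.tsv")
groups <- read_table_tsv("scratch/cohort/groups.tsv")

gene_recs <- gene_correlations(expr, meth_gene, groups, method = "spearman")
write_table_tsv(gene_recs, "scratch/cohort/gene_correlations.tsv")

cpg_recs <- cpg_correlations(expr, meth_m, annot, groups,
                             method = "spearman")
write_table_tsv(cpg_recs, "scratch/cohort/cpg_correlations.tsv")

cat(sprintf("gene-level records: %d; CpG-level records: %d\n",
            nrow(gene_recs), nrow(cpg_recs)))
cat(sprintf("median rho: normal %.3f, tumor %.3f (gene level)\n",
            median(gene_recs$rho_normal), median(gene_recs$rho_tumor)))
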