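#!/usr/bin/env Rscript
# Stage 4: miRNA-gene correlation and age trends.
#
# Each selected AA-miRNA is correlated (Pearson, on logCPM with a 0.5
# prior) against every tested gene, with exact t-based two-sided
# p-values at n = 12. Linear age trends (logCPM per year, OLS with 95%
# CI) are reported for the selected features.
library(agemir)

for (f in c("aa_mirna.tsv", "aa_gene.tsv"))
  if (!file.exists(file.path("results", f)))
    stop("missing results/", f, " - run analysis/03_meta.R first")

sim <- file.path("results", "sim")
mirna <- read_count_matrix(file.path(sim, "mirna_counts.tsv"), "miRNA")
gene <- read_count_matrix(file.path(sim, "gene_counts.tsv"), "gene")
samples <- read_sample_table(file.path(sim, "samples.tsv"))
aa_mirna <- read_tsv(file.path("results", "aa_mirna.tsv"))
aa_gene <- read_tsv(file.path("results", "aa_gene.tsv"))

mir_lcpm <- log_cpm(mirna)
gene_lcpm <- log_cpm(gene)
cors <- correlate_all(mir_lcpm[aa_mirna$feature, , drop = FALSE], gene_lcpm)
write_table(cors, file.path("results", "correlations.tsv"))
cat(nrow(cors), "miRNA-gene correlations (",
    sum(cors$p_cor < 0.05), "at p < 0.05 )\n")

sel <- c(aa_mirna$feature, aa_gene$feature)
expr <- rbind(mir_lcpm[aa_mirna$feature, , drop = FALSE],
              gene_lcpm[aa_gene$feature, , drop = FALSE])
trends <- linear_trends(expr, samples)
write_table(trends, file.path("results", "age_trends.tsv"))
cat("Age trends for", nrow(trends), "selected features:",
    sum(trends$p_trend < 0.05), "with p_trend < 0.05\n")
cat("Wrote results/correlations.tsv and results/age_trends.tsv\n")
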