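#!/usr/bin/env Rscript
# Stage 5: valid-pair rule, direct/indirect classification, target
# enrichment.
#
# A pair is valid when (i) both features are age-associated, (ii) the
# correlation is significant at p < 0.05 and (iii) its sign matches the
# product of the two features' effect directions. Valid pairs whose
# gene is a database-predicted target of the miRNA AND negatively
# correlated are direct interactions; the rest are indirect. Per miRNA,
# the overlap of its target set with the AA-genes is tested against the
# hypergeometric background of all tested genes.
library(agemir)

if (!file.exists(file.path("results", "correlations.tsv")))
  stop("missing results/correlations.tsv - run analysis/04_correlate.R first")

sim <- file.path("results", "sim")
aa_mirna <- read_tsv(file.path("results", "aa_mirna.tsv"))
aa_gene <- read_tsv(file.path("results", "aa_gene.tsv"))
cors <- read_tsv(file.path("results", "correlations.tsv"))
meta_gene <- read_tsv(file.path("results", "meta_gene.tsv"))
targetdb <- read_target_db(file.path(sim, "targets.tsv"))

pairs <- valid_pairs(aa_mirna, aa_gene, cors)
pairs <- classify_pairs(pairs, targetdb)
write_table(pairs, file.path("results", "pairs.tsv"))
cat(nrow(aa_mirna) * nrow(aa_gene), "candidate pairs ->", nrow(pairs),
    "valid;", sum(pairs$interaction == "direct"), "direct,",
    sum(pairs$interaction == "indirect"), "indirect\n")
cat("Correlation types:",
    paste(names(table(pairs$type_label)), table(pairs$type_label),
          collapse = ", "), "\n")

enr <- enrich_all_mirnas(aa_mirna$feature, targetdb, aa_gene$feature,
                         meta_gene$feature, cors)
write_table(enr, file.path("results", "target_enrichment.tsv"))
cat("Target-set enrichment: fold change range",
    paste(round(range(enr$fold_change), 2), collapse = " - "),
    "across", nrow(enr), "miRNA x scope rows\n")

truth_pairs <- file.path(sim, "truth_pairs.tsv")
if (file.exists(truth_pairs)) {
  tp <- read_tsv(truth_pairs)
  direct <- pairs[pairs$interaction == "direct", ]
  hit <- paste(tp$mirna, tp$gene) %in% paste(direct$mirna, direct$gene)
  cat("Planted couplings recovered as direct:", sum(hit), "/", nrow(tp), "\n")
}
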