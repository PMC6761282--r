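#!/usr/bin/env Rscript
# Stage 3: Fisher meta-analysis and selection of age-associated features.
#
# The two per-contrast p-values are combined per feature with Fisher's
# method (chi-square, df = 4) and BH-adjusted across all tested
# features. miRNAs are selected by nominal p < 0.05 in BOTH contrasts
# with consistent direction (the replication criterion); genes by
# FDR < 0.05 on the combined p, then the consistency filter.
# Direction-discordant features that pass everything else are reported
# separately, not dropped.
library(agemir)

for (f in c("de_mirna.tsv", "de_gene.tsv"))
  if (!file.exists(file.path("results", f)))
    stop("missing results/", f, " - run analysis/02_diffexp.R first")

meta_mirna <- meta_combine(read_tsv(file.path("results", "de_mirna.tsv")))
meta_gene <- meta_combine(read_tsv(file.path("results", "de_gene.tsv")))
rule <- selection_rule()

sel_mirna <- select_aa_features(meta_mirna, rule, "nominal_both")
sel_gene <- select_aa_features(meta_gene, rule, "fdr_meta")

write_table(meta_mirna, file.path("results", "meta_mirna.tsv"))
write_table(meta_gene, file.path("results", "meta_gene.tsv"))
write_table(sel_mirna$selected, file.path("results", "aa_mirna.tsv"))
write_table(sel_mirna$discordant, file.path("results", "aa_mirna_discordant.tsv"))
write_table(sel_gene$selected, file.path("results", "aa_gene.tsv"))
write_table(sel_gene$discordant, file.path("results", "aa_gene_discordant.tsv"))

cat("AA-miRNAs:", nrow(sel_mirna$selected), "selected,",
    nrow(sel_mirna$discordant), "discordant\n")
cat("AA-genes:", sum(meta_gene$fdr < rule$fdr_cut, na.rm = TRUE),
    "at FDR <", rule$fdr_cut, "->", nrow(sel_gene$selected),
    "direction-consistent (", nrow(sel_gene$discordant), "discordant )\n")

# planted-truth check when stage 1's truth tables are present
truth_path <- file.path("results", "sim", "truth_mirna.tsv")
if (file.exists(truth_path)) {
  tm <- read_tsv(truth_path)
  tg <- read_tsv(file.path("results", "sim", "truth_gene.tsv"))
  cat("Recovered", sum(tm$feature %in% sel_mirna$selected$feature), "/",
      nrow(tm), "planted miRNAs and",
      sum(tg$feature %in% sel_gene$selected$feature), "/", nrow(tg),
      "planted genes\n")
}
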