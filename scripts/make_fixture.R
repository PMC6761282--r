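#!/usr/bin/env Rscript
# Regenerates the committed desk-scale fixture under inst/extdata/tiny:
# 50 miRNAs x 500 genes, 12 samples in four age groups, planted
# age-associated features and miRNA-target repression couplings.
# Library sizes are scaled down with the feature count so per-feature
# depth stays realistic while files remain small. Deterministic: the
# same seed always yields byte-identical files.
library(agemir)

cfg <- sim_config(
  n_mirna = 50L, n_gene = 500L,
  n_aa_mirna = 7L, n_aa_gene = 20L, n_direct_pairs = 7L,
  mirna_libsize_range = c(1.5e5, 2.5e5),
  gene_libsize_range = c(8e5, 1.2e6),
  seed = 20200417L)

bundle <- simulate_aging_cohort(cfg)
paths <- write_fixture(bundle, file.path("inst", "extdata", "tiny"))
cat("wrote", length(paths), "files:\n")
cat(paste(" ", paths, paste0("(", file.size(paths), " bytes)")), sep = "\n")
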