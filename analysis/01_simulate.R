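#!/usr/bin/env Rscript
# Stage 1: simulate the study cohort.
#
# The deposited cohort (12 right-atrial samples in four age groups) is
# not redistributed here, so the workflow runs on a simulated cohort
# with the same design and known planted truth: 500 miRNAs and 5,000
# genes (a desk-scale stand-in for the study's ~1,482 and ~23,346),
# 10 age-associated miRNAs and 50 age-associated genes planted at
# logFC 2 per decade-pair contrast, and 15 miRNA-target repression
# couplings. Inputs for the later stages are written as plain TSV/GMT.
library(agemir)

out <- file.path("results", "sim")
cfg <- sim_config(n_mirna = 500L, n_gene = 5000L,
                  n_aa_mirna = 10L, n_aa_gene = 50L, n_direct_pairs = 15L,
                  gene_libsize_range = c(4e6, 6e6),
                  seed = 20200417L)
bundle <- simulate_aging_cohort(cfg)
paths <- write_fixture(bundle, out)

cat("Simulated cohort:", nrow(bundle$mirna), "miRNAs,", nrow(bundle$gene),
    "genes,", nrow(bundle$samples), "samples\n")
cat("Planted truth:", nrow(bundle$truth$aa_mirna), "AA-miRNAs,",
    nrow(bundle$truth$aa_gene), "AA-genes,",
    nrow(bundle$truth$direct_pairs), "repression couplings\n")
cat("Target database:", nrow(bundle$targetdb), "pairs (planted + decoys)\n")
cat("Wrote", length(paths), "files under", out, "\n")
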