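# Shared fixtures, built in code. The tiny bundle is simulated once per
# test run; seeds are fixed so every expectation is reproducible.

make_samples <- function(n_per_group = 3L) {
  groups <- c("SR40", "SR50", "SR60", "SR70")
  ages <- c(SR40 = 40L, SR50 = 50L, SR60 = 60L, SR70 = 70L)
  n <- 4L * n_per_group
  sample_table(data.frame(
    sample_id = sprintf("S%02d", seq_len(n)),
    group = rep(groups, each = n_per_group),
    age = rep(ages, each = n_per_group),
    sex = rep_len(c("F", "M", "M"), n),
    stringsAsFactors = FALSE))
}

# two-group-only sample table (for single-contrast fits)
make_two_group_samples <- function(n_per_group, case = "SR60", ref = "SR40") {
  ages <- c(SR40 = 40L, SR50 = 50L, SR60 = 60L, SR70 = 70L)
  n <- 2L * n_per_group
  sample_table(data.frame(
    sample_id = sprintf("S%02d", seq_len(n)),
    group = rep(c(ref, case), each = n_per_group),
    age = rep(ages[c(ref, case)], each = n_per_group),
    sex = rep_len(c("F", "M", "M"), n),
    stringsAsFactors = FALSE))
}

make_cm <- function(counts, kind = "gene") {
  if (is.null(rownames(counts))) rownames(counts) <- paste0("f", seq_len(nrow(counts)))
  if (is.null(colnames(counts))) colnames(counts) <- sprintf("S%02d", seq_len(ncol(counts)))
  count_matrix(counts, kind)
}

tiny_cfg <- function(...) {
  sim_config(n_mirna = 60L, n_gene = 400L, n_aa_mirna = 5L, n_aa_gene = 16L,
             n_direct_pairs = 5L,
             mirna_libsize_range = c(2e5, 4e5),
             gene_libsize_range = c(5e5, 1e6),
             seed = 42L, ...)
}

# built lazily, shared across test files
tiny_bundle_env <- new.env()
tiny_bundle <- function() {
  if (is.null(tiny_bundle_env$b))
    tiny_bundle_env$b <- simulate_aging_cohort(tiny_cfg())
  tiny_bundle_env$b
}

tiny_pipeline <- function() {
  if (is.null(tiny_bundle_env$res)) {
    b <- tiny_bundle()
    tiny_bundle_env$res <- suppressMessages(
      run_aging_pipeline(b$mirna, b$gene, b$samples, b$targetdb, b$gene_sets))
  }
  tiny_bundle_env$res
}
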