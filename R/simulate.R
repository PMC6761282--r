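#' Configuration for the coupled miRNA/mRNA count simulator
#'
#' Defaults emulate the study design the pipeline was built for: 12
#' samples in four age groups (SR40/SR50/SR60/SR70, 3 each, one female
#' and two males per group), ~1,482 miRNAs and ~23,346 genes,
#' negative-binomial counts (variance = mu + phi * mu^2) with
#' sample-specific library sizes, planted age-dependent log-fold-changes
#' and planted miRNA-to-target repression couplings.
#'
#' Planted age effects use per-group multipliers 2^(dir * logFC * s_g)
#' with monotone, zero-centered group scores s = (-0.75, -0.25, 0.25,
#' 0.75), so each decade-pair contrast (SR60 vs SR40; SR70 vs SR50) has
#' true logFC equal to `planted_logfc` while the planted mass stays
#' balanced across samples. A coupled target gene's mean is multiplied
#' by 2^(-coupling_strength * centered latent log2-CPM of its
#' regulator), i.e. repression acts through the regulator's noise-free
#' expression, keeping the planted truth well-defined.
#'
#' Counts emulate sequencing's compositionality: expected proportions
#' are renormalized to sum to one within each sample before being
#' scaled by its library size, so a sample's total depth is set by the
#' sequencer, not by the planted biology. The true mean CPM matrices in
#' the returned ground truth are post-normalization.
#'
#' @param n_per_group samples per age group (default 3).
#' @param n_mirna,n_gene feature counts (study scale by default; reduce
#'   for desk-scale runs).
#' @param phi common NB dispersion (default 0.1).
#' @param mirna_libsize_range,gene_libsize_range per-sample totals,
#'   drawn log-uniformly.
#' @param n_aa_mirna,n_aa_gene planted age-associated features
#'   (defaults 7 and 42, the study's discovery counts).
#' @param planted_logfc true log2 fold change per decade-pair contrast
#'   (default 2).
#' @param n_direct_pairs planted repression couplings (default 8).
#' @param coupling_strength log2 repression per unit centered regulator
#'   log2-CPM (default 0.8).
#' @param decoy_factor decoy target-database pairs per planted pair
#'   (default 10).
#' @param baseline_sdlog log-normal spread of baseline abundances.
#' @param n_gene_sets random gene sets written to the fixture GMT.
#' @param age_jitter add +-2 y uniform jitter to the representative
#'   group ages (default FALSE).
#' @param seed mandatory integer seed; all randomness flows from it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_per_group = 3L, n_mirna = 1482L, n_gene = 23346L,
                       phi = 0.1,
                       mirna_libsize_range = c(8e5, 1.2e6),
                       gene_libsize_range = c(1.5e7, 2.5e7),
                       n_aa_mirna = 7L, n_aa_gene = 42L,
                       planted_logfc = 2, n_direct_pairs = 8L,
                       coupling_strength = 0.8, decoy_factor = 10L,
                       baseline_sdlog = 1.5, n_gene_sets = 10L,
                       age_jitter = FALSE, seed) {
  if (missing(seed)) stop("seed is mandatory for reproducibility")
  cfg <- list(n_per_group = as.integer(n_per_group),
              n_mirna = as.integer(n_mirna), n_gene = as.integer(n_gene),
              phi = phi,
              mirna_libsize_range = mirna_libsize_range,
              gene_libsize_range = gene_libsize_range,
              n_aa_mirna = as.integer(n_aa_mirna),
              n_aa_gene = as.integer(n_aa_gene),
              planted_logfc = planted_logfc,
              n_direct_pairs = as.integer(n_direct_pairs),
              coupling_strength = coupling_strength,
              decoy_factor = as.integer(decoy_factor),
              baseline_sdlog = baseline_sdlog,
              n_gene_sets = as.integer(n_gene_sets),
              age_jitter = isTRUE(age_jitter),
              seed = as.integer(seed))
  stopifnot(cfg$n_per_group >= 2L, cfg$phi >= 0,
            cfg$n_aa_mirna <= cfg$n_mirna,
            cfg$n_aa_gene + cfg$n_direct_pairs <= cfg$n_gene,
            cfg$n_direct_pairs == 0L || cfg$n_aa_mirna > 0L)
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate a coupled miRNA/mRNA aging cohort
#'
#' @param cfg a [sim_config()].
#' @return List with `mirna` and `gene` [count_matrix()]s, `samples`
#'   (sample table), `targetdb` (planted direct pairs plus decoys),
#'   `gene_sets` (fixture GMT collection: random sets plus one set
#'   holding the coupled targets), `truth` (planted feature ids with
#'   directions, direct pairs, per-feature baseline means and true
#'   logFCs) and the `config`.
#' @export
simulate_aging_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (exists(".Random.seed", envir = globalenv()))
    old_seed <- get(".Random.seed", envir = globalenv())
  else old_seed <- NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(cfg$seed)

  groups <- c("SR40", "SR50", "SR60", "SR70")
  rep_age <- c(SR40 = 40L, SR50 = 50L, SR60 = 60L, SR70 = 70L)
  score <- c(SR40 = -0.75, SR50 = -0.25, SR60 = 0.25, SR70 = 0.75)
  ns <- 4L * cfg$n_per_group
  samples <- data.frame(
    sample_id = sprintf("S%02d", seq_len(ns)),
    group = rep(groups, each = cfg$n_per_group),
    age = rep(rep_age, each = cfg$n_per_group),
    sex = rep_len(c("F", rep("M", cfg$n_per_group - 1L)), ns),
    stringsAsFactors = FALSE)
  if (cfg$age_jitter)
    samples$age <- samples$age + sample(-2:2, ns, replace = TRUE)
  samples <- sample_table(samples)
  s_vec <- score[as.character(samples$group)]

  sim_block <- function(n_feat, prefix, librange, planted_idx, directions,
                        extra_log2 = NULL) {
    # baseline CPM: mean CPM is 1e6 / n_feat so columns sum near 1e6
    meanlog <- log(1e6 / n_feat) - cfg$baseline_sdlog^2 / 2
    base <- stats::rlnorm(n_feat, meanlog = meanlog, sdlog = cfg$baseline_sdlog)
    # planted features get moderate abundance so truth is detectable at
    # n = 3 per group without dominating the library composition
    base[planted_idx] <- stats::rlnorm(length(planted_idx),
                                       meanlog = log(1.5e6 / n_feat), sdlog = 0.8)
    eff <- matrix(0, n_feat, ns)
    eff[planted_idx, ] <- outer(directions * cfg$planted_logfc, s_vec)
    if (!is.null(extra_log2)) eff <- eff + extra_log2
    cpm_mean <- base * 2^eff
    # compositional renormalization: proportions sum to one per sample
    cpm_mean <- sweep(cpm_mean, 2L, colSums(cpm_mean) / 1e6, "/")
    lib <- exp(stats::runif(ns, log(librange[1L]), log(librange[2L])))
    mu <- sweep(cpm_mean, 2L, lib / 1e6, "*")
    counts <- if (cfg$phi == 0) {
      matrix(stats::rpois(n_feat * ns, mu), n_feat, ns)
    } else {
      matrix(stats::rnbinom(n_feat * ns, mu = mu, size = 1 / cfg$phi), n_feat, ns)
    }
    dimnames(counts) <- list(sprintf("%s%0*d", prefix, nchar(n_feat), seq_len(n_feat)),
                             samples$sample_id)
    list(counts = counts, base = base, cpm_mean = cpm_mean, lib = lib)
  }

  # miRNAs: planted AA features, alternating direction (ceil-half up)
  aa_mir_idx <- seq_len(cfg$n_aa_mirna)
  mir_dir <- rep_len(c(1, -1), cfg$n_aa_mirna)
  mir <- sim_block(cfg$n_mirna, "miR-", cfg$mirna_libsize_range, aa_mir_idx, mir_dir)
  mir_ids <- rownames(mir$counts)

  # genes: planted AA genes first, then coupled targets of the AA miRNAs
  aa_gene_idx <- seq_len(cfg$n_aa_gene)
  gene_dir <- rep_len(c(1, -1), cfg$n_aa_gene)
  coupled_idx <- cfg$n_aa_gene + seq_len(cfg$n_direct_pairs)
  regulators <- if (cfg$n_direct_pairs > 0L)
    rep_len(aa_mir_idx, cfg$n_direct_pairs) else integer(0)
  extra <- NULL
  if (cfg$n_direct_pairs > 0L) {
    extra <- matrix(0, cfg$n_gene, ns)
    for (j in seq_along(coupled_idx)) {
      # latent log2-CPM of the regulator, centered across samples; the
      # baseline term cancels so only the age effect remains
      lat <- mir_dir[regulators[j]] * cfg$planted_logfc * s_vec
      extra[coupled_idx[j], ] <- -cfg$coupling_strength * (lat - mean(lat))
    }
  }
  gene <- sim_block(cfg$n_gene, "gene-", cfg$gene_libsize_range, aa_gene_idx,
                    gene_dir, extra_log2 = extra)
  gene_ids <- rownames(gene$counts)

  direct_pairs <- data.frame(mirna = mir_ids[regulators],
                             gene = gene_ids[coupled_idx],
                             stringsAsFactors = FALSE)
  # decoy DB pairs: uniform over non-coupled (AA-miRNA, gene) combinations
  n_decoy <- cfg$decoy_factor * cfg$n_direct_pairs
  decoys <- data.frame(mirna = character(0), gene = character(0))
  if (n_decoy > 0L && cfg$n_aa_mirna > 0L) {
    pool_gene <- setdiff(gene_ids, direct_pairs$gene)
    decoys <- unique(data.frame(
      mirna = sample(mir_ids[aa_mir_idx], n_decoy, replace = TRUE),
      gene = sample(pool_gene, n_decoy, replace = TRUE),
      stringsAsFactors = FALSE))
  }
  db <- rbind(direct_pairs, decoys)
  targetdb <- if (nrow(db)) {
    db$source <- "synthetic"
    db$evidence <- "predicted"
    target_db(db)
  } else target_db(data.frame(mirna = character(0), gene = character(0),
                              source = character(0), evidence = character(0)))

  # fixture gene sets: random sets plus one set enriched for the coupled
  # targets (so ORA has a planted positive)
  sets <- list()
  set_size <- max(10L, min(25L, cfg$n_gene %/% 4L))
  for (i in seq_len(cfg$n_gene_sets))
    sets[[sprintf("SET%02d", i)]] <- sample(gene_ids, set_size)
  if (cfg$n_direct_pairs > 0L)
    sets[["COUPLED_TARGETS"]] <- unique(c(direct_pairs$gene,
                                          sample(gene_ids, max(2L, set_size %/% 2L))))
  attr(sets, "description") <- stats::setNames(
    c(rep("random synthetic set", cfg$n_gene_sets),
      if (cfg$n_direct_pairs > 0L) "planted coupled targets"),
    names(sets))

  truth <- list(
    aa_mirna = data.frame(feature = mir_ids[aa_mir_idx],
                          direction = ifelse(mir_dir > 0, "+", "-"),
                          logfc = mir_dir * cfg$planted_logfc,
                          stringsAsFactors = FALSE),
    aa_gene = data.frame(feature = gene_ids[aa_gene_idx],
                         direction = ifelse(gene_dir > 0, "+", "-"),
                         logfc = gene_dir * cfg$planted_logfc,
                         stringsAsFactors = FALSE),
    direct_pairs = direct_pairs,
    mirna_baseline_cpm = stats::setNames(mir$base, mir_ids),
    gene_baseline_cpm = stats::setNames(gene$base, gene_ids),
    mirna_true_mean_cpm = mir$cpm_mean,
    gene_true_mean_cpm = gene$cpm_mean,
    mirna_libsizes = stats::setNames(mir$lib, samples$sample_id),
    gene_libsizes = stats::setNames(gene$lib, samples$sample_id))

  list(mirna = count_matrix(mir$counts, "miRNA"),
       gene = count_matrix(gene$counts, "gene"),
       samples = samples, targetdb = targetdb, gene_sets = sets,
       truth = truth, config = cfg)
}

#' Write a simulated bundle as pipeline input files
#'
#' Writes the exact TSV/GMT inputs the analysis consumes plus the
#' planted-truth tables: `mirna_counts.tsv`, `gene_counts.tsv`,
#' `samples.tsv`, `targets.tsv`, `genesets.gmt`, `truth_mirna.tsv`,
#' `truth_gene.tsv`, `truth_pairs.tsv`. Byte-identical across runs with
#' the same config.
#'
#' @param bundle output of [simulate_aging_cohort()].
#' @param dir output directory (created if missing).
#' @return Invisibly, the written file paths.
#' @export
write_fixture <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("mirna_counts.tsv", "gene_counts.tsv", "samples.tsv",
                            "targets.tsv", "genesets.gmt", "truth_mirna.tsv",
                            "truth_gene.tsv", "truth_pairs.tsv"))
  write_count_matrix(bundle$mirna, paths[1L])
  write_count_matrix(bundle$gene, paths[2L])
  smp <- bundle$samples
  smp$group <- as.character(smp$group)
  write_table(smp, paths[3L])
  write_table(as.data.frame(bundle$targetdb), paths[4L])
  write_gmt(bundle$gene_sets, paths[5L])
  write_table(bundle$truth$aa_mirna, paths[6L])
  write_table(bundle$truth$aa_gene, paths[7L])
  write_table(bundle$truth$direct_pairs, paths[8L])
  invisible(paths)
}
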