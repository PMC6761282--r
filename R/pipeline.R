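#' Run the full integrative miRNA-mRNA aging analysis
#'
#' Chains every stage: per-contrast NB GLM likelihood-ratio tests on
#' both count matrices, Fisher meta-analysis with BH FDR, selection of
#' age-associated miRNAs (nominal p in both contrasts, consistent
#' direction) and genes (FDR on the combined p, consistent direction),
#' all-gene Pearson correlation for each selected miRNA, the
#' three-condition valid-pair rule, direct/indirect classification
#' against the target database, per-miRNA target-set enrichment, the
#' bipartite network, and (when gene sets are supplied) pathway
#' over-representation of the network genes. Counts in and out of every
#' filter are reported via `message()`.
#'
#' @param mirna,gene [count_matrix()] objects sharing the sample set.
#' @param samples sample table covering all samples.
#' @param targetdb a `target_db` of miRNA target predictions.
#' @param gene_sets optional gene-set collection (see [read_gmt()]) for
#'   pathway ORA.
#' @param contrasts the two reciprocal contrasts
#'   (default [default_contrasts()]).
#' @param rule a [selection_rule()].
#' @param p_cor_cut correlation significance threshold (default 0.05).
#' @param prior_count logCPM/reporting prior (default 0.5).
#' @param phi fixed dispersion(s), or `NULL` to estimate per contrast
#'   (Cox-Reid grid).
#' @param alias optional gene annotation alias table passed to
#'   [valid_pairs()].
#' @return List with elements `meta_mirna`, `meta_gene`, `aa_mirna`,
#'   `aa_gene` (each a `selected` + `discordant` list), `correlations`,
#'   `pairs`, `enrichment`, `network`, `pathways` (`NULL` without gene
#'   sets or with an empty network) and `params`.
#' @export
run_aging_pipeline <- function(mirna, gene, samples, targetdb,
                               gene_sets = NULL,
                               contrasts = default_contrasts(),
                               rule = selection_rule(), p_cor_cut = 0.05,
                               prior_count = 0.5, phi = NULL, alias = NULL) {
  message("[diffexp] miRNA matrix: ", nrow(mirna), " features x ", ncol(mirna), " samples")
  de_mir <- run_two_set_de(mirna, samples, contrasts, phi = phi, prior_count = prior_count)
  message("[diffexp] gene matrix: ", nrow(gene), " features x ", ncol(gene), " samples")
  de_gene <- run_two_set_de(gene, samples, contrasts, phi = phi, prior_count = prior_count)

  meta_mir <- meta_combine(de_mir)
  meta_gene <- meta_combine(de_gene)
  aa_mir <- select_aa_features(meta_mir, rule, mode = "nominal_both")
  aa_gene <- select_aa_features(meta_gene, rule, mode = "fdr_meta")
  message("[select] miRNAs: ", nrow(meta_mir), " tested -> ",
          nrow(aa_mir$selected), " selected (", nrow(aa_mir$discordant), " discordant)")
  message("[select] genes: ", nrow(meta_gene), " tested -> ",
          sum(meta_gene$fdr < rule$fdr_cut, na.rm = TRUE), " at FDR < ", rule$fdr_cut,
          " -> ", nrow(aa_gene$selected), " direction-consistent")

  mir_lcpm <- log_cpm(mirna, prior_count)
  gene_lcpm <- log_cpm(gene, prior_count)
  tested_genes <- meta_gene$feature
  sel_mir_ids <- aa_mir$selected$feature

  if (length(sel_mir_ids) > 0L) {
    cors <- correlate_all(mir_lcpm[sel_mir_ids, , drop = FALSE],
                          gene_lcpm[tested_genes, , drop = FALSE])
    message("[correlate] ", length(sel_mir_ids), " miRNAs x ",
            length(tested_genes), " genes -> ", nrow(cors), " pairs (",
            sum(cors$p_cor < p_cor_cut), " at p < ", p_cor_cut, ")")
    pairs <- valid_pairs(aa_mir$selected, aa_gene$selected, cors,
                         p_cor_cut = p_cor_cut, alias = alias)
    message("[integrate] ", nrow(aa_mir$selected) * nrow(aa_gene$selected),
            " candidate pairs -> ", nrow(pairs), " valid (",
            attr(pairs, "n_unannotated"), " unannotated excluded)")
    pairs <- classify_pairs(pairs, targetdb)
    message("[integrate] direct: ", sum(pairs$interaction == "direct"),
            ", indirect: ", sum(pairs$interaction == "indirect"))
    enrichment <- enrich_all_mirnas(sel_mir_ids, targetdb, aa_gene$selected$feature,
                                    tested_genes, cors, p_cor_cut)
  } else {
    message("[correlate] no selected miRNAs; skipping integration")
    cors <- data.frame(mirna = character(0), gene = character(0),
                       r = numeric(0), n = integer(0), p_cor = numeric(0))
    pairs <- data.frame()
    enrichment <- data.frame()
  }

  network <- if (nrow(pairs)) build_network(pairs) else igraph::make_empty_graph(directed = FALSE)
  pathways <- NULL
  if (!is.null(gene_sets) && nrow(pairs)) {
    pathways <- ora(unique(pairs$gene), gene_sets, tested = tested_genes)
    message("[pathways] ", nrow(pathways), " sets tested, ",
            sum(pathways$q < 0.05), " at q < 0.05")
  }

  list(meta_mirna = meta_mir, meta_gene = meta_gene,
       aa_mirna = aa_mir, aa_gene = aa_gene,
       correlations = cors, pairs = pairs, enrichment = enrichment,
       network = network, pathways = pathways,
       params = list(rule = rule, p_cor_cut = p_cor_cut,
                     prior_count = prior_count,
                     phi = c(attr(de_mir, "phi"), attr(de_gene, "phi"))))
}

#' Write the pipeline's result tables as TSV files
#'
#' @param res result of [run_aging_pipeline()].
#' @param dir output directory (created if missing).
#' @return Invisibly, the written paths.
#' @export
write_pipeline_results <- function(res, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  out <- character(0)
  wt <- function(tab, name) {
    p <- file.path(dir, name)
    write_table(tab, p)
    out <<- c(out, p)
  }
  wt(res$meta_mirna, "meta_mirna.tsv")
  wt(res$meta_gene, "meta_gene.tsv")
  wt(res$aa_mirna$selected, "aa_mirna.tsv")
  wt(res$aa_mirna$discordant, "aa_mirna_discordant.tsv")
  wt(res$aa_gene$selected, "aa_gene.tsv")
  wt(res$aa_gene$discordant, "aa_gene_discordant.tsv")
  wt(res$correlations, "correlations.tsv")
  if (nrow(res$pairs)) wt(res$pairs, "pairs.tsv")
  if (nrow(res$enrichment)) wt(res$enrichment, "target_enrichment.tsv")
  if (!is.null(res$pathways)) wt(res$pathways, "pathways.tsv")
  if (igraph::ecount(res$network) > 0L) {
    export_network(res$network, file.path(dir, "network.sif"), "SIF")
    export_network(res$network, file.path(dir, "network.graphml"), "GraphML")
    out <- c(out, file.path(dir, c("network.sif", "network.graphml")))
  }
  invisible(out)
}
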