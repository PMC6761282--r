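#' Apply the three-condition valid-pair rule
#'
#' A (miRNA, gene) pair is a valid age-associated interaction when
#' (i) both the miRNA and the gene were selected as age-associated,
#' (ii) their expression correlates at p < `p_cor_cut`, and
#' (iii) the correlation sign is consistent with the two features'
#' directions of effect: `sign(r) = sign(logFC_mirna) * sign(logFC_gene)`.
#' Pairs whose gene lacks an entry in the optional annotation alias table
#' are excluded and counted (`n_unannotated` attribute). An exact r = 0
#' cannot pass condition (ii) but is rejected with a warning if seen.
#'
#' @param aa_mirnas selected miRNA table (from [select_aa_features()];
#'   needs `feature`, `logFC1`, `p_fisher`, `direction`).
#' @param aa_genes selected gene table (same columns plus `fdr`).
#' @param correlations table from [correlate_all()] covering all
#'   (AA-miRNA, AA-gene) pairs.
#' @param p_cor_cut correlation significance threshold (default 0.05).
#' @param alias optional two-column data.frame (`gene`, `alias`); genes
#'   without an alias are dropped from pair outputs.
#' @return data.frame of valid pairs with the columns of Table-style
#'   output: `mirna`, `gene`, `direction_mirna`, `p_fisher_mirna`, `r`,
#'   `p_cor`, `direction_gene`, `p_fisher_gene`, `fdr_gene`.
#' @export
valid_pairs <- function(aa_mirnas, aa_genes, correlations, p_cor_cut = 0.05,
                        alias = NULL) {
  stopifnot(p_cor_cut > 0, p_cor_cut < 1)
  cand <- expand.grid(mirna = aa_mirnas$feature, gene = aa_genes$feature,
                      stringsAsFactors = FALSE)
  key <- paste(cand$mirna, cand$gene, sep = "\r")
  ckey <- paste(correlations$mirna, correlations$gene, sep = "\r")
  hit <- match(key, ckey)
  if (anyNA(hit))
    stop("missing correlation for ", sum(is.na(hit)),
         " candidate pair(s): incomplete upstream run")
  cand$r <- correlations$r[hit]
  cand$p_cor <- correlations$p_cor[hit]
  im <- match(cand$mirna, aa_mirnas$feature)
  ig <- match(cand$gene, aa_genes$feature)
  cand$direction_mirna <- aa_mirnas$direction[im]
  cand$p_fisher_mirna <- aa_mirnas$p_fisher[im]
  cand$direction_gene <- aa_genes$direction[ig]
  cand$p_fisher_gene <- aa_genes$p_fisher[ig]
  cand$fdr_gene <- aa_genes$fdr[ig]

  if (any(cand$r == 0 & cand$p_cor < p_cor_cut))
    warning("pair with exact r = 0 rejected (sign undefined)")
  sgn <- function(d) ifelse(substr(d, 1L, 1L) == "-", -1, 1)
  keep <- cand$p_cor < p_cor_cut &
    cand$r != 0 &
    sign(cand$r) == sgn(cand$direction_mirna) * sgn(cand$direction_gene)
  out <- cand[keep, , drop = FALSE]

  n_unannotated <- 0L
  if (!is.null(alias)) {
    known <- out$gene %in% alias$gene
    n_unannotated <- sum(!known)
    if (n_unannotated > 0)
      message("excluding ", n_unannotated, " pair(s) with unannotated gene names")
    out <- out[known, , drop = FALSE]
  }
  out <- out[order(out$mirna, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_unannotated") <- n_unannotated
  out
}

#' Classify valid pairs as direct or indirect interactions
#'
#' A pair is a *direct* interaction when the gene is a predicted target
#' of the miRNA in the target database AND the correlation is negative
#' (the repression signature); otherwise it is *indirect*.
#' Database-predicted pairs with positive correlation are labelled
#' indirect and flagged `predicted_positive`. Each pair also gets its
#' correlation-type label (`up-up`, `up-down`, `down-up`, `down-down`)
#' from the two features' directions.
#'
#' @param pairs table from [valid_pairs()].
#' @param targetdb a `target_db` (see [read_target_db()]).
#' @param evidence passed to [target_genes()]: `"any"` or
#'   `"validated"`.
#' @return The input with `type_label`, `interaction`,
#'   `predicted_positive` appended.
#' @export
classify_pairs <- function(pairs, targetdb, evidence = c("any", "validated")) {
  evidence <- match.arg(evidence)
  word <- function(d) ifelse(substr(d, 1L, 1L) == "-", "down", "up")
  pairs$type_label <- paste(word(pairs$direction_mirna), word(pairs$direction_gene), sep = "-")
  in_db <- vapply(seq_len(nrow(pairs)), function(i)
    pairs$gene[i] %in% target_genes(targetdb, pairs$mirna[i], evidence), TRUE)
  pairs$interaction <- ifelse(in_db & pairs$r < 0, "direct", "indirect")
  pairs$predicted_positive <- in_db & pairs$r > 0
  pairs
}

#' Hypergeometric enrichment of a miRNA's target set in the AA-genes
#'
#' Tests whether the miRNA's predicted targets overlap the selected
#' age-associated genes more than expected by chance:
#' fold change `(k / n_targets) / (K / N)` and upper-tail hypergeometric
#' `P(X >= k)` drawing `n_targets` from a universe of `N` genes of which
#' `K` are age-associated. An empty target set yields fold change 0,
#' p = 1 and `flagged = TRUE`.
#'
#' @param targets character vector: the miRNA's target genes within the
#'   universe.
#' @param aa_genes character vector of selected age-associated genes.
#' @param universe_size number of genes tested (N).
#' @return List: `n_targets`, `k`, `K`, `N`, `fold_change`, `p_hyper`,
#'   `flagged`.
#' @export
target_enrichment <- function(targets, aa_genes, universe_size) {
  targets <- unique(targets)
  aa_genes <- unique(aa_genes)
  n <- length(targets)
  K <- length(aa_genes)
  N <- universe_size
  stopifnot(N >= K, N >= n)
  if (n == 0L)
    return(list(n_targets = 0L, k = 0L, K = K, N = N,
                fold_change = 0, p_hyper = 1, flagged = TRUE))
  k <- length(intersect(targets, aa_genes))
  list(n_targets = n, k = k, K = K, N = N,
       fold_change = (k / n) / (K / N),
       p_hyper = stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE),
       flagged = FALSE)
}

#' Target-set enrichment for every miRNA, split by interaction scope
#'
#' For each selected miRNA, tests its database targets among the
#' age-associated genes separately for the direct scope (database
#' targets) and the indirect scope (non-target genes correlated with the
#' miRNA), mirroring the direct/indirect target summary table.
#'
#' @param aa_mirnas character vector of selected miRNA ids.
#' @param targetdb a `target_db`.
#' @param aa_genes character vector of selected age-associated genes.
#' @param universe character vector of all tested genes.
#' @param correlations table from [correlate_all()] (needed for the
#'   indirect scope: genes correlated at `p_cor_cut` but not predicted
#'   targets).
#' @param p_cor_cut correlation threshold defining the indirect scope.
#' @return data.frame with one row per (miRNA, scope).
#' @export
enrich_all_mirnas <- function(aa_mirnas, targetdb, aa_genes, universe,
                              correlations, p_cor_cut = 0.05) {
  rows <- list()
  for (m in sort(aa_mirnas)) {
    tg <- intersect(target_genes(targetdb, m), universe)
    cor_m <- correlations[correlations$mirna == m & correlations$p_cor < p_cor_cut, ]
    indirect <- setdiff(intersect(cor_m$gene, universe), tg)
    for (scope in c("direct", "indirect")) {
      set <- if (scope == "direct") tg else indirect
      e <- target_enrichment(set, intersect(aa_genes, universe), length(universe))
      rows[[length(rows) + 1L]] <- data.frame(
        mirna = m, scope = scope, n_targets = e$n_targets, k = e$k,
        K = e$K, N = e$N, fold_change = e$fold_change, p_hyper = e$p_hyper,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
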