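#' Over-representation analysis against gene-set collections
#'
#' Upper-tail hypergeometric test of a query gene set against each
#' supplied set, with BH adjustment across all tested sets. The universe
#' defaults to the union of all gene-set members intersected with the
#' supplied `tested` genes (when given); query genes outside the
#' universe are dropped with a logged count. Results are sorted by
#' ascending p, ties broken by set id, so output order is deterministic.
#'
#' @param query_genes character vector of query gene ids.
#' @param sets named list of gene sets (see [read_gmt()]).
#' @param universe optional explicit universe; default described above.
#' @param tested optional vector of all genes measured by the assay,
#'   intersected into the default universe.
#' @param min_overlap report only sets with at least this many query
#'   members (default 0: all sets, zero-overlap sets get p = 1).
#' @return data.frame: `set_id`, `description`, `k`, `n_set`, `K`, `N`,
#'   `p`, `q`.
#' @export
ora <- function(query_genes, sets, universe = NULL, tested = NULL, min_overlap = 0L) {
  desc <- attr(sets, "description")
  if (is.null(desc)) desc <- stats::setNames(rep(NA_character_, length(sets)), names(sets))
  if (is.null(universe)) {
    universe <- unique(unlist(sets, use.names = FALSE))
    if (!is.null(tested)) universe <- intersect(universe, tested)
  }
  universe <- unique(universe)
  q0 <- unique(query_genes)
  query <- intersect(q0, universe)
  if (length(query) < length(q0))
    message("dropping ", length(q0) - length(query), " query gene(s) outside the universe")
  if (length(query) == 0L) stop("empty query after intersecting with the universe")
  N <- length(universe)
  K <- length(query)
  rows <- lapply(sort(names(sets)), function(id) {
    members <- intersect(sets[[id]], universe)
    n_set <- length(members)
    k <- length(intersect(members, query))
    p <- if (n_set == 0L) 1 else
      stats::phyper(k - 1L, K, N - K, n_set, lower.tail = FALSE)
    data.frame(set_id = id, description = desc[[id]], k = k, n_set = n_set,
               K = K, N = N, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p)
  out <- out[out$k >= min_overlap, , drop = FALSE]
  out <- out[order(out$p, out$set_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build the bipartite miRNA-mRNA interaction network
#'
#' One node per distinct miRNA and gene, one edge per classified pair.
#' Node attributes: `kind` (miRNA/gene) and `direction` (up/down with
#' age); edge attributes: `sign` of the correlation and `interaction`
#' (direct/indirect). Duplicate (miRNA, gene) pairs are collapsed to one
#' edge with a logged count.
#'
#' @param pairs table from [classify_pairs()].
#' @return An [igraph::igraph] bipartite graph.
#' @export
build_network <- function(pairs) {
  dup <- duplicated(pairs[c("mirna", "gene")])
  if (any(dup)) {
    message("collapsing ", sum(dup), " duplicate pair(s) to single edges")
    pairs <- pairs[!dup, , drop = FALSE]
  }
  word <- function(d) ifelse(substr(d, 1L, 1L) == "-", "down", "up")
  mirs <- sort(unique(pairs$mirna))
  genes <- sort(unique(pairs$gene))
  nodes <- data.frame(
    name = c(mirs, genes),
    kind = c(rep("miRNA", length(mirs)), rep("gene", length(genes))),
    direction = c(word(pairs$direction_mirna[match(mirs, pairs$mirna)]),
                  word(pairs$direction_gene[match(genes, pairs$gene)])),
    stringsAsFactors = FALSE)
  edges <- data.frame(
    from = pairs$mirna, to = pairs$gene,
    sign = ifelse(pairs$r < 0, "-", "+"),
    interaction = pairs$interaction,
    stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE, vertices = nodes)
  igraph::V(g)$type <- igraph::V(g)$kind == "gene"  # bipartite marker
  g
}

#' Export a network for visualization tools
#'
#' `SIF` writes one line per edge, `source <interaction> target`,
#' loadable by Cytoscape; `GraphML` (via igraph) carries all node and
#' edge attributes and round-trips through [igraph::read_graph()].
#' An empty graph yields a valid empty file.
#'
#' @param g graph from [build_network()].
#' @param path output file path.
#' @param format `"SIF"` or `"GraphML"`.
#' @export
export_network <- function(g, path, format = c("SIF", "GraphML")) {
  format <- match.arg(format)
  if (format == "SIF") {
    if (igraph::ecount(g) == 0L) {
      writeLines(character(0), path)
      return(invisible(path))
    }
    el <- igraph::as_edgelist(g)
    writeLines(paste(el[, 1L], igraph::E(g)$interaction, el[, 2L]), path)
  } else {
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}
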