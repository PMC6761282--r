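#!/usr/bin/env Rscript
# Stage 6: network export and pathway over-representation.
#
# The classified pairs form a bipartite miRNA-gene network, exported as
# SIF and GraphML for Cytoscape-style viewers. Genes in the network are
# tested for over-representation in the supplied gene sets
# (hypergeometric upper tail, BH-adjusted across sets).
library(agemir)

if (!file.exists(file.path("results", "pairs.tsv")))
  stop("missing results/pairs.tsv - run analysis/05_integrate.R first")

sim <- file.path("results", "sim")
pairs <- read_tsv(file.path("results", "pairs.tsv"))
meta_gene <- read_tsv(file.path("results", "meta_gene.tsv"))
sets <- read_gmt(file.path(sim, "genesets.gmt"))

g <- build_network(pairs)
export_network(g, file.path("results", "network.sif"), "SIF")
export_network(g, file.path("results", "network.graphml"), "GraphML")
n_mir <- sum(igraph::V(g)$kind == "miRNA")
cat("Network:", igraph::vcount(g), "nodes (", n_mir, "miRNAs,",
    igraph::vcount(g) - n_mir, "genes ),", igraph::ecount(g), "edges\n")

pw <- ora(unique(pairs$gene), sets, tested = meta_gene$feature)
write_table(pw, file.path("results", "pathways.tsv"))
cat("Pathway ORA:", nrow(pw), "sets tested;",
    sum(pw$q < 0.05), "at q < 0.05\n")
if (any(pw$q < 0.05))
  cat("Top set:", pw$set_id[1], "( k =", pw$k[1], ", p =",
      signif(pw$p[1], 2), ", q =", signif(pw$q[1], 2), ")\n")
cat("Wrote results/network.sif, results/network.graphml, results/pathways.tsv\n")
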