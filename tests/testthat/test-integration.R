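mk_sel <- function(ids, dirs, p_fisher = 1e-4, fdr = NULL) {
  out <- data.frame(feature = ids, direction = dirs, p_fisher = p_fisher,
                    stringsAsFactors = FALSE)
  if (!is.null(fdr)) out$fdr <- fdr
  out
}

mk_cors <- function(mirnas, genes, r) {
  grid <- expand.grid(mirna = mirnas, gene = genes, stringsAsFactors = FALSE)
  grid <- grid[order(grid$mirna, grid$gene), ]
  grid$r <- r
  grid$n <- 12L
  grid$p_cor <- pearson_p(r, 12L)
  grid
}

test_that("the three-condition rule admits and rejects as specified", {
  mir <- mk_sel("m1", "++")
  gene <- mk_sel(c("gUp", "gDown"), c("++", "--"), fdr = c(0.01, 0.003))
  # m1 up; gDown down with strong negative correlation -> valid;
  # gUp up but negatively correlated -> sign mismatch
  cors <- mk_cors("m1", c("gDown", "gUp"), c(-0.84, -0.7))
  vp <- valid_pairs(mir, gene, cors)
  expect_equal(vp$gene, "gDown")
  expect_equal(vp$r, -0.84)
  expect_equal(vp$fdr_gene, 0.003)

  # weak correlation (p = 0.06-ish) rejected by condition (ii)
  r_weak <- -0.55  # p ~ 0.063 at n = 12
  expect_gt(pearson_p(r_weak, 12), 0.05)
  cors2 <- mk_cors("m1", c("gDown", "gUp"), c(r_weak, 0.9))
  vp2 <- valid_pairs(mir, gene, cors2)
  expect_false("gDown" %in% vp2$gene)
  expect_equal(vp2$gene, "gUp")  # ++ x ++ with r > 0 is consistent

  # missing correlation rows are an upstream error, not a silent skip
  expect_error(valid_pairs(mir, gene, cors[1, ]), "missing correlation")
})

test_that("unannotated genes are excluded from pair output and counted", {
  mir <- mk_sel("m1", "++")
  gene <- mk_sel(c("g1", "g2"), c("--", "--"), fdr = 0.01)
  cors <- mk_cors("m1", c("g1", "g2"), c(-0.8, -0.85))
  alias <- data.frame(gene = "g1", alias = "GENE1")
  expect_message(vp <- valid_pairs(mir, gene, cors, alias = alias),
                 "excluding 1 pair")
  expect_equal(vp$gene, "g1")
  expect_equal(attr(vp, "n_unannotated"), 1L)
})

test_that("classification needs both database membership and negative r", {
  mir <- mk_sel("m1", "++")
  gene <- mk_sel(c("gA", "gB", "gC"), c("--", "++", "--"), fdr = 0.01)
  cors <- mk_cors("m1", c("gA", "gB", "gC"), c(-0.8, 0.85, -0.9))
  db <- target_db(data.frame(mirna = c("m1", "m1"), gene = c("gA", "gB")))
  pairs <- classify_pairs(valid_pairs(mir, gene, cors), db)
  get <- function(g, col) pairs[[col]][pairs$gene == g]
  expect_equal(get("gA", "interaction"), "direct")        # in DB, r < 0
  expect_equal(get("gA", "type_label"), "up-down")
  expect_equal(get("gB", "interaction"), "indirect")      # in DB but r > 0
  expect_true(get("gB", "predicted_positive"))
  expect_equal(get("gB", "type_label"), "up-up")
  expect_equal(get("gC", "interaction"), "indirect")      # r < 0, not in DB
  # direct/indirect partition the valid pairs
  expect_setequal(pairs$interaction, c("direct", "indirect"))
  expect_equal(nrow(pairs), 3L)
})

test_that("target enrichment reproduces printed fold changes and edge cases", {
  # background 42 age-associated genes of 23,346 tested
  aa <- paste0("aa", 1:42)
  uni_n <- 23346L
  mk_targets <- function(n, k) c(aa[seq_len(k)], paste0("t", seq_len(n - k)))
  e1 <- target_enrichment(mk_targets(131, 1), aa, uni_n)
  expect_equal(round(e1$fold_change, 2), 4.24)
  e2 <- target_enrichment(mk_targets(618, 5), aa, uni_n)
  expect_equal(round(e2$fold_change, 2), 4.50)
  e3 <- target_enrichment(mk_targets(45, 0), aa, uni_n)
  expect_equal(e3$fold_change, 0)
  expect_equal(e3$p_hyper, 1)

  e0 <- target_enrichment(character(0), aa, uni_n)
  expect_true(e0$flagged)
  expect_equal(e0$fold_change, 0)
  expect_equal(e0$p_hyper, 1)
})

test_that("hypergeometric tail matches brute-force subset enumeration", {
  # P(X >= 1 | N = 10, K = 3, n = 2) = 1 - C(7,2)/C(10,2) = 8/15
  e <- target_enrichment(c("a", "b"), c("s1", "s2", "s3"),  10L)
  expect_equal(e$p_hyper, 1, tolerance = 1e-12)  # disjoint labels: k = 0
  # enumerate all C(10, 2) draws explicitly
  pop <- c(paste0("s", 1:3), paste0("f", 1:7))
  draws <- combn(pop, 2)
  p_enum <- mean(colSums(matrix(draws %in% paste0("s", 1:3), 2)) >= 1)
  expect_equal(p_enum, 8 / 15, tolerance = 1e-12)
  e1 <- target_enrichment(c("s1", "f1"), paste0("s", 1:3), 10L)
  # implementation's P(X >= 1) for n = 2 draws must equal the enumeration
  expect_equal(phyper(0, 3, 7, 2, lower.tail = FALSE), p_enum, tolerance = 1e-12)
  expect_equal(e1$k, 1L)
})

test_that("enlarging the AA-gene set never decreases the overlap", {
  set.seed(61)
  targets <- paste0("g", sample(100, 30))
  aa <- paste0("g", sample(100, 10))
  k_small <- target_enrichment(targets, aa, 100L)$k
  aa_big <- union(aa, paste0("g", sample(100, 20)))
  expect_gte(target_enrichment(targets, aa_big, 100L)$k, k_small)
})

test_that("every emitted pair satisfies the sign-consistency invariant", {
  res <- tiny_pipeline()
  pairs <- res$pairs
  expect_gt(nrow(pairs), 0)
  sgn <- function(d) ifelse(substr(d, 1, 1) == "-", -1, 1)
  expect_true(all(sign(pairs$r) == sgn(pairs$direction_mirna) * sgn(pairs$direction_gene)))
  expect_true(all(pairs$p_cor < 0.05))
  # direct implies database membership and negative correlation
  direct <- pairs[pairs$interaction == "direct", ]
  expect_true(all(direct$r < 0))
  b <- tiny_bundle()
  in_db <- vapply(seq_len(nrow(direct)), function(i)
    direct$gene[i] %in% target_genes(b$targetdb, direct$mirna[i]), TRUE)
  expect_true(all(in_db))
})

test_that("planted repression couplings are recovered as direct pairs", {
  b <- tiny_bundle()
  res <- tiny_pipeline()
  planted <- paste(b$truth$direct_pairs$mirna, b$truth$direct_pairs$gene)
  direct <- res$pairs[res$pairs$interaction == "direct", ]
  hit <- planted %in% paste(direct$mirna, direct$gene)
  expect_gte(mean(hit), 0.8)
})
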