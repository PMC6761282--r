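test_that("identical groups give logFC 0, LR 0, p 1", {
  Y <- rbind(f1 = rep(10, 6), f2 = rep(25, 6))
  cm <- make_cm(Y)
  smp <- make_two_group_samples(3L)
  res <- fit_nb_glm_lrt(cm, smp, contrast("c", "SR60", "SR40"), phi = 0.1)
  expect_equal(res$logFC, c(0, 0), tolerance = 1e-8)
  expect_equal(res$LR, c(0, 0), tolerance = 1e-8)
  expect_equal(res$pvalue, c(1, 1), tolerance = 1e-8)
})

test_that("Poisson limit reproduces the closed-form group-mean LRT", {
  # equal library sizes (filler feature equalizes column totals)
  Y <- rbind(f1 = c(4, 6, 14, 26), filler = c(96, 94, 86, 74))
  cm <- make_cm(Y)
  smp <- make_two_group_samples(2L)
  res <- fit_nb_glm_lrt(cm, smp, contrast("c", "SR60", "SR40"), phi = 0,
                        prior_count = 0)
  # 2 * (10 ln(5/12.5) + 40 ln(20/12.5)); logFC = log2(20/5)
  lr_expected <- 2 * (10 * log(5 / 12.5) + 40 * log(20 / 12.5))
  expect_equal(res$LR[1], lr_expected, tolerance = 1e-6)
  expect_equal(res$logFC[1], 2, tolerance = 1e-6)
})

test_that("NB LRT matches a brute-force likelihood grid", {
  # frozen from maximizing the NB(phi = 0.5) log-likelihood per group
  # over a mean grid (step 5e-4): y1 = (3,7) vs y2 = (15,25)
  Y <- rbind(f1 = c(3, 7, 15, 25), filler = c(97, 93, 85, 75))
  cm <- make_cm(Y)
  smp <- make_two_group_samples(2L)
  res <- fit_nb_glm_lrt(cm, smp, contrast("c", "SR60", "SR40"), phi = 0.5)
  expect_equal(res$LR[1], 2.97849896657, tolerance = 1e-4)
})

test_that("NB GLM LRT agrees with edgeR glmFit/glmLRT", {
  set.seed(101)
  n <- 150L
  mu <- rlnorm(n, log(80), 1)
  fc <- 2^rnorm(n, 0, 0.8)
  Y <- cbind(matrix(rnbinom(3 * n, mu = mu, size = 5), n),
             matrix(rnbinom(3 * n, mu = mu * fc, size = 5), n))
  cm <- make_cm(Y)
  smp <- make_two_group_samples(3L)
  mine <- fit_nb_glm_lrt(cm, smp, contrast("c", "SR60", "SR40"), phi = 0.2)

  y <- edgeR::DGEList(counts = unclass(cm), group = rep(c("A", "B"), each = 3))
  fit <- edgeR::glmFit(y, model.matrix(~rep(0:1, each = 3)), dispersion = 0.2,
                       prior.count = 0)
  lrt <- edgeR::glmLRT(fit)
  expect_equal(mine$LR, lrt$table$LR, tolerance = 1e-6)
  expect_equal(mine$pvalue, lrt$table$PValue, tolerance = 1e-6)
  # reported logFC is prior-shrunken, so only near-equal to edgeR's raw one
  expect_equal(mine$logFC, lrt$table$logFC, tolerance = 0.1)
})

test_that("scaling all library sizes leaves LR and logFC unchanged", {
  set.seed(5)
  Y <- matrix(rnbinom(40 * 6, mu = 60, size = 10), 40)
  cm <- make_cm(Y)
  # filler row multiplies every column total by 5 without touching Y
  Y2 <- rbind(Y, filler = 4 * colSums(Y))
  rownames(Y2) <- c(rownames(cm), "filler")
  cm2 <- make_cm(Y2)
  smp <- make_two_group_samples(3L)
  ctr <- contrast("c", "SR60", "SR40")
  r1 <- fit_nb_glm_lrt(cm, smp, ctr, phi = 0.1)
  r2 <- fit_nb_glm_lrt(cm2, smp, ctr, phi = 0.1)
  keep <- match(r1$feature, r2$feature)
  expect_equal(r1$LR, r2$LR[keep], tolerance = 1e-6)
  expect_equal(r1$logFC, r2$logFC[keep], tolerance = 1e-6)
})

test_that("chi-square upper tail reproduces the printed per-contrast p-values", {
  # LR statistics and p-values as printed in the discovery table
  lr <- c(13.23, 6.49, 6.97, 4.34, 5.82, 5.05, 4.41, 6.34, 3.92, 6.13, 3.94, 5.00, 4.10, 4.02)
  p <- c(2.8e-4, 0.011, 0.0083, 0.037, 0.016, 0.025, 0.036, 0.012, 0.048, 0.013, 0.047, 0.025, 0.043, 0.045)
  expect_equal(signif(chi2_upper_tail(lr, 1L), 2), p)
  expect_equal(chi2_upper_tail(0, 1L), 1)
  expect_equal(chi2_upper_tail(0, 4L), 1)
  expect_error(chi2_upper_tail(-1, 1L), "negative")
})

test_that("p-values are uniform on null NB data", {
  set.seed(77)
  n <- 800L
  mu <- rlnorm(n, log(100), 1)
  Y <- matrix(rnbinom(6 * n, mu = mu, size = 10), n)
  cm <- make_cm(Y)
  smp <- make_two_group_samples(3L)
  res <- fit_nb_glm_lrt(cm, smp, contrast("c", "SR60", "SR40"), phi = 0.1)
  ks <- suppressWarnings(ks.test(res$pvalue, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("run_two_set_de ranks planted features on top in both contrasts", {
  b <- tiny_bundle()
  de <- suppressMessages(run_two_set_de(b$mirna, b$samples, phi = 0.1))
  planted <- b$truth$aa_mirna$feature
  top1 <- de$feature[order(de$p1)][seq_along(planted)]
  top2 <- de$feature[order(de$p2)][seq_along(planted)]
  expect_gte(sum(planted %in% top1), length(planted) - 1L)
  expect_gte(sum(planted %in% top2), length(planted) - 1L)
})

test_that("run_two_set_de is deterministic and rejects degenerate contrasts", {
  b <- tiny_bundle()
  d1 <- suppressMessages(run_two_set_de(b$mirna, b$samples, phi = 0.1))
  d2 <- suppressMessages(run_two_set_de(b$mirna, b$samples, phi = 0.1))
  expect_identical(d1, d2)
  expect_error(contrast("x", "SR60", "SR60"), "must differ")
  expect_error(
    suppressMessages(run_two_set_de(b$mirna, b$samples,
                                    list(contrast("a", "SR60", "SR40"),
                                         contrast("b", "SR70", "SR70")))))
})

test_that("all-zero features are skipped and logged, not tested", {
  Y <- rbind(f1 = c(5, 6, 9, 12, 11, 8), dead = rep(0, 6))
  cm <- make_cm(Y)
  smp <- make_two_group_samples(3L)
  expect_message(
    res <- fit_nb_glm_lrt(cm, smp, contrast("c", "SR60", "SR40"), phi = 0.1),
    "skipping 1 all-zero")
  expect_equal(res$feature, "f1")
  expect_equal(attr(res, "skipped"), "dead")
})
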