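test_that("count matrix TSV round-trips and library sizes are column sums", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("feature\ts1\ts2", "A\t1\t2", "B\t3\t4"), path)
  cm <- read_count_matrix(path, "gene")
  expect_equal(unname(unclass(cm)), matrix(c(1, 3, 2, 4), 2), ignore_attr = TRUE)
  expect_equal(library_sizes(cm), c(s1 = 4, s2 = 6))
  expect_equal(library_sizes(make_cm(matrix(7, 1, 1))), c(S01 = 7))

  out <- withr::local_tempfile(fileext = ".tsv")
  write_count_matrix(cm, out)
  expect_equal(unclass(read_count_matrix(out, "gene")), unclass(cm))
})

test_that("malformed count input is rejected, never coerced", {
  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines("feature\ts1", bad)
  expect_error(read_count_matrix(bad, "gene"), "no features")

  writeLines(c("feature\ts1\ts2", "A\t1\t-1"), bad)
  expect_error(read_count_matrix(bad, "gene"), "negative count.*'A'.*'s2'")

  writeLines(c("feature\ts1", "A\t1.5"), bad)
  expect_error(read_count_matrix(bad, "gene"), "non-integer")

  writeLines(c("feature\ts1", "A\tx"), bad)
  expect_error(read_count_matrix(bad, "gene"), "non-numeric")

  writeLines(c("feature\ts1", "A\t1", "A\t2"), bad)
  expect_error(read_count_matrix(bad, "gene"), "duplicate feature ids")

  expect_error(library_sizes(make_cm(matrix(c(1, 2, 0, 0), 2))), "zero total")
})

test_that("log_cpm matches the closed-form definition", {
  cm <- make_cm(matrix(c(100, 999900), 2, 1))
  lv <- log_cpm(cm, prior_count = 0.5)
  # hand-evaluated: log2((100 + 0.5) / (1e6 + 1) * 1e6)
  expect_equal(lv["f1", 1], 6.65105024848, tolerance = 1e-10)
  cm0 <- make_cm(matrix(c(0, 1e6), 2, 1))
  expect_equal(log_cpm(cm0, 0.5)["f1", 1], -1.00000144269, tolerance = 1e-9)
  expect_error(log_cpm(cm0, 0), "log of zero")
})

test_that("CPM without prior sums to 1e6 and log_cpm is monotone", {
  set.seed(1)
  cm <- make_cm(matrix(rpois(60, 50), 10, 6))
  expect_equal(unname(colSums(cpm(cm))), rep(1e6, 6), tolerance = 1e-6)

  # strictly increasing in count within a sample
  cm2 <- make_cm(matrix(c(0:4, rep(100, 5)), 5, 2))
  lv <- log_cpm(cm2, 0.5)
  expect_true(all(diff(lv[, 1]) > 0))
  # strictly decreasing in library size for a fixed count
  cm3 <- make_cm(matrix(c(10, 90, 10, 190), 2, 2))
  expect_true(log_cpm(cm3, 0.5)["f1", 2] < log_cpm(cm3, 0.5)["f1", 1])
})

test_that("sample table validates groups, sexes and age bands", {
  smp <- make_samples()
  expect_s3_class(smp$group, "factor")
  bad <- data.frame(sample_id = "X", group = "SR40", age = 45L, sex = "M")
  expect_error(sample_table(bad), "age outside group band")
  expect_silent(sample_table(bad, check_bands = FALSE))
  bad$age <- 40L; bad$group <- "SR45"
  expect_error(sample_table(bad), "unknown group")
})

test_that("target table deduplicates pairs keeping strongest evidence", {
  tab <- data.frame(mirna = c("m1", "m1", "m1", "m2"),
                    gene = c("g1", "g1", "g2", "g1"),
                    source = "s",
                    evidence = c("predicted", "validated", "predicted", "predicted"))
  db <- target_db(tab)
  expect_equal(nrow(db), 3L)
  expect_equal(db$evidence[db$mirna == "m1" & db$gene == "g1"], "validated")
  expect_setequal(target_genes(db, "m1"), c("g1", "g2"))
  expect_equal(target_genes(db, "m1", evidence = "validated"), "g1")
  expect_length(target_genes(db, "absent"), 0L)

  path <- withr::local_tempfile(fileext = ".tsv")
  write_table(tab, path)
  expect_equal(nrow(read_target_db(path)), 3L)
})

test_that("GMT files parse, reject malformed lines, and round-trip", {
  path <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("S1\tdesc\tG1\tG2", "S2\tother\tG3\tG4\tG5"), path)
  sets <- read_gmt(path)
  expect_equal(sets$S1, c("G1", "G2"))
  expect_equal(attr(sets, "description")[["S2"]], "other")

  out <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(sets, out)
  expect_equal(read_gmt(out), sets)

  writeLines("S1\tonlydesc", path)
  expect_error(read_gmt(path), "malformed GMT line")
  writeLines(character(0), path)
  expect_error(read_gmt(path), "empty GMT")
})

test_that("result tables round-trip through TSV at printed precision", {
  tab <- data.frame(feature = c("a", "b"), logFC = c(-3.2212345, 0.915),
                    pvalue = c(2.8e-04, 1.23456789e-10))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_table(tab, path)
  back <- read_tsv(path)
  expect_equal(back$feature, tab$feature)
  expect_equal(back$logFC, tab$logFC, tolerance = 1e-12)
  expect_equal(back$pvalue, tab$pvalue, tolerance = 1e-12)
})
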