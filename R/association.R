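#' Pearson product-moment correlation
#'
#' @param x,y numeric vectors of equal length >= 3; constant vectors are
#'   an error (r undefined).
#' @return The correlation coefficient in \[-1, 1\].
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("x and y differ in length")
  if (length(x) < 3L) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("constant vector: r undefined")
  stats::cor(x, y, method = "pearson")
}

#' Two-sided p-value for a Pearson correlation
#'
#' Exact t-based test: `t = r * sqrt(n - 2) / sqrt(1 - r^2)` with
#' `df = n - 2`. For |r| = 1 the statistic is infinite; p = 0 is
#' returned with an `exact_boundary` attribute rather than an error.
#'
#' @param r correlation coefficient(s) in \[-1, 1\].
#' @param n sample count (>= 3).
#' @return Two-sided p-value(s).
#' @export
pearson_p <- function(r, n) {
  if (n < 3L) stop("need n >= 3")
  if (any(abs(r) > 1)) stop("|r| > 1")
  p <- numeric(length(r))
  bnd <- abs(r) == 1
  t <- abs(r[!bnd]) * sqrt(n - 2) / sqrt(1 - r[!bnd]^2)
  p[!bnd] <- 2 * stats::pt(t, df = n - 2, lower.tail = FALSE)
  p[bnd] <- 0
  if (any(bnd)) attr(p, "exact_boundary") <- which(bnd)
  p
}

#' Correlate every selected miRNA with every gene
#'
#' Computes Pearson r (on logCPM) and its exact t-based p-value for each
#' (miRNA, gene) pair, with both matrices aligned on identical sample
#' ids. Output ordering is deterministic: by miRNA id, then gene id.
#'
#' @param mirna_expr logCPM matrix restricted to the age-associated
#'   miRNAs (features x samples).
#' @param gene_expr logCPM matrix of all genes (features x samples).
#' @return data.frame with columns `mirna`, `gene`, `r`, `n`, `p_cor`.
#' @export
correlate_all <- function(mirna_expr, gene_expr) {
  if (ncol(mirna_expr) != ncol(gene_expr) ||
      !identical(colnames(mirna_expr), colnames(gene_expr)))
    stop("sample sets/order differ between miRNA and gene matrices")
  n <- ncol(mirna_expr)
  if (n < 3L) stop("need at least 3 samples")
  mir_ids <- sort(rownames(mirna_expr))
  gene_ids <- sort(rownames(gene_expr))
  R <- stats::cor(t(mirna_expr[mir_ids, , drop = FALSE]),
                  t(gene_expr[gene_ids, , drop = FALSE]), method = "pearson")
  out <- data.frame(
    mirna = rep(mir_ids, each = length(gene_ids)),
    gene = rep(gene_ids, times = length(mir_ids)),
    r = as.vector(t(R)),
    n = n,
    stringsAsFactors = FALSE)
  out$p_cor <- pearson_p(out$r, n)
  attributes(out$p_cor) <- NULL
  out
}

#' Simple linear trend of expression with age
#'
#' Ordinary least squares of logCPM on age in years; the 95% confidence
#' interval on the slope uses the t quantile with df = n - 2.
#'
#' @param expr numeric vector of logCPM values.
#' @param ages numeric vector of ages (years), non-constant.
#' @return List with `slope`, `intercept`, `ci_low`, `ci_high`,
#'   `p_trend`.
#' @export
linear_trend <- function(expr, ages) {
  if (length(expr) != length(ages)) stop("expr and ages differ in length")
  if (length(expr) < 3L) stop("need at least 3 observations")
  if (stats::sd(ages) == 0) stop("constant ages: trend undefined")
  fit <- stats::lm(expr ~ ages)
  sm <- summary(fit)$coefficients
  ci <- stats::confint(fit, "ages", level = 0.95)
  list(slope = unname(sm["ages", "Estimate"]),
       intercept = unname(sm["(Intercept)", "Estimate"]),
       ci_low = unname(ci[1L]),
       ci_high = unname(ci[2L]),
       p_trend = unname(sm["ages", "Pr(>|t|)"]))
}

#' Linear age trends for a set of features
#' @param expr logCPM matrix (features x samples).
#' @param samples sample table supplying `age` per sample (matched by
#'   `sample_id` to the matrix columns).
#' @return data.frame: `feature`, `slope`, `ci_low`, `ci_high`,
#'   `p_trend`.
#' @export
linear_trends <- function(expr, samples) {
  ages <- samples$age[match(colnames(expr), samples$sample_id)]
  if (anyNA(ages)) stop("samples missing from the metadata table")
  rows <- lapply(rownames(expr), function(f) {
    tr <- linear_trend(expr[f, ], ages)
    data.frame(feature = f, slope = tr$slope, ci_low = tr$ci_low,
               ci_high = tr$ci_high, p_trend = tr$p_trend,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
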