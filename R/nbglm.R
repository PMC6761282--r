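#' Define a two-group contrast
#'
#' The study design tests two reciprocal decade-pair contrasts,
#' SR60 vs SR40 and SR70 vs SR50, so that a signal must replicate in two
#' disjoint sample sets before it is called age-associated.
#'
#' @param name contrast label, e.g. `"SR60_vs_SR40"`.
#' @param case older (case) group label.
#' @param ref younger (reference) group label.
#' @return A `contrast` list.
#' @export
contrast <- function(name, case, ref) {
  if (identical(case, ref)) stop("case and reference groups must differ")
  structure(list(name = name, case = case, ref = ref), class = "contrast")
}

#' Default reciprocal age contrasts
#' @return List of two [contrast()] objects: SR60 vs SR40 and SR70 vs SR50.
#' @export
default_contrasts <- function() {
  list(contrast("SR60_vs_SR40", "SR60", "SR40"),
       contrast("SR70_vs_SR50", "SR70", "SR50"))
}

# NB log-likelihood per feature (rows), valid for non-integer y (the
# lgamma form is needed because the reporting fit adds a 0.5 prior).
# phi = 0 is the Poisson limit.
nb_loglik_rows <- function(Y, mu, phi) {
  if (phi == 0) {
    ll <- Y * log(mu) - mu - lgamma(Y + 1)
  } else {
    r <- 1 / phi
    ll <- lgamma(Y + r) - lgamma(r) - lgamma(Y + 1) +
      Y * (log(mu) + log(phi) - log1p(phi * mu)) - r * log1p(phi * mu)
    ll[Y == 0] <- (-r * log1p(phi * mu))[Y == 0]  # avoid 0 * log(0)
  }
  rowSums(ll)
}

# Vectorized IRLS for an NB GLM with log link, shared design across
# features. X has 1 (null) or 2 (intercept + group) columns. Returns
# per-feature coefficients, fitted means, log-likelihood, convergence
# flag and log det(X'WX) (used by the Cox-Reid adjustment).
nb_glm_fit_rows <- function(Y, X, offset, phi, maxit = 50L, tol = 1e-8) {
  stopifnot(ncol(X) %in% c(1L, 2L), ncol(Y) == nrow(X))
  nf <- nrow(Y)
  ns <- ncol(Y)
  off <- matrix(offset, nf, ns, byrow = TRUE)
  # start at log((count + 0.5) / libsize)-scale means per design cell
  eta <- log(Y + 0.5) - off
  if (ncol(X) == 2L) {
    x1 <- X[, 2L]
    m_ref <- rowMeans(eta[, x1 == 0, drop = FALSE])
    m_case <- rowMeans(eta[, x1 == 1, drop = FALSE])
    beta <- cbind(m_ref, m_case - m_ref)
  } else {
    beta <- cbind(rowMeans(eta))
  }
  dev_old <- rep(Inf, nf)
  conv <- rep(FALSE, nf)
  logdet <- numeric(nf)
  for (it in seq_len(maxit)) {
    eta <- beta %*% t(X)
    eta <- pmin(pmax(eta, -30), 30)
    mu <- exp(eta + off)
    W <- mu / (1 + phi * mu)
    Z <- eta + (Y - mu) / mu
    if (ncol(X) == 2L) {
      x1m <- matrix(X[, 2L], nf, ns, byrow = TRUE)
      A11 <- rowSums(W)
      A12 <- rowSums(W * x1m)
      A22 <- rowSums(W * x1m * x1m)
      b1 <- rowSums(W * Z)
      b2 <- rowSums(W * x1m * Z)
      det <- A11 * A22 - A12 * A12
      det[det <= 0] <- NA_real_
      beta <- cbind((A22 * b1 - A12 * b2) / det,
                    (A11 * b2 - A12 * b1) / det)
      logdet <- log(det)
    } else {
      A11 <- rowSums(W)
      beta <- cbind(rowSums(W * Z) / A11)
      logdet <- log(A11)
    }
    eta <- pmin(pmax(beta %*% t(X), -30), 30)
    mu <- exp(eta + off)
    dev <- -2 * nb_loglik_rows(Y, mu, phi)
    conv <- abs(dev - dev_old) / (abs(dev) + 0.1) < tol
    dev_old <- dev
    if (all(conv, na.rm = TRUE)) break
  }
  bad <- !is.finite(rowSums(beta))
  conv[bad] <- FALSE
  list(beta = beta, mu = mu, ll = nb_loglik_rows(Y, mu, phi),
       converged = conv & !bad, logdet_xtwx = logdet)
}

#' Upper tail of the chi-square distribution
#'
#' The reference distribution of the likelihood-ratio statistic
#' (df = 1 per contrast) and of Fisher's combined statistic (df = 2k).
#'
#' @param stat non-negative statistic(s).
#' @param df positive integer degrees of freedom.
#' @return Upper-tail probability in (0, 1].
#' @export
chi2_upper_tail <- function(stat, df) {
  if (any(stat < 0)) stop("negative chi-square statistic")
  stopifnot(df >= 1)
  stats::pchisq(stat, df = df, lower.tail = FALSE)
}

#' Negative-binomial GLM likelihood-ratio test for one contrast
#'
#' Per feature, fits the full model (intercept + group indicator, natural
#' log library sizes as offsets) and the null model (intercept only) by
#' IRLS at a common dispersion `phi`, and tests the group coefficient
#' with LR = 2(ll_full - ll_null) against chi-square(df = 1). The
#' reported logFC comes from a refit with a 0.5 prior count added to the
#' counts (shrinkage for display stability); the test itself uses raw
#' counts. Features with all-zero counts across the contrast's samples
#' are skipped and counted in the `skipped` attribute.
#'
#' @param cm a [count_matrix()].
#' @param samples sample table (see [sample_table()]).
#' @param ctr a [contrast()].
#' @param phi common NB dispersion (>= 0; 0 is the Poisson limit).
#' @param prior_count prior for the reporting refit and for logCPM.
#' @return data.frame with columns `feature`, `logFC`, `logCPM`, `LR`,
#'   `pvalue`, `converged`; attribute `skipped` holds the dropped
#'   feature ids.
#' @export
fit_nb_glm_lrt <- function(cm, samples, ctr, phi, prior_count = 0.5) {
  stopifnot(phi >= 0)
  sel_case <- samples$sample_id[samples$group == ctr$case]
  sel_ref <- samples$sample_id[samples$group == ctr$ref]
  if (length(sel_case) == 0L || length(sel_ref) == 0L)
    stop("contrast group(s) absent from sample table: ", ctr$name)
  if (length(intersect(sel_case, sel_ref)) > 0L)
    stop("overlapping case/reference samples in contrast ", ctr$name)
  sel <- c(sel_ref, sel_case)
  if (!all(sel %in% colnames(cm))) stop("samples missing from count matrix")
  Y <- unclass(cm)[, sel, drop = FALSE]
  keep <- rowSums(Y) > 0
  skipped <- rownames(Y)[!keep]
  if (length(skipped))
    message(ctr$name, ": skipping ", length(skipped), " all-zero feature(s)")
  Y <- Y[keep, , drop = FALSE]
  if (nrow(Y) == 0L) stop("all features are zero across the contrast samples")
  off <- log(colSums(unclass(cm))[sel])
  X_full <- cbind(1, as.integer(sel %in% sel_case))
  X_null <- cbind(rep(1, length(sel)))

  full <- nb_glm_fit_rows(Y, X_full, off, phi)
  null <- nb_glm_fit_rows(Y, X_null, off, phi)
  LR <- pmax(0, 2 * (full$ll - null$ll))
  conv <- full$converged & null$converged
  p <- ifelse(conv, chi2_upper_tail(LR, 1L), NaN)

  shrunk <- nb_glm_fit_rows(Y + prior_count, X_full, off, phi)
  lcpm <- log_cpm(count_matrix(unclass(cm)[keep, sel, drop = FALSE],
                               attr(cm, "feature_kind")),
                  prior_count = prior_count)
  res <- data.frame(feature = rownames(Y),
                    logFC = shrunk$beta[, 2L] / log(2),
                    logCPM = rowMeans(lcpm),
                    LR = LR,
                    pvalue = p,
                    converged = conv,
                    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  attr(res, "skipped") <- skipped
  attr(res, "contrast") <- ctr$name
  res
}

#' Run both reciprocal contrasts and align results by feature
#'
#' @param cm a [count_matrix()].
#' @param samples sample table.
#' @param contrasts list of two [contrast()]s (default
#'   [default_contrasts()]).
#' @param phi common dispersion: a single value shared by both
#'   contrasts, a length-2 vector (one per contrast), or `NULL` to
#'   estimate one per contrast via [estimate_common_dispersion()].
#' @param prior_count prior count for reporting.
#' @return data.frame with per-feature columns from both contrasts
#'   (suffixes `1`, `2`) plus `logCPM_all`, the all-sample average
#'   abundance; features skipped in either contrast are dropped and
#'   counted in the `n_dropped` attribute.
#' @export
run_two_set_de <- function(cm, samples, contrasts = default_contrasts(),
                           phi = NULL, prior_count = 0.5) {
  stopifnot(length(contrasts) == 2L)
  for (ctr in contrasts) {
    if (length(intersect(samples$sample_id[samples$group == ctr$case],
                         samples$sample_id[samples$group == ctr$ref])))
      stop("overlapping groups in contrast ", ctr$name)
  }
  if (is.null(phi)) {
    phi <- vapply(contrasts, function(ctr)
      estimate_common_dispersion(cm, samples, ctr)$common_phi, 0)
  }
  phi <- rep_len(phi, 2L)
  r1 <- fit_nb_glm_lrt(cm, samples, contrasts[[1L]], phi[1L], prior_count)
  r2 <- fit_nb_glm_lrt(cm, samples, contrasts[[2L]], phi[2L], prior_count)
  common <- intersect(r1$feature, r2$feature)
  n_dropped <- length(union(r1$feature, r2$feature)) - length(common)
  if (n_dropped > 0)
    message("dropping ", n_dropped, " feature(s) untested in one contrast")
  r1 <- r1[match(common, r1$feature), ]
  r2 <- r2[match(common, r2$feature), ]
  lcpm_all <- log_cpm(cm, prior_count = prior_count)
  out <- data.frame(feature = common,
                    logFC1 = r1$logFC, logCPM1 = r1$logCPM, LR1 = r1$LR, p1 = r1$pvalue,
                    logFC2 = r2$logFC, logCPM2 = r2$logCPM, LR2 = r2$LR, p2 = r2$pvalue,
                    logCPM_all = rowMeans(lcpm_all)[common],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "phi") <- phi
  attr(out, "n_dropped") <- n_dropped
  attr(out, "contrasts") <- vapply(contrasts, `[[`, "", "name")
  out
}
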