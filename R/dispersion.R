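#' Estimate a common NB dispersion for one contrast
#'
#' The NB variance model is `var = mu + phi * mu^2`; a single `phi` is
#' shared by all features (no trended or tagwise shrinkage — with n = 3
#' per group there is little information for per-feature dispersions).
#'
#' `cox_reid_grid` maximizes the Cox-Reid adjusted profile likelihood
#' summed over features: for each candidate `phi` the full model
#' (intercept + group) is fitted to every feature and
#' `sum_f [ ll_f(phi) - 0.5 * log det(X' W_f X) ]`
#' is evaluated on a 41-point grid in log10(phi) over \[-4, 1\], followed
#' by a golden-section refinement inside the bracketing interval.
#' `method_of_moments` pools per-feature moment estimates; `fixed`
#' returns `fix_phi` unchanged.
#'
#' @param cm a [count_matrix()].
#' @param samples sample table.
#' @param ctr a [contrast()] naming the two groups to fit.
#' @param method one of `"cox_reid_grid"`, `"method_of_moments"`,
#'   `"fixed"`.
#' @param fix_phi the dispersion to return when `method = "fixed"`.
#' @return List with `common_phi` (>= 0) and `method`.
#' @export
estimate_common_dispersion <- function(cm, samples, ctr,
                                       method = c("cox_reid_grid", "method_of_moments", "fixed"),
                                       fix_phi = NULL) {
  method <- match.arg(method)
  if (method == "fixed") {
    stopifnot(!is.null(fix_phi), fix_phi >= 0)
    return(list(common_phi = fix_phi, method = method))
  }
  sel_case <- samples$sample_id[samples$group == ctr$case]
  sel_ref <- samples$sample_id[samples$group == ctr$ref]
  if (length(sel_case) < 2L || length(sel_ref) < 2L)
    stop("need >= 2 samples per group to estimate dispersion")
  sel <- c(sel_ref, sel_case)
  Y <- unclass(cm)[, sel, drop = FALSE]
  Y <- Y[rowSums(Y) > 0, , drop = FALSE]
  if (nrow(Y) == 0L) stop("all features constant (zero); cannot estimate dispersion")
  off <- log(colSums(unclass(cm))[sel])
  X <- cbind(1, as.integer(sel %in% sel_case))

  if (method == "method_of_moments") {
    # pooled within-group moments on the CPM scale; the Poisson part of
    # the count variance becomes m * 1e6 / libsize after CPM scaling
    grp <- X[, 2L]
    cp <- sweep(Y, 2L, exp(off), "/") * 1e6
    est <- numeric(0)
    for (g in c(0, 1)) {
      sub <- cp[, grp == g, drop = FALSE]
      m <- rowMeans(sub)
      v <- apply(sub, 1L, stats::var)
      ok <- m > 0
      lib <- mean(exp(off[grp == g]))
      est <- c(est, pmax(0, (v[ok] - m[ok] * 1e6 / lib) / m[ok]^2))
    }
    return(list(common_phi = mean(est), method = method))
  }

  apl <- function(log10phi) {
    fit <- nb_glm_fit_rows(Y, X, off, 10^log10phi)
    sum(fit$ll - 0.5 * fit$logdet_xtwx, na.rm = TRUE)
  }
  grid <- seq(-4, 1, length.out = 41L)
  vals <- vapply(grid, apl, 0)
  i <- which.max(vals)
  lo <- grid[max(1L, i - 1L)]
  hi <- grid[min(length(grid), i + 1L)]
  gr <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  x1 <- b - gr * (b - a); x2 <- a + gr * (b - a)
  f1 <- apl(x1); f2 <- apl(x2)
  while (b - a > 1e-4) {
    if (f1 < f2) {
      a <- x1; x1 <- x2; f1 <- f2
      x2 <- a + gr * (b - a); f2 <- apl(x2)
    } else {
      b <- x2; x2 <- x1; f2 <- f1
      x1 <- b - gr * (b - a); f1 <- apl(x1)
    }
  }
  list(common_phi = 10^((a + b) / 2), method = method)
}
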