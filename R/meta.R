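#' Fisher's method for combining p-values
#'
#' Combines k independent p-values with the statistic `-2 * sum(log(p))`
#' referred to chi-square with 2k degrees of freedom. Used here to merge
#' the two reciprocal age-contrast tests per feature into one overall
#' significance.
#'
#' @param pvalues vector of p-values in (0, 1].
#' @return List with `stat` and `p_combined`.
#' @export
fisher_combine <- function(pvalues) {
  if (length(pvalues) == 0L) stop("no p-values to combine")
  if (any(is.na(pvalues))) stop("NA p-value")
  if (any(pvalues > 1)) stop("p-value > 1")
  if (any(pvalues <= 0)) stop("p-value <= 0: infinite Fisher statistic")
  stat <- -2 * sum(log(pvalues))
  list(stat = stat, p_combined = chi2_upper_tail(stat, df = 2L * length(pvalues)))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up BH adjustment (delegates to [stats::p.adjust()]); adjusted
#' values are >= the raw ones, order-preserving and capped at 1.
#'
#' @param pvalues vector of p-values in \[0, 1\] (may be empty).
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(pvalues) {
  if (length(pvalues) == 0L) return(numeric(0))
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE)) stop("p-values outside [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Meta-analysis of the two reciprocal contrasts
#'
#' Takes the aligned two-contrast table from [run_two_set_de()] and adds,
#' per feature: the direction string (signs of the two logFCs), Fisher's
#' combined statistic and p-value (df = 4), the BH FDR over all tested
#' features, and the direction-consistency flag. Underflowed p-values of
#' exactly 0 are floored at 1e-300 before the log, with a warning. A
#' zero logFC contributes direction "+" (tie-break; a zero effect should
#' never pass the significance filters anyway).
#'
#' @param de table from [run_two_set_de()].
#' @return The input with columns `direction`, `fisher_stat`,
#'   `p_fisher`, `fdr`, `consistent` appended.
#' @export
meta_combine <- function(de) {
  stopifnot(all(c("feature", "logFC1", "p1", "logFC2", "p2") %in% names(de)))
  p1 <- de$p1
  p2 <- de$p2
  if (any(c(p1, p2) == 0, na.rm = TRUE)) {
    warning("p-value underflow: flooring at 1e-300 before Fisher's log")
    p1 <- pmax(p1, 1e-300)
    p2 <- pmax(p2, 1e-300)
  }
  if (any(de$logFC1 == 0 | de$logFC2 == 0, na.rm = TRUE))
    warning("zero logFC treated as direction '+'")
  sgn <- function(x) ifelse(x < 0, "-", "+")
  stat <- -2 * (log(p1) + log(p2))
  de$direction <- paste0(sgn(de$logFC1), sgn(de$logFC2))
  de$fisher_stat <- stat
  de$p_fisher <- chi2_upper_tail(stat, df = 4L)
  de$fdr <- bh_adjust(de$p_fisher)
  de$consistent <- de$direction %in% c("++", "--")
  de
}

#' Selection rule thresholds
#' @param nominal_p per-contrast p threshold (default 0.05).
#' @param fdr_cut threshold on the BH-adjusted Fisher p (default 0.05).
#' @param require_consistency require equal logFC signs in both
#'   contrasts (default TRUE).
#' @return A `selection_rule` list.
#' @export
selection_rule <- function(nominal_p = 0.05, fdr_cut = 0.05, require_consistency = TRUE) {
  stopifnot(nominal_p > 0, nominal_p < 1, fdr_cut > 0, fdr_cut < 1)
  structure(list(nominal_p = nominal_p, fdr_cut = fdr_cut,
                 require_consistency = require_consistency),
            class = "selection_rule")
}

#' Select age-associated features
#'
#' Two selection paths mirror the study's miRNA and gene criteria:
#' `nominal_both` keeps features with p < `nominal_p` in *both* contrasts
#' (the miRNA path); `fdr_meta` keeps features with BH-adjusted Fisher
#' p < `fdr_cut` (the gene path: FDR over all tested genes first, then
#' the consistency filter). In either mode, features passing every filter
#' except direction consistency are returned separately as `discordant`
#' rather than silently merged or dropped.
#'
#' @param meta table from [meta_combine()].
#' @param rule a [selection_rule()].
#' @param mode `"nominal_both"` or `"fdr_meta"`.
#' @return List of data.frames `selected` and `discordant`.
#' @export
select_aa_features <- function(meta, rule = selection_rule(),
                               mode = c("nominal_both", "fdr_meta")) {
  mode <- match.arg(mode)
  pass <- switch(mode,
                 nominal_both = meta$p1 < rule$nominal_p & meta$p2 < rule$nominal_p,
                 fdr_meta = meta$fdr < rule$fdr_cut)
  pass[is.na(pass)] <- FALSE
  if (rule$require_consistency) {
    selected <- meta[pass & meta$consistent, , drop = FALSE]
    discordant <- meta[pass & !meta$consistent, , drop = FALSE]
  } else {
    selected <- meta[pass, , drop = FALSE]
    discordant <- meta[0L, , drop = FALSE]
  }
  rownames(selected) <- rownames(discordant) <- NULL
  list(selected = selected, discordant = discordant)
}
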