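#' Construct a validated count matrix
#'
#' A `count_matrix` is an integer matrix of sequencing read counts
#' (features in rows, samples in columns) tagged with the kind of
#' feature it quantifies. All downstream differential-expression and
#' correlation steps start from this container.
#'
#' @param counts numeric matrix of non-negative integers with unique
#'   rownames (feature ids) and colnames (sample ids).
#' @param feature_kind `"miRNA"` or `"gene"`.
#' @return An object of class `count_matrix`: the integer matrix with a
#'   `feature_kind` attribute.
#' @export
count_matrix <- function(counts, feature_kind = c("miRNA", "gene")) {
  feature_kind <- match.arg(feature_kind)
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (nrow(counts) == 0L) stop("no features")
  if (ncol(counts) == 0L) stop("no samples")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must carry feature rownames and sample colnames")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate feature ids: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stop("duplicate sample ids")
  if (any(!is.finite(counts))) stop("non-finite count entries")
  if (any(counts < 0)) {
    bad <- which(counts < 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("negative count at feature '%s', sample '%s'",
                 rownames(counts)[bad[1L]], colnames(counts)[bad[2L]]))
  }
  if (any(counts != round(counts))) {
    bad <- which(counts != round(counts), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-integer count at feature '%s', sample '%s'",
                 rownames(counts)[bad[1L]], colnames(counts)[bad[2L]]))
  }
  storage.mode(counts) <- "double"  # counts can exceed .Machine$integer.max in libsums
  structure(counts, feature_kind = feature_kind, class = c("count_matrix", "matrix", "array"))
}

#' Read a count matrix from TSV
#'
#' Expects a header row of sample ids and a first column of feature ids.
#' Malformed cells (negative, non-integer, non-numeric) are an error that
#' names the offending feature and sample; duplicated feature ids are an
#' error. Nothing is silently coerced.
#'
#' @param path TSV file path.
#' @param feature_kind `"miRNA"` or `"gene"`.
#' @return A [count_matrix()].
#' @export
read_count_matrix <- function(path, feature_kind = c("miRNA", "gene")) {
  feature_kind <- match.arg(feature_kind)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                           colClasses = "character", quote = "")
  if (nrow(tab) == 0L) stop("no features in ", path)
  ids <- tab[[1L]]
  body <- tab[, -1L, drop = FALSE]
  num <- suppressWarnings(vapply(body, as.numeric, numeric(nrow(body))))
  if (!is.matrix(num)) num <- matrix(num, nrow = nrow(body), dimnames = list(NULL, colnames(body)))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-numeric count at feature '%s', sample '%s' in %s",
                 ids[bad[1L]], colnames(num)[bad[2L]], path))
  }
  rownames(num) <- ids
  count_matrix(num, feature_kind)
}

#' Per-sample library sizes
#'
#' Library size is the raw column total; it is the only between-sample
#' adjustment applied (no TMM-style factors; see `norm_factors` for a
#' plug-in hook).
#'
#' @param cm a [count_matrix()] (or any counts matrix).
#' @param norm_factors optional positive multipliers, one per sample,
#'   applied to the raw totals (defaults to 1, i.e. no extra
#'   normalization).
#' @return Named numeric vector of positive totals.
#' @export
library_sizes <- function(cm, norm_factors = NULL) {
  ls <- colSums(cm)
  if (!is.null(norm_factors)) {
    stopifnot(length(norm_factors) == length(ls), all(norm_factors > 0))
    ls <- ls * norm_factors
  }
  if (any(ls <= 0)) {
    stop("sample(s) with zero total counts cannot be normalized: ",
         paste(names(ls)[ls <= 0], collapse = ", "))
  }
  ls
}

#' log2 counts-per-million
#'
#' `logCPM[f, s] = log2((count[f, s] + prior) / (libsize[s] + 2 * prior) * 1e6)`,
#' the edgeR-style pseudo-count convention: the prior shrinks
#' log-abundances of low counts and keeps zeros finite.
#'
#' @param cm a [count_matrix()].
#' @param prior_count non-negative pseudo-count added to every cell
#'   (default 0.5).
#' @param norm_factors optional per-sample normalization multipliers.
#' @return Numeric matrix of log2 CPM with the input's dimnames.
#' @export
log_cpm <- function(cm, prior_count = 0.5, norm_factors = NULL) {
  stopifnot(is.numeric(prior_count), length(prior_count) == 1L, prior_count >= 0)
  ls <- library_sizes(cm, norm_factors)
  if (prior_count == 0 && any(cm == 0))
    stop("prior_count = 0 with zero counts: log of zero")
  lv <- log2(sweep(unclass(cm) + prior_count, 2L, ls + 2 * prior_count, "/") * 1e6)
  attr(lv, "feature_kind") <- attr(cm, "feature_kind")
  lv
}

#' Counts-per-million (linear scale)
#' @inheritParams log_cpm
#' @return Numeric matrix; without a prior each column sums to 1e6.
#' @export
cpm <- function(cm, prior_count = 0, norm_factors = NULL) {
  ls <- library_sizes(cm, norm_factors)
  sweep(unclass(cm) + prior_count, 2L, ls + 2 * prior_count, "/") * 1e6
}

#' Read the sample metadata table
#'
#' TSV with columns `sample_id`, `group`, `age`, `sex`. Groups follow the
#' study design: SR40 (38-42 y), SR50 (48-52 y), SR60 (58-62 y),
#' SR70 (68-72 y). When `check_bands = TRUE`, ages outside their group's
#' band are an error.
#'
#' @param path TSV file path.
#' @param check_bands validate ages against the group bands.
#' @return data.frame with factor `group` ordered SR40 < SR50 < SR60 < SR70.
#' @export
read_sample_table <- function(path, check_bands = TRUE) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE, quote = "")
  need <- c("sample_id", "group", "age", "sex")
  if (!all(need %in% names(tab)))
    stop("sample table must have columns: ", paste(need, collapse = ", "))
  sample_table(tab, check_bands = check_bands)
}

#' Validate a sample metadata data.frame
#' @param tab data.frame with `sample_id`, `group`, `age`, `sex`.
#' @inheritParams read_sample_table
#' @return The validated data.frame.
#' @export
sample_table <- function(tab, check_bands = TRUE) {
  groups <- c("SR40", "SR50", "SR60", "SR70")
  if (anyDuplicated(tab$sample_id)) stop("duplicate sample ids")
  if (!all(tab$group %in% groups))
    stop("unknown group label(s): ", paste(setdiff(tab$group, groups), collapse = ", "))
  if (!all(tab$sex %in% c("F", "M"))) stop("sex must be F or M")
  tab$age <- as.integer(tab$age)
  if (check_bands) {
    lo <- c(SR40 = 38L, SR50 = 48L, SR60 = 58L, SR70 = 68L)
    bad <- tab$age < lo[tab$group] | tab$age > lo[tab$group] + 4L
    if (any(bad))
      stop("age outside group band for sample(s): ",
           paste(tab$sample_id[bad], collapse = ", "))
  }
  tab$group <- factor(tab$group, levels = groups)
  tab
}

#' Read a miRNA-target prediction table
#'
#' Stand-in for multiMiR-style output: TSV with columns `mirna`, `gene`
#' and optional `source`, `evidence` (`predicted` or `validated`).
#' Duplicate (mirna, gene) pairs are collapsed to one record, keeping the
#' strongest evidence (`validated` over `predicted`).
#'
#' @param path TSV file path.
#' @return A `target_db`: data.frame of unique pairs with a lookup helper
#'   via [target_genes()].
#' @export
read_target_db <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE, quote = "")
  if (!all(c("mirna", "gene") %in% names(tab)))
    stop("target table must have columns mirna, gene")
  if (is.null(tab$source)) tab$source <- "unknown"
  if (is.null(tab$evidence)) tab$evidence <- "predicted"
  target_db(tab)
}

#' Build a target database from a data.frame of pairs
#' @param tab data.frame with columns `mirna`, `gene` and optional
#'   `source`, `evidence`.
#' @return data.frame of class `target_db`, deduplicated on (mirna, gene).
#' @export
target_db <- function(tab) {
  if (is.null(tab$source)) tab$source <- "unknown"
  if (is.null(tab$evidence)) tab$evidence <- "predicted"
  if (!all(tab$evidence %in% c("predicted", "validated")))
    stop("evidence must be 'predicted' or 'validated'")
  # keep validated over predicted on duplicates
  ord <- order(tab$mirna, tab$gene, tab$evidence != "validated")
  tab <- tab[ord, , drop = FALSE]
  tab <- tab[!duplicated(tab[c("mirna", "gene")]), , drop = FALSE]
  rownames(tab) <- NULL
  class(tab) <- c("target_db", "data.frame")
  tab
}

#' Predicted target set of one miRNA
#' @param db a `target_db`.
#' @param mirna miRNA id.
#' @param evidence `"any"` (default) unions predicted and validated
#'   records; `"validated"` restricts to validated ones.
#' @return Character vector (a set) of gene ids.
#' @export
target_genes <- function(db, mirna, evidence = c("any", "validated")) {
  evidence <- match.arg(evidence)
  keep <- db$mirna == mirna
  if (evidence == "validated") keep <- keep & db$evidence == "validated"
  unique(db$gene[keep])
}

#' Read gene sets in GMT format
#'
#' Each line is `set_id<TAB>description<TAB>member1<TAB>member2...`.
#' Lines with fewer than three fields and duplicated set ids are errors.
#'
#' @param path GMT file path.
#' @return Named list of character vectors, with a `description`
#'   attribute per element.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty GMT file: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 3L))
    stop("malformed GMT line (fewer than 3 fields) at line ", which(nf < 3L)[1L])
  ids <- vapply(parts, `[[`, "", 1L)
  if (anyDuplicated(ids)) stop("duplicate gene-set ids in ", path)
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- ids
  attr(sets, "description") <- stats::setNames(vapply(parts, `[[`, "", 2L), ids)
  sets
}

#' Write gene sets in GMT format
#' @param sets named list of character vectors (optionally with a
#'   `description` attribute as produced by [read_gmt()]).
#' @param path output file path.
#' @export
write_gmt <- function(sets, path) {
  desc <- attr(sets, "description")
  if (is.null(desc)) desc <- stats::setNames(rep("na", length(sets)), names(sets))
  lines <- vapply(names(sets), function(id) {
    paste(c(id, desc[[id]], sets[[id]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
}

#' Write a result table as TSV
#'
#' UTF-8, tab-separated, "." decimal, no quoting; round-trips losslessly
#' through [read_tsv()] at full double precision.
#'
#' @param tab data.frame.
#' @param path output path.
#' @export
write_table <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, fileEncoding = "UTF-8")
}

#' Read back a TSV result table
#' @param path TSV path.
#' @return data.frame.
#' @export
read_tsv <- function(path) {
  utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE, quote = "")
}

#' Write a count matrix as TSV (feature column + sample columns)
#' @param cm a [count_matrix()].
#' @param path output path.
#' @export
write_count_matrix <- function(cm, path) {
  tab <- data.frame(feature = rownames(cm), unclass(cm), check.names = FALSE)
  write_table(tab, path)
}
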