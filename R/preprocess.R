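#' Log2-transform an expression matrix
#'
#' Applies `log2(v + offset)` elementwise, the standard transform for
#' TPM/FPKM-scale abundance estimates before downstream analysis.
#'
#' @param m Non-negative numeric matrix (features x samples).
#' @param offset Pseudocount added before taking logs; default 1, so a raw
#'   value of 0 maps to exactly 0 on the stored scale.
#' @return The transformed matrix.
#' @export
log2_transform <- function(m, offset = 1) {
  stopifnot(is.matrix(m), is.numeric(m))
  if (any(m < 0)) stop("log2_transform: negative input values")
  log2(m + offset)
}

#' Quantile-normalize the sample columns of an expression matrix
#'
#' Forces every sample column to share the same value distribution: each
#' column's sorted values are replaced by the per-rank mean across columns.
#' Delegates to [limma::normalizeQuantiles()] with `ties = TRUE`, the
#' standard implementation for expression arrays; ties within a column
#' receive interpolated reference values at their average rank.
#'
#' @param m Numeric matrix (features x samples) with at least two samples.
#' @return The normalized matrix with the input dimnames.
#' @export
quantile_normalize <- function(m) {
  stopifnot(is.matrix(m), is.numeric(m))
  if (ncol(m) < 2L) stop("quantile_normalize: at least 2 samples required")
  out <- limma::normalizeQuantiles(m, ties = TRUE)
  dimnames(out) <- dimnames(m)
  out
}

#' Collapse multi-probe features to one representative row per gene
#'
#' For a gene measured by several probes/transcripts, the representative is
#' the feature with the largest interquartile range (IQR) across samples.
#' The IQR may be computed in a `reference` cohort rather than in `m` itself,
#' the convention when collapsing paired cohorts measured on one platform so
#' that both use the same representative probe.  IQR ties are broken by the
#' lexicographically smallest feature id.
#'
#' @param m Numeric matrix (features x samples), row names are feature ids.
#' @param feature_to_gene Named character vector mapping feature id -> gene
#'   id; must cover every feature in `m`.
#' @param reference Optional matrix, same feature ids, in which IQRs are
#'   computed.
#' @return A matrix with one row per gene (lexicographic gene order).
#' @export
collapse_by_iqr <- function(m, feature_to_gene, reference = NULL) {
  stopifnot(is.matrix(m), !is.null(rownames(m)))
  feats <- rownames(m)
  missing_map <- setdiff(feats, names(feature_to_gene))
  if (length(missing_map)) {
    stop("feature(s) missing from mapping: ", paste(utils::head(missing_map, 5), collapse = ", "))
  }
  iqr_src <- if (is.null(reference)) m else reference
  missing_ref <- setdiff(feats, rownames(iqr_src))
  if (length(missing_ref)) {
    stop("feature(s) missing from reference: ", paste(utils::head(missing_ref, 5), collapse = ", "))
  }
  iqr <- apply(iqr_src[feats, , drop = FALSE], 1L, stats::IQR, type = 7)
  genes <- feature_to_gene[feats]
  reps <- vapply(split(feats, genes), function(fs) {
    fs <- fs[order(fs)]                       # lexicographic tie-break
    fs[which.max(iqr[fs])]
  }, character(1))
  reps <- reps[order(names(reps))]
  out <- m[reps, , drop = FALSE]
  rownames(out) <- names(reps)
  out
}

#' Homogenize two cohorts to a common global 75th percentile
#'
#' Rescales cohort `b` multiplicatively by `q75(a) / q75(b)` (quantiles over
#' all matrix entries, type-7 definition) so both matrices share the same
#' global 75% quantile.  `a` is returned unchanged; the rescaling preserves
#' the within-matrix rank order of `b`.
#'
#' @param a,b Numeric expression matrices on the same (log2) scale.
#' @return A list with elements `a` and `b` (rescaled).
#' @export
homogenize_q75 <- function(a, b) {
  stopifnot(is.matrix(a), is.matrix(b), length(a) > 0, length(b) > 0)
  qa <- stats::quantile(a, 0.75, names = FALSE, type = 7)
  qb <- stats::quantile(b, 0.75, names = FALSE, type = 7)
  if (qb <= 0) stop("homogenize_q75: global 75th percentile of b is not positive")
  if (qa <= 0) stop("homogenize_q75: global 75th percentile of a is not positive")
  list(a = a, b = b * (qa / qb))
}
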