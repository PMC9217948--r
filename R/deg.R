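#' Remove genes unexpressed in a large fraction of samples
#'
#' A gene is "unexpressed" in a sample when its stored value is exactly 0
#' (a raw TPM of 0 maps to 0 after the log2(v + 1) transform).  Genes that
#' are unexpressed in at least `frac` of the samples are dropped before
#' differential-expression testing.
#'
#' @param m Numeric matrix (genes x samples), log2 scale.
#' @param frac Removal threshold on the zero fraction, in (0, 1]; default
#'   0.5 ("at least half the samples").
#' @return The filtered matrix.
#' @export
filter_unexpressed <- function(m, frac = 0.5) {
  stopifnot(is.matrix(m), frac > 0, frac <= 1)
  n_zero <- rowSums(m == 0)
  keep <- n_zero < frac * ncol(m)
  if (!any(keep)) {
    stop("filter_unexpressed: no genes survive at frac = ", frac,
         "; review the threshold or the input scale")
  }
  m[keep, , drop = FALSE]
}

#' Per-gene Welch t-test between mutant and wild-type samples
#'
#' Tests, gene by gene, the difference in mean expression between mutation-
#' positive and mutation-negative samples (Welch unequal-variance t, two
#' sided).  Degenerate genes with zero variance in both groups get `t = 0`,
#' `p = 1` when the group means are equal, `p = 0` otherwise.
#'
#' @param m Numeric matrix (genes x samples).
#' @param clinical Clinical table aligned with the columns of `m`; the
#'   grouping is `tp53_mutant`.
#' @return A data frame with columns `gene_id`, `t_statistic`, `p_value`.
#' @export
t_test_by_mutation <- function(m, clinical) {
  clinical <- align_cohort(m, clinical)
  grp <- clinical$tp53_mutant
  n1 <- sum(grp); n2 <- sum(!grp)
  if (n1 < 2 || n2 < 2) {
    stop("t_test_by_mutation: both groups need >= 2 samples (mutant n = ",
         n1, ", wild-type n = ", n2, ")")
  }
  x1 <- m[, grp, drop = FALSE]; x2 <- m[, !grp, drop = FALSE]
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1)
  v2 <- rowSums((x2 - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  tt <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(tt), df)
  degen <- se2 == 0
  if (any(degen)) {
    eq <- degen & (m1 == m2)
    tt[eq] <- 0; p[eq] <- 1
    ne <- degen & (m1 != m2)
    tt[ne] <- sign(m1[ne] - m2[ne]) * Inf; p[ne] <- 0
  }
  data.frame(gene_id = rownames(m), t_statistic = unname(tt),
             p_value = unname(p), stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p Vector of p-values in \[0, 1\].
#' @return Adjusted p-values (monotone-enforced, clipped to 1).
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
    stop("bh_adjust: p-values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Select differentially expressed genes at an adjusted-p cutoff
#'
#' @param results Data frame with columns `gene_id` and `adj_p` (see
#'   [deg_table()]).
#' @param threshold Strict cutoff: genes with `adj_p < threshold` are
#'   selected. Default 0.05.
#' @return Character vector of selected gene ids.
#' @export
select_deg <- function(results, threshold = 0.05) {
  stopifnot(threshold > 0, threshold < 1)
  results$gene_id[results$adj_p < threshold]
}

#' Full differential-expression candidate scan
#'
#' Convenience pipeline: expression filter, per-gene Welch t-test on
#' mutation status, BH adjustment and strict adjusted-p selection.
#'
#' @inheritParams t_test_by_mutation
#' @param unexpressed_frac Passed to [filter_unexpressed()].
#' @param threshold Passed to [select_deg()].
#' @return Data frame with columns `gene_id`, `t_statistic`, `p_value`,
#'   `adj_p`, `selected`.
#' @export
deg_table <- function(m, clinical, unexpressed_frac = 0.5, threshold = 0.05) {
  m <- filter_unexpressed(m, unexpressed_frac)
  res <- t_test_by_mutation(m, clinical)
  res$adj_p <- bh_adjust(res$p_value)
  res$selected <- res$adj_p < threshold
  res
}
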