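#' Z-score signature genes and inject Gaussian noise
#'
#' Each signature gene row is standardized to mean 0 / variance 1 across
#' samples, then i.i.d. Normal(0, noise_var) noise is added (note: the
#' second argument is a variance, so noise_var = 0.1 injects noise worth
#' 10% of the unit data variance).  Other rows pass through unchanged.
#'
#' @param m Expression matrix (genes x samples).
#' @param genes Signature genes to standardize/perturb.
#' @param noise_var Noise variance (>= 0).
#' @param seed Optional integer seed for the noise draw; `NULL` uses the
#'   current RNG stream.
#' @return The matrix with the signature rows replaced.
#' @export
znoise <- function(m, genes, noise_var = 0.1, seed = NULL) {
  genes <- as.character(genes)
  missing <- setdiff(genes, rownames(m))
  if (length(missing)) stop("znoise: gene(s) absent: ", paste(missing, collapse = ", "))
  stopifnot(noise_var >= 0)
  sub <- m[genes, , drop = FALSE]
  sds <- apply(sub, 1L, stats::sd)
  if (any(sds == 0)) {
    stop("znoise: zero-variance gene(s): ",
         paste(genes[sds == 0], collapse = ", "))
  }
  z <- (sub - rowMeans(sub)) / sds
  if (!is.null(seed)) set.seed(seed)
  if (noise_var > 0) {
    z <- z + matrix(stats::rnorm(length(z), 0, sqrt(noise_var)), nrow(z), ncol(z))
  }
  m[genes, ] <- z
  m
}

#' Subsampling + noise robustness analysis of a signature
#'
#' Repeatedly draws working sets of `floor(frac * N)` samples without
#' replacement, z-scores the signature genes on the working set, adds
#' Normal(0, noise_var) noise, and records the SVM-LOOCV AUC.  The report
#' summarizes the AUC distribution by its 0.05/0.95 quantiles and the
#' fraction of replicates falling below a reference threshold.
#'
#' @inheritParams svm_loocv
#' @param n_reps Number of working sets.
#' @param frac Subsample fraction in (0, 1].
#' @param noise_var Injected noise variance.
#' @param seed Integer seed.
#' @param auc_ref Reference threshold for the "fraction below" summary.
#' @return A list of class `robustness_report`: `aucs`, `q05`, `q95`,
#'   `frac_below`, plus the run parameters.
#' @export
robustness_analysis <- function(m, clinical, genes, settings = svm_settings(),
                                n_reps = 500, frac = 0.9, noise_var = 0.1,
                                seed = 1L, auc_ref = 0.65) {
  clinical <- align_cohort(m, clinical)
  stopifnot(frac > 0, frac <= 1, n_reps >= 1)
  n <- ncol(m)
  n_work <- floor(frac * n)
  if (n_work < 4L) stop("robustness_analysis: working sets too small")
  set.seed(seed)
  aucs <- vapply(seq_len(n_reps), function(rep) {
    for (try in seq_len(100L)) {
      idx <- sort(sample.int(n, n_work))
      y <- clinical$bcr[idx]
      if (sum(y == 1) >= 2 && sum(y == -1) >= 2) break
      if (try == 100L) stop("robustness_analysis: subsample kept losing a class")
      message("robustness_analysis: resampling a single-class working set")
    }
    mw <- m[, idx, drop = FALSE]
    cw <- clinical[idx, , drop = FALSE]
    mw <- znoise(mw, genes, noise_var, seed = NULL)
    evaluate_signature(mw, cw, genes, settings)$auc
  }, numeric(1))
  structure(list(aucs = aucs,
                 q05 = stats::quantile(aucs, 0.05, names = FALSE, type = 7),
                 q95 = stats::quantile(aucs, 0.95, names = FALSE, type = 7),
                 frac_below = mean(aucs < auc_ref), auc_ref = auc_ref,
                 n_reps = n_reps, frac = frac, noise_var = noise_var,
                 seed = seed),
            class = "robustness_report")
}

#' @export
print.robustness_report <- function(x, ...) {
  cat(sprintf(
    "Robustness: %d working sets (frac %.2f, noise var %.3g)\n",
    x$n_reps, x$frac, x$noise_var))
  cat(sprintf("  AUC quantiles: q05 = %.3f, q95 = %.3f; fraction below %.2f: %.3f\n",
              x$q05, x$q95, x$auc_ref, x$frac_below))
  invisible(x)
}
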