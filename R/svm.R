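#' SVM settings for signature evaluation
#'
#' @param kernel One of "linear", "polynomial", "radial".  Default linear;
#'   hyperparameters are held at their defaults rather than tuned.
#' @param cost Soft-margin cost C (> 0).
#' @param gamma Kernel coefficient for polynomial/radial kernels; the string
#'   "default" means 1 / (number of features).
#' @param class_weights Either "balanced_fold" (the default: on every
#'   training fold, weight(+1) = n- / n+ and weight(-1) = 1, the reciprocal
#'   of the class ratio) or a named numeric vector with names "1" and "-1".
#' @return A list of class `svm_settings`.
#' @export
svm_settings <- function(kernel = c("linear", "polynomial", "radial"),
                         cost = 1, gamma = "default",
                         class_weights = "balanced_fold") {
  kernel <- match.arg(kernel)
  stopifnot(cost > 0)
  if (is.numeric(gamma)) stopifnot(gamma > 0)
  else if (!identical(gamma, "default")) stop("gamma must be numeric or \"default\"")
  if (is.numeric(class_weights)) {
    if (!setequal(names(class_weights), c("1", "-1"))) {
      stop("numeric class_weights need names \"1\" and \"-1\"")
    }
  } else if (!identical(class_weights, "balanced_fold")) {
    stop("class_weights must be \"balanced_fold\" or a named numeric vector")
  }
  structure(list(kernel = kernel, cost = cost, gamma = gamma,
                 class_weights = class_weights), class = "svm_settings")
}

#' Default class weights: reciprocal of the class ratio
#'
#' weight(+1) = n- / n+ and weight(-1) = 1, computed from the labels of a
#' training set, so the minority positive class is up-weighted.
#'
#' @param y Vector of labels in \{-1, +1\} (or a clinical table, in which
#'   case its `bcr` column is used).
#' @return Named numeric vector with elements "1" and "-1".
#' @export
default_class_weights <- function(y) {
  if (is.data.frame(y)) y <- y$bcr
  n_pos <- sum(y == 1); n_neg <- sum(y == -1)
  if (n_pos == 0 || n_neg == 0) stop("both classes must be present to compute class weights")
  c("1" = n_neg / n_pos, "-1" = 1)
}

# Resolve numeric gamma for a feature dimension d.
resolve_gamma <- function(settings, d) {
  if (is.numeric(settings$gamma)) settings$gamma else 1 / d
}

# Fit a C-classification SVM through e1071's libsvm backend, bypassing the
# svm() wrapper's data-frame/NA handling (pure numeric inputs here); the
# solver call and solution are identical to e1071::svm(..., scale = FALSE).
fit_svm <- function(x, y, settings, weights) {
  nr <- nrow(x); d <- ncol(x)
  lev <- c("-1", "1")
  yi <- as.double(match(as.character(y), lev))
  wl <- as.integer(match(names(weights), lev))
  kernel_code <- match(settings$kernel, c("linear", "polynomial", "radial")) - 1L
  gamma <- resolve_gamma(settings, d)
  err <- paste(rep(" ", 255), collapse = "")
  cret <- .C(e1071:::R_svmtrain, as.double(t(x)), as.integer(nr), as.integer(d),
             yi, as.integer(0), as.integer(0),
             as.integer(0L), as.integer(kernel_code), as.integer(3L),
             as.double(gamma), as.double(0), as.double(settings$cost),
             as.double(0.5), wl, as.double(weights),
             as.integer(length(weights)), as.double(40), as.double(0.001),
             as.double(0.1), as.integer(1L), as.integer(0L), as.integer(0L),
             as.integer(0L),
             nclasses = integer(1), nr = integer(1), index = integer(nr),
             labels = integer(2), nSV = integer(2), rho = double(1),
             coefs = double(nr), sigma = double(1), probA = double(1),
             probB = double(1), cresults = double(0), ctotal1 = double(1),
             ctotal2 = double(1), error = err)
  if (cret$error != err) stop("svm training failed: ", cret$error)
  idx <- cret$index[seq_len(cret$nr)]
  list(index = idx, SV = x[idx, , drop = FALSE],
       coefs = cret$coefs[seq_len(cret$nr)], rho = cret$rho,
       labels = cret$labels[1:2], kernel = settings$kernel,
       gamma = gamma, cost = settings$cost)
}

# Decision values oriented so positive => class "+1", regardless of the
# backend's internal label ordering (libsvm orders labels by first
# appearance in the training data).
decision_values <- function(model, newx, settings = NULL) {
  K <- switch(model$kernel,
    linear = newx %*% t(model$SV),
    polynomial = (model$gamma * (newx %*% t(model$SV)))^3,
    radial = {
      d2 <- outer(rowSums(newx^2), rowSums(model$SV^2), "+") -
        2 * newx %*% t(model$SV)
      exp(-model$gamma * d2)
    })
  dv <- drop(K %*% model$coefs) - model$rho
  if (model$labels[1L] == 1L) dv <- -dv   # internal label 1 = class "-1"
  dv
}

# Extract the samples x features matrix for a gene subset, with checks.
signature_matrix <- function(m, genes) {
  genes <- as.character(genes)
  missing <- setdiff(genes, rownames(m))
  if (length(missing)) {
    stop("gene(s) absent from expression matrix: ",
         paste(utils::head(missing, 10), collapse = ", "))
  }
  t(m[genes, , drop = FALSE])
}

#' SVM leave-one-out cross-validation
#'
#' For each sample i, an SVM is trained on the other N - 1 samples and
#' applied to sample i, yielding a decision value t_i (the transcriptomic
#' risk score) and a predicted label zhat_i = sign(t_i), with sign(0) taken
#' as +1.  Decision values are oriented so positive implies class +1.  With
#' the default "balanced_fold" weighting, class weights are recomputed on
#' every training fold.
#'
#' Internally, folds that leave out the same class share identical training-
#' fold class weights, so one full-data model per left-out class is fitted
#' and a genuine per-fold refit is performed only for samples that are
#' support vectors of that model; removing a non-support-vector leaves the
#' soft-margin SVM solution unchanged, so the shortcut is exact.
#'
#' @param m Expression matrix (genes x samples, log2 scale; features are
#'   used unstandardized).
#' @param clinical Clinical table aligned with `m`; labels come from `bcr`.
#' @param genes Character vector of signature genes, all present in `m`.
#' @param settings An [svm_settings()].
#' @return A list with `predicted` (-1/+1 vector) and `decision` (numeric
#'   vector), both named by sample id.
#' @export
svm_loocv <- function(m, clinical, genes, settings = svm_settings()) {
  clinical <- align_cohort(m, clinical)
  x <- signature_matrix(m, genes)
  y <- clinical$bcr
  n <- length(y)
  if (sum(y == 1) < 2 || sum(y == -1) < 2) {
    stop("svm_loocv: both BCR classes need >= 2 samples")
  }
  dv <- numeric(n)
  fixed_w <- is.numeric(settings$class_weights)
  n_pos <- sum(y == 1); n_neg <- sum(y == -1)
  # groups of folds sharing identical training-fold weights
  groups <- if (fixed_w) list(seq_len(n)) else split(seq_len(n), y)
  for (idx in groups) {
    if (fixed_w) {
      w <- settings$class_weights
    } else {
      cls <- y[idx[1L]]
      fp <- n_pos - (cls == 1); fn <- n_neg - (cls == -1)
      w <- c("1" = fn / fp, "-1" = 1)
    }
    full <- fit_svm(x, y, settings, w)
    is_sv <- logical(n); is_sv[full$index] <- TRUE
    for (i in idx) {
      if (is_sv[i]) {
        fold <- fit_svm(x[-i, , drop = FALSE], y[-i], settings, w)
        dv[i] <- decision_values(fold, x[i, , drop = FALSE], settings)
      } else {
        dv[i] <- decision_values(full, x[i, , drop = FALSE], settings)
      }
    }
  }
  names(dv) <- rownames(x)
  list(predicted = stats::setNames(ifelse(dv >= 0, 1L, -1L), rownames(x)),
       decision = dv)
}

#' Area under the ROC curve from scores
#'
#' Computed as the Mann-Whitney concordance P(t+ > t-) + 0.5 P(t+ = t-)
#' over all (positive, negative) pairs, via midranks.
#'
#' @param y Labels in \{-1, +1\}; both classes must be present.
#' @param t Numeric scores.
#' @return AUC in \[0, 1\].
#' @export
auc_from_scores <- function(y, t) {
  stopifnot(length(y) == length(t))
  n_pos <- sum(y == 1); n_neg <- sum(y == -1)
  if (n_pos == 0 || n_neg == 0) stop("auc_from_scores: both classes must be present")
  r <- rank(t)
  (sum(r[y == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Fisher's exact test on a 2x2 table
#'
#' Exact hypergeometric test of independence.  `alternative = "greater"`
#' tests positive association between the row and column classifications
#' (odds ratio > 1) for tables laid out with agreement on the diagonal.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @param alternative "two_sided" or "greater".
#' @return The exact p-value.
#' @export
fisher_exact <- function(table, alternative = c("two_sided", "greater")) {
  alternative <- match.arg(alternative)
  table <- as.matrix(table)
  stopifnot(identical(dim(table), c(2L, 2L)))
  if (any(table < 0) || any(table != round(table))) {
    stop("fisher_exact: counts must be non-negative integers")
  }
  alt <- if (alternative == "two_sided") "two.sided" else "greater"
  stats::fisher.test(table, alternative = alt)$p.value
}

# 2x2 contingency table of true vs predicted labels with fixed layout:
# rows true (+1, -1), columns predicted (+1, -1).
contingency_22 <- function(y, zhat) {
  tab <- table(factor(y, levels = c(1, -1)), factor(zhat, levels = c(1, -1)))
  m <- matrix(as.integer(tab), 2, 2,
              dimnames = list(true = c("+1", "-1"), predicted = c("+1", "-1")))
  m
}

#' Evaluate a gene signature by SVM-LOOCV
#'
#' Bundles the LOOCV predictions with the 2x2 table of true versus predicted
#' labels, two-sided and one-sided Fisher exact p-values, and the AUC of the
#' decision values (transcriptomic risk scores).
#'
#' @inheritParams svm_loocv
#' @return An object of class `signature_eval`: list with `genes`,
#'   `predicted`, `decision`, `auc`, `p_two_sided`, `p_one_sided`,
#'   `contingency`.
#' @export
evaluate_signature <- function(m, clinical, genes, settings = svm_settings()) {
  clinical <- align_cohort(m, clinical)
  cv <- svm_loocv(m, clinical, genes, settings)
  y <- clinical$bcr
  tab <- contingency_22(y, cv$predicted)
  structure(list(genes = as.character(genes),
                 predicted = cv$predicted, decision = cv$decision,
                 auc = auc_from_scores(y, cv$decision),
                 p_two_sided = fisher_exact(tab, "two_sided"),
                 p_one_sided = fisher_exact(tab, "greater"),
                 contingency = tab),
            class = "signature_eval")
}

#' @export
print.signature_eval <- function(x, ...) {
  cat(sprintf("Signature evaluation: %d genes, %d samples\n",
              length(x$genes), length(x$predicted)))
  cat(sprintf("  AUC = %.3f; Fisher p (two-sided) = %.3g, (one-sided) = %.3g\n",
              x$auc, x$p_two_sided, x$p_one_sided))
  print(x$contingency)
  invisible(x)
}

#' Cross-cohort signature evaluation
#'
#' Trains a single SVM on every sample of the training cohort (class weights
#' from the reciprocal-ratio rule on the full training set, unless fixed in
#' `settings`) and scores the test cohort; AUC and Fisher p-values are
#' computed on the test cohort only.
#'
#' @param train,test Lists with elements `expression` and `clinical` (a
#'   simulated cohort from [simulate_cohort()] works directly).
#' @inheritParams svm_loocv
#' @return A `signature_eval` for the test cohort.
#' @export
evaluate_cross_cohort <- function(train, test, genes, settings = svm_settings()) {
  ctr <- align_cohort(train$expression, train$clinical)
  cte <- align_cohort(test$expression, test$clinical)
  xtr <- signature_matrix(train$expression, genes)
  xte <- signature_matrix(test$expression, genes)
  ytr <- ctr$bcr; yte <- cte$bcr
  if (sum(ytr == 1) < 2 || sum(ytr == -1) < 2) {
    stop("evaluate_cross_cohort: both classes need >= 2 training samples")
  }
  if (sum(yte == 1) == 0 || sum(yte == -1) == 0) {
    stop("evaluate_cross_cohort: test cohort must contain both classes")
  }
  w <- if (is.numeric(settings$class_weights)) settings$class_weights
       else default_class_weights(ytr)
  model <- fit_svm(xtr, ytr, settings, w)
  dv <- decision_values(model, xte, settings)
  names(dv) <- rownames(xte)
  zhat <- stats::setNames(ifelse(dv >= 0, 1L, -1L), rownames(xte))
  tab <- contingency_22(yte, zhat)
  structure(list(genes = as.character(genes), predicted = zhat, decision = dv,
                 auc = auc_from_scores(yte, dv),
                 p_two_sided = fisher_exact(tab, "two_sided"),
                 p_one_sided = fisher_exact(tab, "greater"),
                 contingency = tab),
            class = "signature_eval")
}
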