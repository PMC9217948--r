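#' Kaplan-Meier stratification and two-group log-rank test
#'
#' @param groups Binary group labels (e.g. predicted BCR classes), two
#'   non-empty groups.
#' @param times Non-negative follow-up times.
#' @param events Logical event indicators.
#' @return List with `fit` (a [survival::survfit] object holding the
#'   per-group Kaplan-Meier curves), `chisq` and `p` (two-group log-rank).
#' @export
km_logrank <- function(groups, times, events) {
  groups <- factor(groups)
  if (nlevels(groups) != 2L) {
    stop("km_logrank: exactly two non-empty groups required, got ", nlevels(groups))
  }
  df <- data.frame(times = times, events = as.integer(events), groups = groups)
  fit <- survival::survfit(survival::Surv(times, events) ~ groups, data = df)
  sd <- survival::survdiff(survival::Surv(times, events) ~ groups, data = df)
  p <- stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE)
  list(fit = fit, chisq = unname(sd$chisq), p = unname(p))
}

#' Fit a Cox proportional-hazards model
#'
#' Breslow tie handling; the global p-value is the score (log-rank) test.
#' The returned object carries the per-sample linear predictor (prognostic
#' index) needed by [royston_r2()] and the BIC computed with the number of
#' events as effective sample size:
#' `BIC = -2 * loglik + q * log(D)` with q coefficients and D events.
#'
#' @param covariates Numeric matrix or data frame of covariates (one row
#'   per sample); no constant columns.
#' @param times,events Survival outcome.
#' @param model_id Optional label (e.g. "M-1").
#' @return An object of class `cox_model_result`: `coef`, `loglik`
#'   (maximized partial log-likelihood), `p` (global score test), `bic`,
#'   `lp` (linear predictor), `n_events`, `fit`, and `r2` (filled by
#'   [royston_r2()], otherwise `NA`).
#' @export
cox_fit <- function(covariates, times, events, model_id = NULL) {
  covariates <- as.data.frame(covariates)
  stopifnot(nrow(covariates) == length(times), length(times) == length(events))
  num <- vapply(covariates, is.numeric, logical(1))
  const <- vapply(covariates, function(v) length(unique(v)) < 2L, logical(1))
  if (any(const)) {
    stop("cox_fit: constant covariate(s): ",
         paste(names(covariates)[const], collapse = ", "))
  }
  if (sum(events) < 1) stop("cox_fit: at least one event required")
  df <- cbind(covariates, .time = times, .event = as.integer(events))
  fit <- survival::coxph(survival::Surv(.time, .event) ~ ., data = df,
                         ties = "breslow")
  if (anyNA(stats::coef(fit))) stop("cox_fit: model did not converge (NA coefficients)")
  q <- length(stats::coef(fit))
  D <- sum(events)
  loglik <- fit$loglik[2L]
  sct <- summary(fit)$sctest
  res <- list(model_id = model_id, coef = stats::coef(fit), loglik = loglik,
              p = unname(sct["pvalue"]), bic = -2 * loglik + q * log(D),
              lp = unname(fit$linear.predictors), n_events = D,
              r2 = NA_real_, fit = fit)
  class(res) <- "cox_model_result"
  res
}

#' @export
print.cox_model_result <- function(x, ...) {
  cat(sprintf("Cox model%s: %d coefficient(s), %d events\n",
              if (is.null(x$model_id)) "" else paste0(" ", x$model_id),
              length(x$coef), x$n_events))
  cat(sprintf("  loglik = %.3f, BIC = %.2f, global score p = %.3g, R2 = %s\n",
              x$loglik, x$bic, x$p,
              if (is.na(x$r2)) "NA" else sprintf("%.3f", x$r2)))
  invisible(x)
}

#' Royston's explained variation for a survival model
#'
#' Implements the D-based measure: the samples' prognostic index is replaced
#' by scaled normal order scores (Blom rankits divided by kappa =
#' sqrt(8/pi)), a Cox model is fitted on that single covariate to estimate
#' the prognostic-separation statistic D, and
#' `R^2 = (D^2/kappa^2) / (D^2/kappa^2 + sigma^2)` with `sigma^2 = pi^2/6`.
#' A constant prognostic index yields 0.
#'
#' @param result A `cox_model_result` (its linear predictor is used), or a
#'   numeric vector of prognostic-index values.
#' @param times,events Survival outcome.
#' @return Explained variation in \[0, 1).
#' @export
royston_r2 <- function(result, times, events) {
  lp <- if (inherits(result, "cox_model_result")) result$lp else as.numeric(result)
  stopifnot(length(lp) == length(times))
  if (stats::sd(lp) == 0) return(0)
  n <- length(lp)
  rankit <- stats::qnorm((rank(lp, ties.method = "average") - 3 / 8) / (n + 1 / 4))
  kappa <- sqrt(8 / pi)
  scaled <- rankit / kappa
  df <- data.frame(.time = times, .event = as.integer(events), scaled = scaled)
  fit <- survival::coxph(survival::Surv(.time, .event) ~ scaled, data = df,
                         ties = "breslow")
  D <- unname(stats::coef(fit))
  (D^2 / kappa^2) / (D^2 / kappa^2 + pi^2 / 6)
}

# Clinicopathologic design matrix: Gleason grade categories (3+4 reference,
# then 4+3, then other), T stage (T1 reference), age in years.
cpf_design <- function(clinical) {
  gl <- ifelse(clinical$gleason_primary == 3 & clinical$gleason_secondary == 4, "3+4",
        ifelse(clinical$gleason_primary == 4 & clinical$gleason_secondary == 3, "4+3",
               "other"))
  gl <- factor(gl, levels = c("3+4", "4+3", "other"))
  ts <- factor(clinical$t_stage, levels = c("T1", "T2", "T3"))
  if (anyNA(ts)) stop("cpf_design: missing t_stage values; complete covariates required")
  drop_empty <- function(f, what) {
    if (any(table(f) == 0)) {
      warning("cpf_design: empty ", what, " level(s) collapsed: ",
              paste(levels(f)[table(f) == 0], collapse = ", "))
      droplevels(f)
    } else f
  }
  gl <- drop_empty(gl, "Gleason category")
  ts <- drop_empty(ts, "T-stage")
  data.frame(gleason = gl, t_stage = ts, age = clinical$age)
}

#' Compare transcriptomic risk scores against clinicopathologic factors
#'
#' Fits the three Cox models of the evaluation protocol on one cohort:
#' M-1 with the transcriptomic risk score (the continuous SVM-LOOCV decision
#' value) as the only covariate, M-2 with the three clinicopathologic
#' factors (Gleason category 3+4 / 4+3 / other, T stage, age), and M-3 with
#' both.  Each model is summarized by Royston's explained variation R^2,
#' BIC (events as effective sample size) and the global score-test p-value.
#'
#' @param trs Numeric vector of transcriptomic risk scores, one per sample.
#' @param clinical Clinical table (same sample order as `trs`).
#' @param times,events Optional survival outcome; defaults to the clinical
#'   table's `rfs_time` / `rfs_event`.
#' @return A list of class `cox_comparison`: `table` (data frame with
#'   model, r2, bic, p, loglik, n_coef) and `models` (the three
#'   `cox_model_result` objects).
#' @export
compare_models <- function(trs, clinical, times = clinical$rfs_time,
                           events = clinical$rfs_event) {
  stopifnot(length(trs) == nrow(clinical))
  cpf <- cpf_design(clinical)
  covs <- list(`M-1` = data.frame(trs = trs),
               `M-2` = cpf,
               `M-3` = cbind(data.frame(trs = trs), cpf))
  models <- lapply(names(covs), function(id) {
    res <- cox_fit(covs[[id]], times, events, model_id = id)
    res$r2 <- royston_r2(res, times, events)
    res
  })
  names(models) <- names(covs)
  tab <- data.frame(
    model = names(covs),
    r2 = vapply(models, `[[`, numeric(1), "r2"),
    bic = vapply(models, `[[`, numeric(1), "bic"),
    p = vapply(models, `[[`, numeric(1), "p"),
    loglik = vapply(models, `[[`, numeric(1), "loglik"),
    n_coef = vapply(models, function(x) length(x$coef), integer(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(table = tab, models = models), class = "cox_comparison")
}

#' @export
print.cox_comparison <- function(x, ...) {
  cat("Cox model comparison (TRS vs clinicopathologic factors):\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}
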