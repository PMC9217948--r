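#' Configuration for the synthetic-cohort generator
#'
#' Bundles and validates every knob of the simulator.  The generator plants a
#' binary mutation covariate that shifts the means of `n_mut_assoc` genes by
#' `deg_effect` standard deviations, and a prognostic subset of those genes
#' (`n_prognostic`) whose standardized expression drives a proportional-
#' hazards relapse process together with clinicopathologic covariates.
#'
#' @param n_samples Samples per cohort.
#' @param n_cohorts Number of cohorts; cohort 0 is the discovery cohort (no
#'   batch effect), later cohorts receive independent per-gene batch effects
#'   emulating platform differences.
#' @param n_genes Total genes.
#' @param n_mut_assoc Number of planted mutation-associated genes.
#' @param n_prognostic Number of planted genes that also carry outcome
#'   signal; must not exceed `n_mut_assoc`.
#' @param mut_prevalence Mutation probability per sample, in (0, 1).
#' @param deg_effect Standardized mean shift (log2 units / gene SD) added to
#'   planted genes in mutant samples.  Note the shift rides on every planted
#'   gene, so for outcome prediction it acts as noise aligned with the
#'   signature direction; large values cap the achievable AUC.
#' @param prog_effect Per-gene log-hazard coefficient on the standardized
#'   residual expression (net of the mutation shift).
#' @param mut_effect Direct log-hazard of mutation status (default 0.7, a
#'   hazard ratio of about 2 for mutant tumors).
#' @param baseline_hazard Events per time unit at average risk.
#' @param censor_time Administrative censoring time (time units, > 0).
#' @param cpf_effects Named numeric vector of clinicopathologic effects:
#'   `gleason` (per ordinal grade group 3+4 < 4+3 < other), `t_stage` (per
#'   stage step T1 < T2 < T3), `age` (per decade from 62).
#' @param batch_scale_sd,batch_shift_sd SDs of the per-cohort per-gene
#'   multiplicative (log-normal) scale and additive shift batch effects.
#' @param unexpressed_frac Fraction of background genes rendered
#'   "unexpressed" (exact zeros in a fraction of samples) so the
#'   expression filter is exercised.
#' @param unexpressed_zero_frac Fraction of samples in which an unexpressed
#'   gene is zero.
#' @param seed Master integer seed; per-cohort substreams are derived
#'   deterministically from it.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_samples = 200, n_cohorts = 2, n_genes = 1000,
                       n_mut_assoc = 100, n_prognostic = 15,
                       mut_prevalence = 0.3, deg_effect = 0.5,
                       prog_effect = 0.5, mut_effect = 0.7,
                       baseline_hazard = 0.05, censor_time = 10,
                       cpf_effects = c(gleason = 0.4, t_stage = 0.3, age = 0.2),
                       batch_scale_sd = 0.1, batch_shift_sd = 0.5,
                       unexpressed_frac = 0.05, unexpressed_zero_frac = 0.7,
                       seed = 1L) {
  cfg <- list(n_samples = n_samples, n_cohorts = n_cohorts, n_genes = n_genes,
              n_mut_assoc = n_mut_assoc, n_prognostic = n_prognostic,
              mut_prevalence = mut_prevalence, deg_effect = deg_effect,
              prog_effect = prog_effect, mut_effect = mut_effect,
              baseline_hazard = baseline_hazard,
              censor_time = censor_time, cpf_effects = cpf_effects,
              batch_scale_sd = batch_scale_sd, batch_shift_sd = batch_shift_sd,
              unexpressed_frac = unexpressed_frac,
              unexpressed_zero_frac = unexpressed_zero_frac,
              seed = as.integer(seed))
  chk <- function(ok, field, msg) if (!ok) stop("invalid sim_config field '", field, "': ", msg)
  chk(n_samples >= 2, "n_samples", "need at least 2 samples")
  chk(n_cohorts >= 1, "n_cohorts", "need at least 1 cohort")
  chk(n_prognostic <= n_mut_assoc, "n_prognostic", "must be <= n_mut_assoc")
  chk(n_mut_assoc <= n_genes, "n_mut_assoc", "must be <= n_genes")
  chk(mut_prevalence > 0 && mut_prevalence < 1, "mut_prevalence", "must lie in (0, 1)")
  chk(censor_time > 0, "censor_time", "must be > 0")
  chk(baseline_hazard > 0, "baseline_hazard", "must be > 0")
  chk(all(c("gleason", "t_stage", "age") %in% names(cpf_effects)),
      "cpf_effects", "needs named elements gleason, t_stage, age")
  chk(batch_scale_sd >= 0, "batch_scale_sd", "must be >= 0")
  chk(batch_shift_sd >= 0, "batch_shift_sd", "must be >= 0")
  chk(unexpressed_frac >= 0 && unexpressed_frac < 1, "unexpressed_frac", "must lie in [0, 1)")
  chk(unexpressed_zero_frac >= 0 && unexpressed_zero_frac <= 1,
      "unexpressed_zero_frac", "must lie in [0, 1]")
  structure(cfg, class = "sim_config")
}

# Gene-level ground truth shared by all cohorts of a study: baseline means,
# SDs, planted gene identities.  Drawn from the master seed only.
sim_truth_genes <- function(cfg) {
  set.seed(cfg$seed)
  gene_ids <- sprintf("g%04d", seq_len(cfg$n_genes))
  mu <- stats::rnorm(cfg$n_genes, 7, 2)
  sigma <- stats::runif(cfg$n_genes, 0.5, 1.5)
  deg_idx <- sample.int(cfg$n_genes, cfg$n_mut_assoc)
  prog_idx <- deg_idx[sample.int(cfg$n_mut_assoc, cfg$n_prognostic)]
  n_unexpr <- floor(cfg$unexpressed_frac * cfg$n_genes)
  pool <- setdiff(seq_len(cfg$n_genes), deg_idx)
  unexpr_idx <- if (n_unexpr > 0) sample(pool, min(n_unexpr, length(pool))) else integer(0)
  deg_eff <- numeric(cfg$n_genes); deg_eff[deg_idx] <- cfg$deg_effect
  prog_coef <- numeric(cfg$n_genes); prog_coef[prog_idx] <- cfg$prog_effect
  list(gene_ids = gene_ids, mu = mu, sigma = sigma,
       deg_idx = sort(deg_idx), prog_idx = sort(prog_idx),
       unexpr_idx = sort(unexpr_idx),
       deg_effect = deg_eff, prog_coef = prog_coef)
}

#' Simulate one cohort of expression and clinical data
#'
#' Background expression of gene g in sample i is Normal(mu_g, sigma_g^2) on
#' the log2 scale; planted mutation-associated genes get an extra
#' `deg_effect * sigma_g` in mutant samples.  The latent risk score sums
#' `prog_effect` times the standardized residual expression (net of the
#' mutation shift) of the prognostic genes, a direct mutation hazard term
#' `mut_effect`, and the clinicopathologic terms; relapse times are exponential with
#' hazard `baseline_hazard * exp(risk - mean(risk))`, administratively
#' censored at `censor_time`, and the binary endpoint is `+1` exactly when
#' the event occurs before censoring.  Cohorts with index >= 1 receive
#' independent per-gene batch effects (log-normal scale, normal shift).
#'
#' @param cfg A [sim_config()].
#' @param cohort_index 0-based cohort index; 0 = discovery cohort, no batch
#'   effect.
#' @return A list with elements `expression` (genes x samples matrix),
#'   `clinical` (see [validate_clinical()]) and `truth` (planted
#'   mutation-associated ids `deg_ids`, prognostic ids `prognostic_ids`,
#'   per-gene effects, per-sample latent `risk`).
#' @export
simulate_cohort <- function(cfg, cohort_index = 0) {
  stopifnot(inherits(cfg, "sim_config"), cohort_index >= 0)
  g <- sim_truth_genes(cfg)
  n <- cfg$n_samples
  # Per-cohort substream; +1 keeps cohort 0 off the gene-truth stream.
  set.seed(cfg$seed + as.integer(cohort_index) + 1L)
  sample_ids <- sprintf("c%d_s%03d", cohort_index, seq_len(n))

  mutant <- stats::rbinom(n, 1L, cfg$mut_prevalence) == 1L
  noise <- matrix(stats::rnorm(cfg$n_genes * n), cfg$n_genes, n)
  x <- noise * g$sigma + g$mu
  if (length(g$deg_idx)) {
    x[g$deg_idx, mutant] <- x[g$deg_idx, mutant] +
      cfg$deg_effect * g$sigma[g$deg_idx]
  }
  # Outcome signal rides on the standardized expression net of the mutation
  # shift: mutation moves the planted genes' means, while relapse risk tracks
  # their residual biological variation (summing shifted z-scores instead
  # would stack n_prognostic coherent copies of the mutation shift into the
  # log-hazard, letting mutation status alone dominate every outcome).
  z_prog <- noise[g$prog_idx, , drop = FALSE]

  gl_opts <- list(c(3L, 4L), c(4L, 3L), c(4L, 4L), c(3L, 5L), c(5L, 3L),
                  c(4L, 5L), c(5L, 4L), c(5L, 5L))
  gl_prob <- c(0.31, 0.23, 0.24, 0.02, 0.02, 0.09, 0.05, 0.04)
  gl_pick <- sample.int(length(gl_opts), n, replace = TRUE, prob = gl_prob)
  gleason_primary <- vapply(gl_opts[gl_pick], `[[`, integer(1), 1L)
  gleason_secondary <- vapply(gl_opts[gl_pick], `[[`, integer(1), 2L)
  gl_group <- ifelse(gleason_primary == 3L & gleason_secondary == 4L, 0L,
                     ifelse(gleason_primary == 4L & gleason_secondary == 3L, 1L, 2L))
  t_stage <- sample(c("T1", "T2", "T3"), n, replace = TRUE, prob = c(0.10, 0.55, 0.35))
  t_num <- match(t_stage, c("T1", "T2", "T3")) - 1L
  age <- stats::rnorm(n, 62, 7)

  risk <- cfg$prog_effect * colSums(z_prog) +
    cfg$mut_effect * as.numeric(mutant) +
    cfg$cpf_effects[["gleason"]] * gl_group +
    cfg$cpf_effects[["t_stage"]] * t_num +
    cfg$cpf_effects[["age"]] * (age - 62) / 10
  risk <- risk - mean(risk)

  latent_time <- stats::rexp(n, rate = cfg$baseline_hazard * exp(risk))
  rfs_event <- latent_time <= cfg$censor_time
  rfs_time <- pmin(latent_time, cfg$censor_time)
  bcr <- ifelse(rfs_event, 1L, -1L)

  if (cohort_index >= 1) {
    scale_g <- exp(stats::rnorm(cfg$n_genes, 0, cfg$batch_scale_sd))
    shift_g <- stats::rnorm(cfg$n_genes, 0, cfg$batch_shift_sd)
    x <- x * scale_g + shift_g
  }
  for (gi in g$unexpr_idx) {
    nz <- round(cfg$unexpressed_zero_frac * n)
    if (nz > 0) x[gi, sample.int(n, nz)] <- 0
  }
  dimnames(x) <- list(g$gene_ids, sample_ids)

  clinical <- data.frame(sample_id = sample_ids, tp53_mutant = mutant,
                         bcr = bcr, rfs_time = rfs_time, rfs_event = rfs_event,
                         gleason_primary = gleason_primary,
                         gleason_secondary = gleason_secondary,
                         t_stage = t_stage, age = age,
                         stringsAsFactors = FALSE)
  validate_clinical(clinical)
  truth <- list(deg_ids = g$gene_ids[g$deg_idx],
                prognostic_ids = g$gene_ids[g$prog_idx],
                unexpressed_ids = g$gene_ids[g$unexpr_idx],
                deg_effect = stats::setNames(g$deg_effect, g$gene_ids),
                prog_coef = stats::setNames(g$prog_coef, g$gene_ids),
                risk = stats::setNames(risk, sample_ids))
  list(expression = x, clinical = clinical, truth = truth)
}

#' Simulate a multi-cohort study
#'
#' Cohort 0 is the discovery cohort (no batch effect); cohorts 1..k receive
#' independent batch effects emulating platform differences between
#' validation cohorts.  All cohorts share the same planted gene-level truth.
#'
#' @param cfg A [sim_config()].
#' @return A list of cohorts as returned by [simulate_cohort()].
#' @export
simulate_study <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  lapply(seq_len(cfg$n_cohorts) - 1L, function(k) simulate_cohort(cfg, k))
}

#' Write a simulated study to disk
#'
#' Writes per-cohort `expr_<k>.tsv` and `clinical_<k>.tsv` plus a shared
#' `truth.json` under `dir`.
#'
#' @param study Output of [simulate_study()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (k in seq_along(study)) {
    write_expression(study[[k]]$expression,
                     file.path(dir, sprintf("expr_%d.tsv", k - 1L)))
    write_clinical(study[[k]]$clinical,
                   file.path(dir, sprintf("clinical_%d.tsv", k - 1L)))
  }
  tr <- study[[1L]]$truth
  jsonlite::write_json(list(deg_ids = tr$deg_ids, prognostic_ids = tr$prognostic_ids,
                            unexpressed_ids = tr$unexpressed_ids),
                       file.path(dir, "truth.json"))
  invisible(dir)
}
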