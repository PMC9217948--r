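#' Configuration of the stochastic signature-discovery run
#'
#' Defaults follow the published operating point: 1000 random subsets of 25
#' genes, a performance filter at AUC >= 0.65 and two-sided Fisher
#' p <= 1e-4 (both inclusive), at least 3 hits for a gene to enter the
#' initial signature, and a lower signature-size limit of 10 for the
#' wrapper.  The extended-analysis variant (2000 subsets, min_hits 2) is
#' reached by overriding `n_subsets` and `min_hits`.
#'
#' @param n_subsets Number of random gene subsets to sample and score.
#' @param subset_size Genes per subset.
#' @param auc_min Inclusive lower AUC cutoff for the filter.
#' @param p_max Inclusive upper two-sided Fisher p cutoff for the filter.
#' @param min_hits Minimum number of passing subsets a gene must appear in
#'   to join the initial signature.
#' @param k_min Lower limit on the size of the final signature.
#' @param spline_df Smoothing control for the wrapper's spline: "auto"
#'   (generalized cross-validation) or a numeric effective df.
#' @param seed Integer seed driving subset sampling.
#' @return A list of class `discovery_config`.
#' @export
discovery_config <- function(n_subsets = 1000, subset_size = 25,
                             auc_min = 0.65, p_max = 1e-4, min_hits = 3,
                             k_min = 10, spline_df = "auto", seed = 1L) {
  stopifnot(n_subsets >= 1, subset_size >= 2, auc_min >= 0, auc_min <= 1,
            p_max > 0, p_max <= 1, min_hits >= 1, k_min >= 1)
  if (!identical(spline_df, "auto")) stopifnot(is.numeric(spline_df), spline_df > 1)
  structure(list(n_subsets = as.integer(n_subsets),
                 subset_size = as.integer(subset_size),
                 auc_min = auc_min, p_max = p_max,
                 min_hits = as.integer(min_hits), k_min = as.integer(k_min),
                 spline_df = spline_df, seed = as.integer(seed)),
            class = "discovery_config")
}

#' Sample random gene subsets from the candidate pool
#'
#' Each subset holds `subset_size` distinct genes drawn uniformly without
#' replacement; subsets are sampled independently of each other (the same
#' subset may recur by chance).  Reproducible from `cfg$seed`.
#'
#' @param candidates Character vector of candidate gene ids.
#' @param cfg A [discovery_config()].
#' @return A list of `n_subsets` character vectors.
#' @export
sample_subsets <- function(candidates, cfg) {
  candidates <- as.character(candidates)
  if (length(candidates) < cfg$subset_size) {
    stop("sample_subsets: ", length(candidates), " candidates < subset_size = ",
         cfg$subset_size)
  }
  set.seed(cfg$seed)
  lapply(seq_len(cfg$n_subsets),
         function(i) sample(candidates, cfg$subset_size))
}

#' Filter scored subsets on AUC and Fisher p cutoffs
#'
#' Keeps subsets with `auc >= auc_min` and `p_two_sided <= p_max`, both
#' bounds inclusive.
#'
#' @param evals List of `signature_eval` objects (or any lists carrying
#'   `auc` and `p_two_sided`).
#' @param cfg A [discovery_config()].
#' @return Logical vector marking the selected subsets.
#' @export
filter_subsets <- function(evals, cfg) {
  auc <- vapply(evals, `[[`, numeric(1), "auc")
  p <- vapply(evals, `[[`, numeric(1), "p_two_sided")
  auc >= cfg$auc_min & p <= cfg$p_max
}

#' Collect the initial signature by hit counting
#'
#' Genes appearing in at least `min_hits` of the selected subsets form the
#' initial signature, returned in lexicographic order.
#'
#' @param selected_subsets List of gene-id vectors (the subsets that passed
#'   the filter).
#' @param cfg A [discovery_config()].
#' @return Character vector of initial-signature genes.
#' @export
initial_signature <- function(selected_subsets, cfg) {
  hits <- table(unlist(selected_subsets))
  genes <- sort(names(hits)[hits >= cfg$min_hits])
  if (length(genes) == 0) {
    stop("initial_signature: no gene reached ", cfg$min_hits,
         " hits; consider a larger n_subsets (e.g. 2000) and/or a smaller ",
         "min_hits (e.g. 2), or relaxed filter cutoffs")
  }
  genes
}

#' Leave-one-gene-out ranking of the initial signature
#'
#' For each gene g_i of the initial signature, computes the SVM-LOOCV AUC
#' obtained when every gene except g_i is used (vector A), then orders the
#' genes for backward elimination: genes whose removal yields the highest
#' AUC -- the most expendable, performance-eroding genes -- come first, so
#' the wrapper curve drops them before the signal-bearing core.  The sort
#' is stable (ties keep original order).
#'
#' @inheritParams svm_loocv
#' @param genes The initial signature (m genes).
#' @return List with `A` (AUCs in input gene order), `genes_sorted` (drop
#'   order: most expendable first), `A_sorted` (nonincreasing).
#' @export
wrapper_rank <- function(m, clinical, genes, settings = svm_settings()) {
  genes <- as.character(genes)
  A <- vapply(seq_along(genes), function(i) {
    evaluate_signature(m, clinical, genes[-i], settings)$auc
  }, numeric(1))
  ord <- order(-A)                      # stable: ties keep original order
  list(A = stats::setNames(A, genes),
       genes_sorted = genes[ord], A_sorted = A[ord])
}

#' Suffix AUC curve for the wrapper
#'
#' For i = 1 .. (m - k_min), computes B_i, the SVM-LOOCV AUC when the
#' suffix gene set \{g*_(i+1), ..., g*_m\} of the ranked signature is used,
#' and C_i = m - i, the corresponding gene count.  Because the drop order
#' removes the most expendable genes first, B typically rises while
#' redundant or eroding genes are shed and falls once the signal core is
#' reached -- the single-mode shape the spline stopping rule assumes.
#'
#' @inheritParams svm_loocv
#' @param genes_sorted Ranked genes from [wrapper_rank()].
#' @param cfg A [discovery_config()] (supplies `k_min`).
#' @return List with numeric `B` and integer `C` (strictly decreasing from
#'   m - 1 down to k_min).
#' @export
wrapper_curve <- function(m, clinical, genes_sorted, cfg,
                          settings = svm_settings()) {
  mm <- length(genes_sorted)
  if (mm < cfg$k_min + 2L) {
    stop("wrapper_curve: initial signature has ", mm,
         " genes; need at least k_min + 2 = ", cfg$k_min + 2L)
  }
  steps <- seq_len(mm - cfg$k_min)
  B <- vapply(steps, function(i) {
    evaluate_signature(m, clinical, genes_sorted[(i + 1L):mm], settings)$auc
  }, numeric(1))
  list(B = B, C = mm - steps)
}

# TRUE when a fitted curve rises then falls (at most one sign change of
# slope, + to -); flat segments are tolerated.
is_unimodal <- function(fit) {
  s <- sign(diff(fit))
  s <- s[s != 0]
  if (length(s) == 0) return(TRUE)
  changes <- sum(diff(s) != 0)
  changes == 0 || (changes == 1 && s[1] == 1)
}

#' Spline-guided stopping rule of the wrapper
#'
#' Fits a smoothing spline of B (suffix AUC) on C (gene count), locates the
#' mode c* of the fitted curve on a dense grid over the observed C range,
#' and selects the observed point with the largest C strictly below c* --
#' the data point adjacent to the mode from the left.  If no observed C
#' lies below c* (or the curve is flat), the smallest-C point is chosen
#' (parsimony).  If the spline cannot be fitted, the point with maximal B
#' is used instead (with a warning).
#'
#' With `spline_df = "auto"` the smoothing is chosen to honour the
#' procedure's premise that the curve is *single-mode*: the fit starts at
#' the effective df picked by generalized cross-validation and the df is
#' reduced stepwise until the fitted curve is unimodal over the grid
#' (GCV alone routinely returns a wiggly, multi-modal fit whose argmax is
#' an arbitrary local bump).  A numeric `spline_df` fixes the df directly.
#'
#' @param B,C Output of [wrapper_curve()].
#' @param genes_sorted Ranked genes from [wrapper_rank()].
#' @param cfg A [discovery_config()].
#' @return A list of class `wrapper_trace` with fields `B`, `C`,
#'   `spline_mode` (c*), `chosen_c`, `spline_df` (effective df used),
#'   `final_genes` and the fitted curve (`grid`, `fit`).
#' @export
wrapper_select <- function(B, C, genes_sorted, cfg) {
  stopifnot(length(B) == length(C), length(B) >= 3)
  mm <- length(genes_sorted)
  grid <- seq(min(C), max(C), length.out = 1000L)
  flat <- (max(B) - min(B)) < 1e-12
  cstar <- NA_real_
  fit <- NULL
  df_used <- NA_real_
  if (flat) {
    chosen_c <- min(C)                  # degenerate mode: parsimony
    fit <- rep(B[1L], length(grid))
    cstar <- min(C)
  } else {
    fit_df <- function(df) {
      tryCatch({
        sp <- if (is.null(df)) stats::smooth.spline(C, B, cv = FALSE)
              else stats::smooth.spline(C, B, df = df)
        list(df = sp$df, fit = stats::predict(sp, grid)$y)
      }, error = function(e) NULL)
    }
    sp <- if (identical(cfg$spline_df, "auto")) {
      s <- fit_df(NULL)
      if (!is.null(s)) {
        df <- s$df
        while (!is_unimodal(s$fit) && df > 2.5) {
          df <- max(df - 1, 2.5)
          s2 <- fit_df(df)
          if (is.null(s2)) break
          s <- s2
        }
      }
      s
    } else {
      fit_df(cfg$spline_df)
    }
    if (is.null(sp)) {
      warning("wrapper_select: spline fit failed; falling back to the ",
              "observed point with maximal AUC")
      chosen_c <- C[which.max(B)]
    } else {
      fit <- sp$fit
      df_used <- sp$df
      cstar <- grid[which.max(fit)]
      below <- C[C < cstar]
      chosen_c <- if (length(below)) max(below) else min(C)
    }
  }
  i <- mm - chosen_c                    # C_i = m - i
  final_genes <- genes_sorted[(i + 1L):mm]
  structure(list(B = B, C = C, spline_mode = cstar, chosen_c = chosen_c,
                 spline_df = df_used, grid = grid, fit = fit,
                 genes_sorted = genes_sorted, final_genes = final_genes),
            class = "wrapper_trace")
}

#' @export
print.wrapper_trace <- function(x, ...) {
  cat(sprintf("Wrapper trace: %d ranked genes, curve over C = %d..%d\n",
              length(x$genes_sorted), min(x$C), max(x$C)))
  cat(sprintf("  spline mode c* = %.2f -> chosen C = %d (%d final genes)\n",
              x$spline_mode, x$chosen_c, length(x$final_genes)))
  invisible(x)
}

#' Run the full stochastic signature-discovery pipeline
#'
#' Orchestrates subset sampling, SVM-LOOCV scoring, the AUC/p filter with
#' hit counting, and the spline-guided wrapper; every stochastic step is
#' driven by `cfg$seed`, so two runs with the same inputs are identical.
#'
#' @inheritParams svm_loocv
#' @param candidates Candidate gene pool (typically the mutation-associated
#'   genes from [deg_table()] / [select_deg()]).
#' @param cfg A [discovery_config()].
#' @return A list of class `discovery_result`: `final_genes`,
#'   `initial_genes`, `subset_report` (data frame: genes, auc, p_two_sided,
#'   selected), `rank` (leave-one-gene-out ranking), `trace`
#'   ([wrapper_select()] output), `config`, `settings`.
#' @export
discover <- function(m, clinical, candidates, cfg = discovery_config(),
                     settings = svm_settings()) {
  clinical <- align_cohort(m, clinical)
  subsets <- sample_subsets(candidates, cfg)
  evals <- lapply(subsets, function(g) {
    ev <- evaluate_signature(m, clinical, g, settings)
    list(auc = ev$auc, p_two_sided = ev$p_two_sided)
  })
  selected <- filter_subsets(evals, cfg)
  report <- data.frame(
    subset = seq_along(subsets),
    genes = vapply(subsets, paste, character(1), collapse = ","),
    auc = vapply(evals, `[[`, numeric(1), "auc"),
    p_two_sided = vapply(evals, `[[`, numeric(1), "p_two_sided"),
    selected = selected, stringsAsFactors = FALSE)
  if (!any(selected)) {
    stop("discover [filter]: no subset met auc >= ", cfg$auc_min,
         " and p <= ", cfg$p_max, "; consider more subsets or relaxed cutoffs")
  }
  init <- tryCatch(initial_signature(subsets[selected], cfg),
                   error = function(e) stop("discover [initial]: ", conditionMessage(e)))
  rank <- wrapper_rank(m, clinical, init, settings)
  curve <- wrapper_curve(m, clinical, rank$genes_sorted, cfg, settings)
  trace <- wrapper_select(curve$B, curve$C, rank$genes_sorted, cfg)
  structure(list(final_genes = trace$final_genes, initial_genes = init,
                 subset_report = report, rank = rank, trace = trace,
                 config = cfg, settings = settings),
            class = "discovery_result")
}

#' @export
print.discovery_result <- function(x, ...) {
  cat(sprintf(
    "Signature discovery: %d/%d subsets passed the filter; initial %d genes -> final %d genes\n",
    sum(x$subset_report$selected), nrow(x$subset_report),
    length(x$initial_genes), length(x$final_genes)))
  cat("Final signature:", paste(x$final_genes, collapse = ", "), "\n")
  invisible(x)
}

#' Serialize a discovery run's provenance to JSON
#'
#' @param result A `discovery_result`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_provenance <- function(result, path) {
  stopifnot(inherits(result, "discovery_result"))
  out <- list(
    seed = result$config$seed,
    config = unclass(result$config),
    settings = unclass(result$settings),
    subset_report = result$subset_report,
    initial_genes = result$initial_genes,
    rank = list(A = as.list(result$rank$A), genes_sorted = result$rank$genes_sorted),
    wrapper = list(B = result$trace$B, C = result$trace$C,
                   spline_mode = result$trace$spline_mode,
                   chosen_c = result$trace$chosen_c),
    final_genes = result$final_genes)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
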