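test_that("sample_subsets draws reproducible subsets of the requested shape", {
  cands <- sprintf("g%03d", 1:60)
  cfg <- discovery_config(n_subsets = 50, subset_size = 25, seed = 7)
  subs <- sample_subsets(cands, cfg)
  expect_length(subs, 50)
  expect_true(all(lengths(subs) == 25))
  expect_true(all(vapply(subs, anyDuplicated, integer(1)) == 0))
  expect_identical(subs, sample_subsets(cands, cfg))

  cfg_full <- discovery_config(n_subsets = 5, subset_size = 60, seed = 7)
  subs_full <- sample_subsets(cands, cfg_full)
  expect_true(all(vapply(subs_full, setequal, logical(1), cands)))

  expect_error(sample_subsets(cands[1:10], cfg), "candidates")
})

test_that("filter_subsets applies inclusive AUC and p cutoffs", {
  cfg <- discovery_config(auc_min = 0.65, p_max = 1e-4)
  evals <- list(list(auc = 0.66, p_two_sided = 5e-5),
                list(auc = 0.65, p_two_sided = 1e-4),
                list(auc = 0.64, p_two_sided = 1e-6),
                list(auc = 0.9, p_two_sided = 2e-4))
  expect_identical(filter_subsets(evals, cfg), c(TRUE, TRUE, FALSE, FALSE))
})

test_that("monotonicity: stricter cutoffs never enlarge the selection", {
  set.seed(8)
  evals <- lapply(1:100, function(i)
    list(auc = runif(1, 0.4, 1), p_two_sided = 10^runif(1, -8, 0)))
  base <- filter_subsets(evals, discovery_config(auc_min = 0.6, p_max = 1e-3))
  stricter_auc <- filter_subsets(evals, discovery_config(auc_min = 0.7, p_max = 1e-3))
  stricter_p <- filter_subsets(evals, discovery_config(auc_min = 0.6, p_max = 1e-5))
  expect_true(all(base[stricter_auc]))
  expect_true(all(base[stricter_p]))
})

test_that("initial_signature counts hits with a deterministic order", {
  subs <- list(c("b", "a", "c"), c("a", "b", "d"), c("a", "b", "e"), c("a", "f", "g"))
  expect_identical(initial_signature(subs, discovery_config(min_hits = 3)),
                   c("a", "b"))
  expect_identical(initial_signature(subs, discovery_config(min_hits = 2)),
                   c("a", "b"))
  expect_identical(initial_signature(subs, discovery_config(min_hits = 4)), "a")
  expect_error(initial_signature(list(), discovery_config()), "n_subsets")
  # hit-count bookkeeping: total hits = subset_size x number of subsets
  expect_equal(sum(table(unlist(subs))), 3 * 4)
})

test_that("wrapper_rank drops the most expendable gene first", {
  co <- make_separated_cohort(n = 24, d = 5, mu = 2, seed = 3)
  # add a pure-noise gene: its removal should give the best AUC, so it must
  # head the drop order
  set.seed(99)
  noise <- matrix(rnorm(24, 7, 3), 1, 24,
                  dimnames = list("g_noise", colnames(co$expression)))
  m <- rbind(co$expression, noise)
  # weaken separation so noise actually hurts
  m[1:5, ] <- m[1:5, ] * 0.2 + matrix(rnorm(5 * 24, 0, 0.8), 5, 24)
  rk <- wrapper_rank(m, co$clinical, rownames(m))
  expect_length(rk$A, 6)
  expect_identical(sort(unname(rk$A_sorted), decreasing = TRUE),
                   unname(rk$A_sorted))
  expect_identical(rk$genes_sorted[1],
                   names(which.max(rk$A)))
  expect_identical(rk$genes_sorted[1], "g_noise")

  # duplicate-column genes tie and keep original relative order
  m2 <- co$expression[c(1, 1, 2, 3), ]
  rownames(m2) <- c("gA", "gB", "gC", "gD")
  rk2 <- wrapper_rank(m2, co$clinical, rownames(m2))
  dup <- which(rk2$genes_sorted %in% c("gA", "gB"))
  expect_identical(rk2$genes_sorted[dup], c("gA", "gB"))
})

test_that("wrapper_curve produces the suffix-AUC ladder", {
  co <- make_noise_cohort(n = 26, d = 16, seed = 17)
  cfg <- discovery_config(k_min = 10)
  genes <- rownames(co$expression)
  cv <- wrapper_curve(co$expression, co$clinical, genes, cfg)
  expect_length(cv$B, 6)
  expect_identical(cv$C, seq(15L, 10L))
  # all-noise ranked list hovers near chance
  expect_lt(max(abs(cv$B - 0.5)), 0.3)
  expect_error(wrapper_curve(co$expression, co$clinical, genes[1:11], cfg),
               "k_min")
})

test_that("wrapper_select follows the spline mode rule on constructed curves", {
  genes <- sprintf("g%02d", 1:30)
  C <- 29:10
  cfg <- discovery_config(k_min = 10)
  # unimodal curve peaking at C = 18
  B <- 0.8 - 0.002 * (C - 18)^2
  tr <- wrapper_select(B, C, genes, cfg)
  expect_equal(tr$chosen_c, 18)
  expect_length(tr$final_genes, 18)
  expect_identical(tr$final_genes, genes[13:30])
  expect_true(all(tr$final_genes %in% genes))

  # flat curve -> parsimony: smallest C
  tr_flat <- wrapper_select(rep(0.7, 20), C, genes, cfg)
  expect_equal(tr_flat$chosen_c, 10)
  expect_length(tr_flat$final_genes, 10)

  # strictly increasing in C -> mode at max C, chosen point second-largest C
  tr_inc <- wrapper_select(0.5 + 0.01 * (C - 9), C, genes, cfg)
  expect_equal(tr_inc$chosen_c, 28)
})

test_that("wrapper never returns fewer than k_min genes", {
  set.seed(23)
  genes <- sprintf("g%02d", 1:25)
  C <- 24:12
  for (rep in 1:20) {
    B <- runif(length(C), 0.5, 0.9)
    tr <- wrapper_select(B, C, genes, discovery_config(k_min = 12))
    expect_gte(length(tr$final_genes), 12)
    expect_lte(length(tr$final_genes), 24)
  }
})

test_that("discover is deterministic end to end and recovers planted genes", {
  cfg <- sim_config(n_samples = 100, n_genes = 300, n_mut_assoc = 40,
                    n_prognostic = 10, prog_effect = 1, seed = 61)
  co <- simulate_cohort(cfg, 0)
  dcfg <- discovery_config(n_subsets = 60, subset_size = 10, min_hits = 2,
                           k_min = 5, seed = 13)
  r1 <- discover(co$expression, co$clinical, co$truth$deg_ids, dcfg)
  r2 <- discover(co$expression, co$clinical, co$truth$deg_ids, dcfg)
  expect_identical(r1$final_genes, r2$final_genes)
  expect_identical(r1$subset_report, r2$subset_report)
  expect_identical(r1$trace$B, r2$trace$B)

  # provenance round-trips through JSON with identical content
  p1 <- withr::local_tempfile(fileext = ".json")
  p2 <- withr::local_tempfile(fileext = ".json")
  write_provenance(r1, p1); write_provenance(r2, p2)
  expect_identical(readLines(p1), readLines(p2))

  # the planted prognostic genes dominate the hit counts
  sel <- r1$subset_report$selected
  hits <- table(unlist(strsplit(r1$subset_report$genes[sel], ",")))
  top <- names(sort(hits, decreasing = TRUE))[1:5]
  expect_gt(mean(top %in% co$truth$prognostic_ids), 0.5)
})

test_that("an all-null cohort yields no passing subsets", {
  cfg <- sim_config(n_samples = 60, n_genes = 120, n_mut_assoc = 30,
                    n_prognostic = 2, deg_effect = 0, prog_effect = 0,
                    mut_effect = 0, seed = 71)
  co <- simulate_cohort(cfg, 0)
  dcfg <- discovery_config(n_subsets = 40, subset_size = 10, seed = 5)
  expect_error(
    discover(co$expression, co$clinical, co$truth$deg_ids, dcfg),
    "no subset|no gene")
})
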