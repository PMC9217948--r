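test_that("auc_from_scores matches hand-worked examples and brute-force enumeration", {
  expect_equal(auc_from_scores(c(1, -1), c(2, 1)), 1)
  expect_equal(auc_from_scores(c(1, -1, 1, -1), rep(0.3, 4)), 0.5)
  expect_equal(auc_from_scores(c(1, 1, -1, -1), c(0.9, 0.2, 0.5, 0.1)), 0.75)
  expect_error(auc_from_scores(c(1, 1), c(0.2, 0.4)), "both classes")

  set.seed(11)
  for (rep in 1:300) {
    n <- sample(4:30, 1)
    y <- c(1, -1, sample(c(-1, 1), n - 2, TRUE))
    t <- sample(round(rnorm(n), 1))  # rounded scores force ties
    expect_equal(auc_from_scores(y, t), auc_bruteforce(y, t), tolerance = 1e-12)
  }
})

test_that("AUC is invariant under strictly increasing score transforms", {
  set.seed(12)
  y <- sample(c(-1, 1), 30, TRUE, prob = c(0.6, 0.4))
  y[1:2] <- c(1, -1)
  t <- rnorm(30)
  a0 <- auc_from_scores(y, t)
  expect_equal(auc_from_scores(y, exp(t)), a0, tolerance = 1e-12)
  expect_equal(auc_from_scores(y, 3 * t - 100), a0, tolerance = 1e-12)
})

test_that("fisher_exact matches hypergeometric enumeration", {
  expect_equal(fisher_exact(matrix(c(2, 0, 0, 2), 2), "greater"), 1 / 6,
               tolerance = 1e-12)
  expect_equal(fisher_exact(matrix(c(0, 0, 3, 4), 2), "two_sided"), 1)
  expect_error(fisher_exact(matrix(c(-1, 0, 1, 2), 2)), "non-negative")

  tab <- matrix(c(10, 3, 2, 15), 2)
  expect_equal(fisher_exact(tab, "two_sided"), fisher_enum(tab, "two_sided"),
               tolerance = 1e-12)

  set.seed(13)
  for (rep in 1:200) {
    tab <- matrix(rpois(4, 4), 2)
    if (sum(tab) > 40 || sum(tab) == 0) next
    expect_equal(fisher_exact(tab, "two_sided"), fisher_enum(tab, "two_sided"),
                 tolerance = 1e-12)
    expect_equal(fisher_exact(tab, "greater"), fisher_enum(tab, "greater"),
                 tolerance = 1e-12)
  }
})

test_that("default class weights follow the reciprocal-ratio rule", {
  expect_equal(default_class_weights(c(rep(1, 10), rep(-1, 30))),
               c("1" = 3, "-1" = 1))
  expect_equal(default_class_weights(c(rep(1, 5), rep(-1, 5)))[["1"]], 1)
  expect_equal(default_class_weights(c(1, rep(-1, 4)))[["1"]], 4)
  expect_error(default_class_weights(rep(1, 4)), "both classes")
})

test_that("svm_settings validates hyperparameters", {
  expect_error(svm_settings(cost = -1))
  expect_error(svm_settings(gamma = "tuned"), "gamma")
  expect_error(svm_settings(class_weights = c(a = 1, b = 2)), "names")
  s <- svm_settings("radial", cost = 0.105, gamma = (2 / 3) / 25)
  expect_equal(s$gamma, (2 / 3) / 25)
})

test_that("LOOCV separates two well-separated clusters perfectly", {
  co <- make_separated_cohort(n = 20, d = 3, mu = 3)
  ev <- evaluate_signature(co$expression, co$clinical, rownames(co$expression))
  expect_identical(unname(ev$predicted), co$clinical$bcr)
  expect_equal(ev$auc, 1)
  expect_length(ev$decision, 20)
  expect_equal(sum(ev$contingency), 20)
})

test_that("shortcut LOOCV equals the naive per-fold loop", {
  for (seed in 1:4) {
    co <- make_noise_cohort(n = 30, d = 4, seed = seed)
    genes <- rownames(co$expression)
    fast <- svm_loocv(co$expression, co$clinical, genes)
    slow <- naive_loocv(co$expression, co$clinical, genes)
    expect_equal(unname(fast$decision), slow$decision, tolerance = 5e-3)
    expect_identical(unname(fast$predicted), slow$predicted)
  }
  # radial kernel path as well
  co <- make_noise_cohort(n = 24, d = 4, seed = 9)
  fast <- svm_loocv(co$expression, co$clinical, rownames(co$expression),
                    svm_settings("radial"))
  slow_dv <- naive_loocv(co$expression, co$clinical, rownames(co$expression),
                         kernel = "radial")$decision
  expect_equal(unname(fast$decision), slow_dv, tolerance = 5e-3)
})

test_that("LOOCV never leaks the left-out label", {
  for (seed in 1:6) {
    co <- make_noise_cohort(n = 40, d = 6, seed = seed)
    genes <- rownames(co$expression)
    base <- svm_loocv(co$expression, co$clinical, genes)
    i <- sample(40, 1)
    flipped <- co$clinical
    flipped$bcr[i] <- -flipped$bcr[i]
    flipped$rfs_event[i] <- flipped$bcr[i] == 1
    flipped$rfs_time[i] <- if (flipped$rfs_event[i]) 5 else 10
    alt <- svm_loocv(co$expression, flipped, genes)
    expect_identical(unname(base$predicted[i]), unname(alt$predicted[i]))
  }
})

test_that("evaluation errors are informative", {
  co <- make_noise_cohort(n = 20, d = 3)
  expect_error(svm_loocv(co$expression, co$clinical, c("g01", "nope")), "nope")
  one_class <- co$clinical
  one_class$bcr <- rep(-1L, 20); one_class$rfs_event <- FALSE
  one_class$rfs_time <- 10
  expect_error(svm_loocv(co$expression, one_class, "g01"), "both BCR classes")
})

test_that("null expression yields chance-level AUC on average", {
  aucs <- vapply(1:10, function(s) {
    co <- make_noise_cohort(n = 60, d = 8, seed = s + 100)
    evaluate_signature(co$expression, co$clinical, rownames(co$expression))$auc
  }, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.15)
})

test_that("cross-cohort evaluation trains once and respects class checks", {
  cfg <- sim_config(n_samples = 80, n_genes = 60, n_mut_assoc = 12,
                    n_prognostic = 6, prog_effect = 1, n_cohorts = 2, seed = 44)
  st <- simulate_study(cfg)
  genes <- st[[1]]$truth$prognostic_ids
  cx <- evaluate_cross_cohort(st[[1]], st[[2]], genes)
  expect_length(cx$decision, 80)
  expect_gt(cx$auc, 0.6)

  # resubstitution (train = test) is at least as good as LOOCV on same data
  loocv_auc <- evaluate_signature(st[[1]]$expression, st[[1]]$clinical, genes)$auc
  resub <- evaluate_cross_cohort(st[[1]], st[[1]], genes)
  expect_gte(resub$auc + 1e-9, loocv_auc)

  bad <- st[[2]]
  bad$clinical$bcr <- rep(-1L, 80)
  bad$clinical$rfs_event <- FALSE; bad$clinical$rfs_time <- 10
  expect_error(evaluate_cross_cohort(st[[1]], bad, genes), "both classes")
})

test_that("global scale distortion degrades radial-kernel transfer; q75 homogenization recovers it", {
  cfg <- sim_config(n_samples = 100, n_genes = 80, n_mut_assoc = 16,
                    n_prognostic = 8, prog_effect = 1, n_cohorts = 2,
                    batch_scale_sd = 0, batch_shift_sd = 0,
                    unexpressed_frac = 0, seed = 55)
  st <- simulate_study(cfg)
  genes <- st[[1]]$truth$prognostic_ids
  shifted <- list(expression = 2.5 * st[[2]]$expression,
                  clinical = st[[2]]$clinical)
  rbf <- svm_settings("radial")
  raw <- evaluate_cross_cohort(st[[1]], shifted, genes, rbf)
  h <- homogenize_q75(st[[1]]$expression, shifted$expression)
  fixed <- evaluate_cross_cohort(
    st[[1]], list(expression = h$b, clinical = st[[2]]$clinical), genes, rbf)
  expect_gt(fixed$auc, raw$auc + 0.05)

  # a linear kernel's ranking is invariant to the same global rescale
  lin_raw <- evaluate_cross_cohort(st[[1]], shifted, genes)
  lin_fixed <- evaluate_cross_cohort(
    st[[1]], list(expression = h$b, clinical = st[[2]]$clinical), genes)
  expect_equal(lin_raw$auc, lin_fixed$auc, tolerance = 1e-9)
})
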