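# Fixture builders and independent oracles shared across the test files.

# A minimal clinical table consistent with the schema, given labels y in
# {-1, +1}.  Times/events follow the binary-endpoint convention.
make_clinical <- function(sample_ids, y, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(sample_ids)
  ev <- y == 1
  data.frame(
    sample_id = sample_ids,
    tp53_mutant = rep_len(c(TRUE, FALSE), n),
    bcr = as.integer(y),
    rfs_time = ifelse(ev, runif(n, 0.5, 8), 10),
    rfs_event = ev,
    gleason_primary = rep_len(c(3L, 4L), n),
    gleason_secondary = rep_len(c(4L, 3L), n),
    t_stage = rep_len(c("T1", "T2", "T3"), n),
    age = seq(50, 70, length.out = n),
    stringsAsFactors = FALSE)
}

# Two geometrically separated classes: class +1 centered at +mu, class -1
# at -mu in every gene.
make_separated_cohort <- function(n = 20, d = 3, mu = 3, seed = 1) {
  set.seed(seed)
  y <- rep(c(1L, -1L), length.out = n)
  x <- matrix(rnorm(n * d, sd = 0.5), d, n) + matrix(mu * y, d, n, byrow = TRUE)
  dimnames(x) <- list(sprintf("g%02d", seq_len(d)), sprintf("s%02d", seq_len(n)))
  list(expression = x, clinical = make_clinical(colnames(x), y))
}

# A random-noise cohort with random labels (both classes guaranteed).
make_noise_cohort <- function(n = 40, d = 5, seed = 1) {
  set.seed(seed)
  y <- c(rep(1L, ceiling(n / 3)), rep(-1L, n - ceiling(n / 3)))
  y <- sample(y)
  x <- matrix(rnorm(n * d, mean = 7), d, n)
  dimnames(x) <- list(sprintf("g%02d", seq_len(d)), sprintf("s%02d", seq_len(n)))
  list(expression = x, clinical = make_clinical(colnames(x), y))
}

# Naive per-fold SVM-LOOCV using e1071 directly: the independent oracle for
# the package's shortcut implementation.
naive_loocv <- function(m, clinical, genes, kernel = "linear", cost = 1) {
  x <- t(m[genes, , drop = FALSE])
  y <- clinical$bcr[match(rownames(x), clinical$sample_id)]
  n <- length(y)
  dv <- numeric(n)
  for (i in seq_len(n)) {
    yt <- y[-i]
    w <- c("1" = sum(yt == -1) / sum(yt == 1), "-1" = 1)
    fit <- e1071::svm(x[-i, , drop = FALSE], factor(yt, levels = c(-1, 1)),
                      type = "C-classification", kernel = kernel, cost = cost,
                      gamma = 1 / ncol(x), class.weights = w, scale = FALSE)
    p <- predict(fit, x[i, , drop = FALSE], decision.values = TRUE)
    d <- drop(attr(p, "decision.values"))
    if (startsWith(colnames(attr(p, "decision.values")), "-1")) d <- -d
    dv[i] <- d
  }
  list(decision = dv, predicted = ifelse(dv >= 0, 1L, -1L))
}

# Brute-force pairwise AUC oracle.
auc_bruteforce <- function(y, t) {
  tp <- t[y == 1]; tn <- t[y == -1]
  s <- 0
  for (a in tp) for (b in tn) s <- s + (a > b) + 0.5 * (a == b)
  s / (length(tp) * length(tn))
}

# Full hypergeometric enumeration oracle for a 2x2 table with fixed margins.
# Two-sided: sum of point probabilities <= observed (with the standard
# 1 + 1e-7 relative tolerance); greater: upper tail on cell [1,1].
fisher_enum <- function(tab, alternative = "two_sided") {
  a <- tab[1, 1]
  m1 <- sum(tab[1, ]); m2 <- sum(tab[2, ]); k <- sum(tab[, 1])
  lo <- max(0, k - m2); hi <- min(k, m1)
  xs <- lo:hi
  probs <- dhyper(xs, m1, m2, k)
  p_obs <- dhyper(a, m1, m2, k)
  if (alternative == "greater") sum(probs[xs >= a])
  else sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Brute-force Benjamini-Hochberg step-up oracle.
bh_bruteforce <- function(p) {
  n <- length(p)
  o <- order(p)
  ranked <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(ranked)))
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

# 1-D grid-search maximizer of the Breslow Cox partial log-likelihood for a
# single covariate.
cox_grid_oracle <- function(x, times, events, lo = -5, hi = 5, tol = 1e-5) {
  pll <- function(beta) {
    eta <- beta * x
    ll <- 0
    for (tt in sort(unique(times[events]))) {
      d <- which(events & times == tt)
      risk <- which(times >= tt)
      ll <- ll + sum(eta[d]) - length(d) * log(sum(exp(eta[risk])))
    }
    ll
  }
  opt <- optimize(pll, c(lo, hi), maximum = TRUE, tol = tol)
  opt$maximum
}
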