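test_that("empirical ROC handles separation, ties, and matches brute force", {
  r <- empirical_roc(c(1, 2, 3, 4), c(0, 0, 1, 1))
  expect_true(any(r$fpr == 0 & r$tpr == 1))
  expect_equal(r$fpr[1], 0); expect_equal(r$tpr[1], 0)
  expect_equal(r$fpr[length(r$fpr)], 1)
  expect_equal(r$tpr[length(r$tpr)], 1)

  # all scores tied: two-point diagonal
  r2 <- empirical_roc(rep(1, 6), c(0, 1, 0, 1, 0, 1))
  expect_equal(r2$fpr, c(0, 1))
  expect_equal(r2$tpr, c(0, 1))

  # operating points match exhaustive threshold enumeration
  set.seed(5)
  for (i in 1:10) {
    sc <- round(runif(6, 0, 4), 1)
    lb <- c(1, 1, 0, 0, sample(0:1, 2, TRUE))
    if (sum(lb) %in% c(0, 6)) next
    r3 <- empirical_roc(sc, lb)
    for (k in seq_along(r3$thresholds)) {
      t <- r3$thresholds[k]
      expect_equal(r3$tpr[k], mean(sc[lb == 1] >= t))
      expect_equal(r3$fpr[k], mean(sc[lb == 0] >= t))
    }
  }
  expect_error(empirical_roc(1:3, c(1, 1, 1)), class = "degenerate_labels")
})

test_that("AUC equals exhaustive pair counting and the trapezoidal area", {
  expect_equal(roc_auc(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1)
  # tied fixture, frozen from the pair-count oracle
  expect_equal(roc_auc(c(3, 1, 2, 2), c(1, 0, 0, 1)), 0.875)

  set.seed(11)
  for (i in 1:40) {
    n <- sample(4:8, 1)
    sc <- sample(seq(0, 5, by = 0.5), n, replace = TRUE)
    lb <- rbinom(n, 1, 0.5)
    if (sum(lb) %in% c(0, n)) next
    expect_identical(roc_auc(sc, lb), auc_pair_oracle(sc, lb))
    r <- empirical_roc(sc, lb)
    trap <- sum(diff(r$fpr) * (utils::head(r$tpr, -1) + utils::tail(r$tpr, -1)) / 2)
    expect_equal(r$auc, trap, tolerance = 1e-12)
    if (!anyDuplicated(sc)) {
      expect_equal(roc_auc(sc, lb) + roc_auc(-sc, lb), 1)
    }
  }
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(21)
  sc <- rnorm(40); lb <- rbinom(40, 1, 0.5)
  expect_equal(roc_auc(sc, lb),
               as.numeric(pROC::auc(pROC::roc(lb, sc, quiet = TRUE,
                                              direction = "<"))))
})

test_that("stratified bootstrap AUC CI is seeded and sane", {
  sc <- c(1, 2, 3, 10, 11, 12); lb <- c(0, 0, 0, 1, 1, 1)
  res <- auc_ci(sc, lb, n_boot = 200, seed = 4)
  expect_equal(res$ci_low, 1)
  expect_equal(res$ci_high, 1)

  set.seed(31)
  sc2 <- rnorm(30) + rep(c(0, 1), 15); lb2 <- rep(c(0, 1), 15)
  a1 <- auc_ci(sc2, lb2, n_boot = 500, seed = 7)
  a2 <- auc_ci(sc2, lb2, n_boot = 500, seed = 7)
  expect_identical(a1, a2)
  expect_true(a1$ci_low <= a1$ci_high)
  expect_true(a1$ci_low >= 0 && a1$ci_high <= 1)
})

test_that("bootstrap CIs cover a known AUC and shrink with sample size", {
  # generator with binormal AUC ~0.9: separation qnorm(0.9)*sqrt(2)
  delta <- qnorm(0.9) * sqrt(2)
  cover <- 0
  widths <- matrix(NA_real_, 10, 2)
  for (r in 1:10) {
    set.seed(600 + r)
    for (j in 1:2) {
      n <- c(30, 120)[j]
      lb <- rep(0:1, each = n / 2)
      sc <- rnorm(n) + delta * lb
      ci <- auc_ci(sc, lb, n_boot = 300, seed = 800 + r)
      widths[r, j] <- ci$ci_high - ci$ci_low
      if (j == 1 && ci$ci_low <= 0.9 && 0.9 <= ci$ci_high) cover <- cover + 1
    }
  }
  expect_gte(cover, 8)  # ~95% nominal coverage over 10 replicates
  expect_lt(mean(widths[, 2]), mean(widths[, 1]))
})

test_that("paired DeLong test: identity, antisymmetry, oracle agreement", {
  lb <- rep(c(1, 0), each = 6)
  set.seed(13)
  a <- rnorm(12) + lb
  d0 <- delong_test(a, a, lb)
  expect_equal(d0$diff, 0)
  expect_equal(d0$p_value, 1)

  b <- rnorm(12) + 0.3 * lb
  dab <- delong_test(a, b, lb)
  dba <- delong_test(b, a, lb)
  expect_equal(dab$diff, -dba$diff)
  expect_equal(dab$p_value, dba$p_value)
  expect_true(dab$se >= 0)
})

test_that("DeLong matches an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(17)
  lb <- rbinom(40, 1, 0.5)
  a <- rnorm(40) + lb; b <- rnorm(40) + 0.5 * lb
  ours <- delong_test(a, b, lb)
  ra <- pROC::roc(lb, a, quiet = TRUE, direction = "<")
  rb <- pROC::roc(lb, b, quiet = TRUE, direction = "<")
  ref <- pROC::roc.test(ra, rb, method = "delong", paired = TRUE)
  expect_equal(ours$p_value, ref$p.value, tolerance = 1e-9)
})

test_that("sensitivity/specificity at a threshold and the selection rule", {
  sc <- c(10, 20, 30, 5, 8, 2); lb <- c(1, 1, 1, 0, 0, 0)
  low <- sens_spec_at_threshold(sc, lb, threshold = 1, n_boot = 50, seed = 1)
  expect_equal(low$sensitivity, 1)
  high <- sens_spec_at_threshold(sc, lb, threshold = 99, n_boot = 50, seed = 1)
  expect_equal(high$sensitivity, 0)
  expect_equal(high$specificity, 1)

  # 21 of 28 positives at or above 15%: sensitivity 0.75
  set.seed(2)
  pos <- c(runif(21, 15, 80), runif(7, -10, 14.9))
  neg <- runif(37, -40, 10)
  sc2 <- c(pos, neg); lb2 <- rep(c(1, 0), c(28, 37))
  tp <- sens_spec_at_threshold(sc2, lb2, threshold = 15,
                               n_boot = 500, seed = 3)
  expect_equal(tp$sensitivity, 0.75)

  tab <- threshold_performance(sc2, lb2, grid = seq(15, 40, 5),
                               n_boot = 300, seed = 5)
  expect_identical(tab$selected,
                   tab$sens_low <= 0.8 & 0.8 <= tab$sens_high)
  expect_identical(optimal_threshold_range(sc2, lb2, grid = seq(15, 40, 5),
                                           n_boot = 300, seed = 5),
                   tab$threshold[tab$selected])
})
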