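# Empirical ROC analysis of percent-change scores against binary reference
# labels. Orientation convention: larger score = more indicative of the
# positive class, so percent change is used as-is for detecting progression
# and negated for detecting response.

check_binary <- function(labels) {
  labels <- as.integer(as.logical(labels))
  if (anyNA(labels)) stop_volresp("labels must be binary", class = "degenerate_labels")
  if (sum(labels) == 0 || sum(labels) == length(labels)) {
    stop_volresp("need at least one positive and one negative label",
                 class = "degenerate_labels")
  }
  labels
}

#' Empirical ROC curve
#'
#' Operating points at every distinct score value (ties grouped), with the
#' (0,0) and (1,1) endpoints. A case is called positive when its score is
#' greater than or equal to the threshold.
#'
#' @param scores Numeric scores (e.g. signed percent change).
#' @param labels Binary reference labels (logical or 0/1); at least one of
#'   each class.
#' @return A `roc_curve`: list with `thresholds` (decreasing, starting at
#'   `Inf`), `fpr`, `tpr`, `n_pos`, `n_neg`, and `auc`.
#' @export
empirical_roc <- function(scores, labels) {
  labels <- check_binary(labels)
  if (length(scores) != length(labels)) {
    stop_volresp("scores and labels must have equal length",
                 class = "length_mismatch")
  }
  if (anyNA(scores)) stop_volresp("scores must not be NA", class = "invalid_scores")
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(thr, function(t) mean(scores[labels == 1] >= t), 0)
  fpr <- vapply(thr, function(t) mean(scores[labels == 0] >= t), 0)
  structure(
    list(thresholds = thr, fpr = fpr, tpr = tpr,
         n_pos = sum(labels == 1), n_neg = sum(labels == 0),
         auc = roc_auc(scores, labels)),
    class = "roc_curve"
  )
}

#' @export
print.roc_curve <- function(x, ...) {
  cat("Empirical ROC curve:", length(x$thresholds), "operating points,",
      x$n_pos, "positives /", x$n_neg, "negatives, AUC =",
      sprintf("%.3f", x$auc), "\n")
  invisible(x)
}

#' @export
plot.roc_curve <- function(x, ...) {
  graphics::plot(x$fpr, x$tpr, type = "s", xlim = c(0, 1), ylim = c(0, 1),
                 xlab = "False positive rate", ylab = "True positive rate", ...)
  graphics::abline(0, 1, lty = 3, col = "grey50")
  invisible(x)
}

#' Area under the empirical ROC curve
#'
#' Computed as the Mann-Whitney statistic: the mean over positive/negative
#' pairs of `1[s+ > s-] + 0.5 * 1[s+ = s-]` (rank formulation).
#'
#' @inheritParams empirical_roc
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- check_binary(labels)
  r <- rank(scores)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Stratified resample: positives and negatives drawn separately with
# replacement, preserving class counts.
stratified_indices <- function(labels) {
  pos <- which(labels == 1); neg <- which(labels == 0)
  c(sample(pos, length(pos), replace = TRUE),
    sample(neg, length(neg), replace = TRUE))
}

#' AUC with stratified-bootstrap confidence interval
#'
#' Positives and negatives are resampled separately with replacement (class
#' counts preserved); the CI is the percentile interval of the bootstrap AUC
#' distribution. Fully reproducible for a given `seed`.
#'
#' @inheritParams empirical_roc
#' @param n_boot Number of bootstrap replicates (default 2000).
#' @param seed Integer seed; required for reproducibility.
#' @param conf Confidence level (default 0.95).
#' @return An `auc_result`: list with `auc`, `ci_low`, `ci_high`, `n_boot`,
#'   `seed`, `conf`.
#' @export
auc_ci <- function(scores, labels, n_boot = 2000, seed = 1, conf = 0.95) {
  labels <- check_binary(labels)
  stopifnot(n_boot >= 1)
  set.seed(seed)
  boots <- vapply(seq_len(n_boot), function(i) {
    idx <- stratified_indices(labels)
    roc_auc(scores[idx], labels[idx])
  }, 0)
  qs <- stats::quantile(boots, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                        names = FALSE)
  structure(
    list(auc = roc_auc(scores, labels), ci_low = qs[1], ci_high = qs[2],
         n_boot = n_boot, seed = seed, conf = conf),
    class = "auc_result"
  )
}

#' @export
print.auc_result <- function(x, ...) {
  cat(sprintf("AUC %.3f (%.0f%% CI %.3f-%.3f; %d stratified bootstrap reps)\n",
              x$auc, 100 * x$conf, x$ci_low, x$ci_high, x$n_boot))
  invisible(x)
}

# Placement values: for each positive, the fraction of negatives it beats
# (ties half); for each negative, the fraction of positives beating it.
delong_placements <- function(scores, labels) {
  sp <- scores[labels == 1]; sn <- scores[labels == 0]
  v10 <- vapply(sp, function(s) mean((s > sn) + 0.5 * (s == sn)), 0)
  v01 <- vapply(sn, function(s) mean((sp > s) + 0.5 * (sp == s)), 0)
  list(v10 = v10, v01 = v01, auc = mean(v10))
}

#' Paired DeLong test for two correlated AUCs
#'
#' Tests the difference between the AUCs of two score vectors measured on the
#' same cases against the same binary labels, using the placement-value
#' covariance estimate of the variance of the AUC difference and a two-sided
#' normal p-value.
#'
#' @param scores_a,scores_b Numeric scores for the same cases.
#' @inheritParams empirical_roc
#' @return A `delong_test`: list with `auc_a`, `auc_b`, `diff`, `se`, `z`,
#'   `p_value`.
#' @export
delong_test <- function(scores_a, scores_b, labels) {
  labels <- check_binary(labels)
  stopifnot(length(scores_a) == length(labels),
            length(scores_b) == length(labels))
  pa <- delong_placements(scores_a, labels)
  pb <- delong_placements(scores_b, labels)
  m <- length(pa$v10); n <- length(pa$v01)
  d10 <- pa$v10 - pb$v10
  d01 <- pa$v01 - pb$v01
  var_diff <- stats::var(d10) / m + stats::var(d01) / n
  diff <- pa$auc - pb$auc
  if (var_diff <= 0) {
    if (abs(diff) > 0) {
      warning("zero DeLong variance with nonzero AUC difference; p = 0",
              call. = FALSE)
      z <- sign(diff) * Inf; p <- 0
    } else {
      z <- 0; p <- 1
    }
  } else {
    z <- diff / sqrt(var_diff)
    p <- 2 * stats::pnorm(-abs(z))
  }
  structure(
    list(auc_a = pa$auc, auc_b = pb$auc, diff = diff,
         se = sqrt(max(var_diff, 0)), z = z, p_value = p),
    class = "delong_test"
  )
}

#' @export
print.delong_test <- function(x, ...) {
  cat(sprintf(
    "Paired DeLong test: AUC %.3f vs %.3f (diff %+.3f), z = %.3f, p = %.4g\n",
    x$auc_a, x$auc_b, x$diff, x$z, x$p_value))
  invisible(x)
}

#' Sensitivity and specificity at a fixed threshold
#'
#' Sensitivity is the fraction of positives with score at or above the
#' threshold; specificity the fraction of negatives below it. Median and
#' percentile confidence interval are taken over stratified bootstrap
#' replicates, matching how per-threshold operating characteristics are
#' reported alongside an empirical ROC curve.
#'
#' @inheritParams auc_ci
#' @param threshold Decision threshold on the score scale.
#' @return A one-row data frame: `threshold`, point estimates `sensitivity`
#'   and `specificity`, bootstrap medians and CI bounds (`sens_median`,
#'   `sens_low`, `sens_high`, `spec_median`, `spec_low`, `spec_high`).
#' @export
sens_spec_at_threshold <- function(scores, labels, threshold,
                                   n_boot = 2000, seed = 1, conf = 0.95) {
  labels <- check_binary(labels)
  sens_fun <- function(s, l) mean(s[l == 1] >= threshold)
  spec_fun <- function(s, l) mean(s[l == 0] < threshold)
  set.seed(seed)
  reps <- vapply(seq_len(n_boot), function(i) {
    idx <- stratified_indices(labels)
    c(sens_fun(scores[idx], labels[idx]), spec_fun(scores[idx], labels[idx]))
  }, c(0, 0))
  a <- (1 - conf) / 2
  data.frame(
    threshold = threshold,
    sensitivity = sens_fun(scores, labels),
    specificity = spec_fun(scores, labels),
    sens_median = stats::median(reps[1, ]),
    sens_low = stats::quantile(reps[1, ], a, names = FALSE),
    sens_high = stats::quantile(reps[1, ], 1 - a, names = FALSE),
    spec_median = stats::median(reps[2, ]),
    spec_low = stats::quantile(reps[2, ], a, names = FALSE),
    spec_high = stats::quantile(reps[2, ], 1 - a, names = FALSE)
  )
}

#' Threshold sweep with the 80%-sensitivity-in-CI selection rule
#'
#' Evaluates [sens_spec_at_threshold()] over a grid of thresholds and marks as
#' selected those whose sensitivity confidence interval contains the target
#' sensitivity (inclusive at the bounds). The conventional grids are +15% to
#' +40% in 5% steps for detecting progression and -15% to -65% for detecting
#' response; thresholds below the assumed 10% measurement uncertainty are not
#' considered.
#'
#' @inheritParams auc_ci
#' @param grid Numeric vector of thresholds (signed percent).
#' @param target_sens Target sensitivity (default 0.80).
#' @return Data frame as in [sens_spec_at_threshold()] with an extra logical
#'   column `selected`.
#' @export
threshold_performance <- function(scores, labels, grid, target_sens = 0.80,
                                  n_boot = 2000, seed = 1, conf = 0.95) {
  stopifnot(length(grid) >= 1)
  rows <- lapply(seq_along(grid), function(i) {
    sens_spec_at_threshold(scores, labels, grid[i], n_boot = n_boot,
                           seed = seed + i - 1, conf = conf)
  })
  out <- do.call(rbind, rows)
  out$selected <- out$sens_low <= target_sens & target_sens <= out$sens_high
  out
}

#' Thresholds whose sensitivity CI contains the target sensitivity
#'
#' @inheritParams threshold_performance
#' @return The subset of `grid` selected by the rule.
#' @export
optimal_threshold_range <- function(scores, labels, grid, target_sens = 0.80,
                                    n_boot = 2000, seed = 1, conf = 0.95) {
  tab <- threshold_performance(scores, labels, grid, target_sens,
                               n_boot = n_boot, seed = seed, conf = conf)
  tab$threshold[tab$selected]
}
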