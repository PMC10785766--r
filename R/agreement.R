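# Inter-reader agreement and group comparison statistics.

#' Weighted kappa for ordinal inter-reader agreement
#'
#' Cohen's kappa with distance-based disagreement weights over an ordered
#' category set (by default the BT-RADS order 1a < 1b < 2 < 3a < 3b < 3c < 4):
#' `kappa_w = 1 - sum(w * O) / sum(w * E)` where `O` is the observed and `E`
#' the chance-expected cross-classification and `w[i, j]` is `|i - j| / (k-1)`
#' (linear, default) or its square (quadratic). The unweighted kappa and raw
#' observed agreement are returned alongside. An optional bootstrap CI
#' resamples rated cases with replacement.
#'
#' @param reads_a,reads_b Equal-length category vectors, one element per rated
#'   case.
#' @param scheme `"linear"` or `"quadratic"` disagreement weights.
#' @param categories Ordered category levels; defaults to the BT-RADS scale.
#' @param n_boot If positive, number of bootstrap replicates for a percentile
#'   CI on the weighted kappa.
#' @param seed Seed for the bootstrap.
#' @param conf Confidence level for the bootstrap CI.
#' @return A `kappa_result`: `kappa_weighted`, `kappa_unweighted`,
#'   `observed_agreement`, `weight_scheme`, `n`, and `ci` (or `NULL`).
#' @export
weighted_kappa <- function(reads_a, reads_b, scheme = c("linear", "quadratic"),
                           categories = btrads_levels(),
                           n_boot = 0, seed = 1, conf = 0.95) {
  scheme <- match.arg(scheme)
  reads_a <- as.character(reads_a); reads_b <- as.character(reads_b)
  if (length(reads_a) != length(reads_b)) {
    stop_volresp("read vectors must have equal length", class = "length_mismatch")
  }
  unknown <- setdiff(c(reads_a, reads_b), categories)
  if (length(unknown) > 0) {
    stop_volresp("unknown category: ", unknown[1], class = "unknown_category")
  }
  kw <- function(a, b) {
    fa <- factor(a, levels = categories); fb <- factor(b, levels = categories)
    O <- table(fa, fb) / length(a)
    E <- outer(rowSums(O), colSums(O))
    k <- length(categories)
    w <- abs(outer(seq_len(k), seq_len(k), "-")) / (k - 1)
    if (scheme == "quadratic") w <- w^2
    denom <- sum(w * E)
    if (denom == 0) return(1)  # degenerate: all mass on one category
    1 - sum(w * O) / denom
  }
  kw0 <- function(a, b) {
    fa <- factor(a, levels = categories); fb <- factor(b, levels = categories)
    O <- table(fa, fb) / length(a)
    pe <- sum(rowSums(O) * colSums(O))
    po <- sum(diag(O))
    if (pe == 1) return(1)
    (po - pe) / (1 - pe)
  }
  ci <- NULL
  if (n_boot > 0) {
    set.seed(seed)
    reps <- vapply(seq_len(n_boot), function(i) {
      idx <- sample.int(length(reads_a), replace = TRUE)
      kw(reads_a[idx], reads_b[idx])
    }, 0)
    a <- (1 - conf) / 2
    ci <- stats::quantile(reps, c(a, 1 - a), names = FALSE)
  }
  structure(
    list(kappa_weighted = kw(reads_a, reads_b),
         kappa_unweighted = kw0(reads_a, reads_b),
         observed_agreement = mean(reads_a == reads_b),
         weight_scheme = scheme, n = length(reads_a), ci = ci),
    class = "kappa_result"
  )
}

#' @export
print.kappa_result <- function(x, ...) {
  cat(sprintf(
    "Weighted kappa (%s weights): %.3f  (unweighted %.3f, observed agreement %.1f%%, n = %d)\n",
    x$weight_scheme, x$kappa_weighted, x$kappa_unweighted,
    100 * x$observed_agreement, x$n))
  if (!is.null(x$ci)) {
    cat(sprintf("  bootstrap CI: %.3f-%.3f\n", x$ci[1], x$ci[2]))
  }
  invisible(x)
}

#' Friedman rank test across repeated measurement methods
#'
#' Within-block (image) ranks of the method columns, chi-square statistic with
#' the standard tie correction, and chi-square p-value. Used to compare the
#' percent-change distributions of several measurement methods over the same
#' images. Fully tied data (identical columns) give statistic 0 and p = 1.
#'
#' @param block_matrix Numeric matrix, blocks (images) in rows, methods in
#'   columns.
#' @return List with `statistic`, `df`, `p_value`, `n_blocks`, `n_methods`.
#' @export
friedman_rank_test <- function(block_matrix) {
  block_matrix <- as.matrix(block_matrix)
  n <- nrow(block_matrix); k <- ncol(block_matrix)
  if (n < 2 || k < 2) {
    stop_volresp("need at least 2 blocks and 2 methods", class = "invalid_input")
  }
  ranks <- t(apply(block_matrix, 1, rank))
  Rj <- colSums(ranks)
  stat <- 12 / (n * k * (k + 1)) * sum(Rj^2) - 3 * n * (k + 1)
  # tie correction: per-block tied group sizes
  tie_sum <- sum(apply(block_matrix, 1, function(row) {
    t <- table(row); sum(t^3 - t)
  }))
  corr <- 1 - tie_sum / (n * (k^3 - k))
  if (corr <= 0) {
    stat <- 0
  } else {
    stat <- stat / corr
  }
  p <- stats::pchisq(stat, df = k - 1, lower.tail = FALSE)
  list(statistic = stat, df = k - 1, p_value = p, n_blocks = n, n_methods = k)
}

#' One-way ANOVA across groups
#'
#' Classic between/within F test (equal-variance one-way ANOVA), as used to
#' compare cystic-volume percent change across response groups. Thin wrapper
#' around [stats::oneway.test()] with `var.equal = TRUE`; the degenerate case
#' of zero within-group variance with a between-group difference is reported
#' as an infinite F with p = 0.
#'
#' @param values Numeric vector of observations.
#' @param groups Group membership, same length.
#' @return List with `statistic` (F), `df`, `p_value`.
#' @export
one_way_anova <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2 || any(table(groups) < 2)) {
    stop_volresp("need >= 2 groups with >= 2 values each", class = "invalid_input")
  }
  within_ss <- sum(tapply(values, groups, function(v) sum((v - mean(v))^2)))
  if (within_ss == 0) {
    between <- tapply(values, groups, mean)
    if (stats::var(as.numeric(between)) > 0) {
      return(list(statistic = Inf,
                  df = c(nlevels(groups) - 1, length(values) - nlevels(groups)),
                  p_value = 0))
    }
    return(list(statistic = 0,
                df = c(nlevels(groups) - 1, length(values) - nlevels(groups)),
                p_value = 1))
  }
  ft <- stats::oneway.test(values ~ groups, var.equal = TRUE)
  list(statistic = unname(ft$statistic),
       df = unname(c(ft$parameter[1], ft$parameter[2])),
       p_value = ft$p.value)
}

#' Wilcoxon rank-sum test
#'
#' Wrapper around [stats::wilcox.test()]: exact enumeration when both groups
#' have at most 10 observations and there are no ties, otherwise the
#' tie-corrected normal approximation (without continuity correction, so the
#' statistic is invariant under monotone transforms and symmetric fixtures
#' give p = 1).
#'
#' @param x,y Non-empty numeric vectors.
#' @return List with `statistic` (W, the Mann-Whitney U of `x` over `y`),
#'   `p_value`, `exact`.
#' @export
wilcoxon_rank_sum <- function(x, y) {
  stopifnot(length(x) >= 1, length(y) >= 1)
  if (length(unique(c(x, y))) == 1) {
    # fully tied data carry no evidence either way
    return(list(statistic = length(x) * length(y) / 2, p_value = 1,
                exact = FALSE))
  }
  ties <- anyDuplicated(c(x, y)) > 0
  use_exact <- length(x) <= 10 && length(y) <= 10 && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, exact = use_exact, correct = FALSE)
  )
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       exact = use_exact)
}
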