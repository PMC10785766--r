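#' Extrapolate a 2D-product change threshold to a volumetric threshold
#'
#' Under the assumption of a uniformly scaling spherical tumor, a relative
#' change `a` in the product of two perpendicular diameters corresponds to a
#' relative volume change of `(1 + a)^(3/2) - 1`: the diameter scales as
#' `sqrt(1 + a)` and the volume as its cube. This is the map that turns the
#' classic 2D cutoffs (+25% progression, -50% partial response, -25% minor
#' response) into the volumetric cutoffs quoted as +40%, -65% and -35% after
#' rounding to the nearest 5 percentage points.
#'
#' @param threshold_2d Signed fractional change on the 2D-product scale
#'   (e.g. `+0.25` for a 25% increase). Must be greater than -1.
#' @return Signed fractional change on the volume scale.
#' @seealso [sphere_collapse()] for the inverse map.
#' @examples
#' sphere_extrapolate(0.25)   # ~ +0.3975, reported as +40%
#' sphere_extrapolate(-0.50)  # ~ -0.6464, reported as -65%
#' @export
sphere_extrapolate <- function(threshold_2d) {
  if (any(threshold_2d <= -1)) {
    stop_volresp("2D change threshold must be > -1", class = "domain_error")
  }
  (1 + threshold_2d)^(3 / 2) - 1
}

#' Inverse of the sphere extrapolation
#'
#' Maps a fractional volume change back to the 2D-product scale:
#' `(1 + v)^(2/3) - 1`.
#'
#' @param threshold_vol Signed fractional volume change, greater than -1.
#' @return Signed fractional change on the 2D-product scale.
#' @export
sphere_collapse <- function(threshold_vol) {
  if (any(threshold_vol <= -1)) {
    stop_volresp("volume change threshold must be > -1", class = "domain_error")
  }
  (1 + threshold_vol)^(2 / 3) - 1
}

criteria_names <- function() {
  c("RANO_2D", "RAPNO_2D", "VOL_RANO", "VOL_RAPNO", "VOLX_RANO", "VOLX_RAPNO")
}

#' Build a response-criteria rule set
#'
#' Returns one of the six threshold rule sets used for tumor response
#' classification from percent change in a measured quantity:
#'
#' * `RANO_2D` / `RAPNO_2D`: 2D diameter-product change; PD at >= +25% or a new
#'   lesion, PR at <= -50%; RAPNO adds a minor-response (MinR) band for
#'   decreases of 25-50%.
#' * `VOL_RANO` / `VOL_RAPNO`: the same cutoffs applied to solid tumor volume.
#' * `VOLX_RANO` / `VOLX_RAPNO`: volume cutoffs obtained by sphere
#'   extrapolation of the 2D cutoffs - PD at >= +40%, PR at <= -65%, MinR band
#'   35-65% decrease (RAPNO variant).
#'
#' By default the extrapolated rule sets use the rounded thresholds
#' (40/65/35%), as applied in trial practice; `exact_extrapolation = TRUE`
#' uses the unrounded values `(1.25)^1.5 - 1` etc.
#'
#' @param name One of `"RANO_2D"`, `"RAPNO_2D"`, `"VOL_RANO"`, `"VOL_RAPNO"`,
#'   `"VOLX_RANO"`, `"VOLX_RAPNO"`.
#' @param exact_extrapolation Use exact sphere-extrapolated thresholds instead
#'   of the rounded 40/65/35%.
#' @return A `criteria_spec`: list with `name`, `measure` (default measured
#'   quantity), `pd_threshold`, `pr_threshold` (signed percent), and
#'   `minr_bounds` (or `NULL`).
#' @export
response_criteria <- function(name = criteria_names(),
                              exact_extrapolation = FALSE) {
  name <- match.arg(name)
  pd <- 25; pr <- -50; minr_upper <- -25
  if (name %in% c("VOLX_RANO", "VOLX_RAPNO")) {
    if (exact_extrapolation) {
      pd <- 100 * sphere_extrapolate(0.25)
      pr <- 100 * sphere_extrapolate(-0.50)
      minr_upper <- 100 * sphere_extrapolate(-0.25)
    } else {
      pd <- round_pct_to_5(sphere_extrapolate(0.25))
      pr <- round_pct_to_5(sphere_extrapolate(-0.50))
      minr_upper <- round_pct_to_5(sphere_extrapolate(-0.25))
    }
  }
  has_minr <- name %in% c("RAPNO_2D", "VOL_RAPNO", "VOLX_RAPNO")
  structure(
    list(
      name = name,
      measure = if (name %in% c("RANO_2D", "RAPNO_2D")) "area2d" else "solid_volume",
      pd_threshold = pd,
      pr_threshold = pr,
      minr_bounds = if (has_minr) c(pr, minr_upper) else NULL
    ),
    class = "criteria_spec"
  )
}

#' @export
print.criteria_spec <- function(x, ...) {
  cat(x$name, " (measure: ", x$measure, ")\n", sep = "")
  cat(sprintf("  PD: >= %+.4g%% or new lesion\n  PR: <= %+.4g%%\n",
              x$pd_threshold, x$pr_threshold))
  if (!is.null(x$minr_bounds)) {
    cat(sprintf("  MinR: decrease in (%g%%, %g%%]\n",
                -x$minr_bounds[2], -x$minr_bounds[1]))
  }
  invisible(x)
}

#' Classify a percent change under a criteria rule set
#'
#' A new lesion means progressive disease regardless of measured change.
#' Otherwise thresholds are inclusive towards the non-stable label: PD at
#' `pct >= pd_threshold`, PR at `pct <= pr_threshold`, MinR (when the rule set
#' has a minor-response band) for `pr_threshold < pct <= minr upper bound`,
#' and SD otherwise.
#'
#' @param pct Signed percent change(s) from baseline.
#' @param spec A `criteria_spec` from [response_criteria()].
#' @param new_lesion Logical, recycled against `pct`.
#' @return Ordered factor with levels `PR < MinR < SD < PD` (`NA` for `NA`
#'   input).
#' @export
classify_change <- function(pct, spec, new_lesion = FALSE) {
  stopifnot(inherits(spec, "criteria_spec"))
  n <- max(length(pct), length(new_lesion))
  pct <- rep_len(pct, n)
  new_lesion <- rep_len(as.logical(new_lesion), n)
  out <- rep(NA_character_, n)
  known <- !is.na(pct) | new_lesion
  out[new_lesion] <- "PD"
  rest <- known & !new_lesion
  out[rest & pct >= spec$pd_threshold] <- "PD"
  out[rest & pct <= spec$pr_threshold] <- "PR"
  todo <- rest & is.na(out)
  if (!is.null(spec$minr_bounds)) {
    out[todo & pct <= spec$minr_bounds[2]] <- "MinR"
    todo <- rest & is.na(out)
  }
  out[todo] <- "SD"
  response_factor(out)
}

btrads_levels <- function() c("1a", "1b", "2", "3a", "3b", "3c", "4")

#' Map a BT-RADS score to a response category
#'
#' BT-RADS is an ordinal visual-assessment score assigned by neuroradiologists
#' (1a < 1b < 2 < 3a < 3b < 3c < 4; 0 = unscorable). For comparison with
#' measurement-based criteria: `1a` maps to PR (improvement attributed to
#' decreasing tumor burden), `3c` and `4` map to PD (worsening attributed to
#' increasing tumor burden), and `1b`, `2`, `3a`, `3b` map to SD. No minor
#' response is produced; where criteria distinguish MinR it is grouped with PR
#' for comparison against BT-RADS.
#'
#' @param score Character vector of BT-RADS scores.
#' @return Ordered factor with levels `PR < MinR < SD < PD`.
#' @export
btrads_category <- function(score) {
  score <- as.character(score)
  if (any(score == "0", na.rm = TRUE)) {
    stop_volresp("BT-RADS 0 is unscorable", class = "unscorable")
  }
  bad <- !is.na(score) & !score %in% btrads_levels()
  if (any(bad)) {
    stop_volresp("unknown BT-RADS score: ", score[bad][1],
                 class = "unknown_category")
  }
  out <- rep(NA_character_, length(score))
  out[score == "1a"] <- "PR"
  out[score %in% c("1b", "2", "3a", "3b")] <- "SD"
  out[score %in% c("3c", "4")] <- "PD"
  response_factor(out)
}

#' Classify every follow-up image of a series
#'
#' Composes [series_percent_changes()] and [classify_change()]: one label per
#' post-baseline image; images at which the measure is missing get an `NA`
#' label unless a new lesion forces PD.
#'
#' @param series A [participant_series].
#' @param spec A `criteria_spec`.
#' @param measure Measured quantity; defaults to the rule set's own measure.
#' @return Data frame with `t_days`, `pct`, `new_lesion`, `label`.
#' @export
classify_series <- function(series, spec, measure = spec$measure) {
  ch <- series_percent_changes(series, measure)
  ch$label <- classify_change(ch$pct, spec, ch$new_lesion)
  ch[, c("t_days", "pct", "new_lesion", "label")]
}

#' Cross-tabulate two response label streams
#'
#' Full contingency table of a test classifier against a reference, plus
#' per-category sensitivity (fraction of reference category c also labelled c
#' by the test) and specificity (fraction of reference non-c labelled non-c).
#'
#' @param test,reference Equal-length response label vectors (aligned images).
#' @return A `congruence_table`: list with `table`, `sensitivity`,
#'   `specificity`, `agreement` (overall fraction concordant), `n`.
#' @export
congruence_table <- function(test, reference) {
  test <- response_factor(test)
  reference <- response_factor(reference)
  if (length(test) != length(reference)) {
    stop_volresp("label streams must have equal length", class = "length_mismatch")
  }
  keep <- !is.na(test) & !is.na(reference)
  test <- test[keep]; reference <- reference[keep]
  tab <- table(test = test, reference = reference)
  lev <- response_levels()
  sens <- spec <- setNames(rep(NA_real_, length(lev)), lev)
  for (c in lev) {
    n_ref <- sum(reference == c)
    if (n_ref > 0) sens[c] <- sum(test == c & reference == c) / n_ref
    n_not <- sum(reference != c)
    if (n_not > 0) spec[c] <- sum(test != c & reference != c) / n_not
  }
  structure(
    list(table = tab, sensitivity = sens, specificity = spec,
         agreement = mean(test == reference), n = length(test)),
    class = "congruence_table"
  )
}

#' @export
print.congruence_table <- function(x, ...) {
  cat("Congruence of test vs reference labels (n = ", x$n, ", agreement = ",
      sprintf("%.1f%%", 100 * x$agreement), ")\n", sep = "")
  print(x$table)
  cat("Per-category sensitivity of test against reference:\n")
  print(round(x$sensitivity, 3))
  invisible(x)
}
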