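#' Bidimensional tumor area
#'
#' Product of the two perpendicular diameters of a solid lesion, the quantity
#' underlying 2D (RANO/RAPNO-style) response assessment.
#'
#' @param d1 Longest diameter in cm.
#' @param d2 Perpendicular diameter in cm. Must not exceed `d1` element-wise.
#' @return Area in cm^2 (`d1 * d2`). `NA` values propagate.
#' @examples
#' bidimensional_area(3, 2)
#' @export
bidimensional_area <- function(d1, d2) {
  bad <- (d1 <= 0 | d2 <= 0) & !is.na(d1) & !is.na(d2)
  if (any(bad)) {
    stop_volresp("diameters must be positive", class = "invalid_measurement")
  }
  if (any(d1 < d2, na.rm = TRUE)) {
    stop_volresp("d1 must be the longest diameter (d1 >= d2)",
                 class = "invalid_measurement")
  }
  d1 * d2
}

#' Solid tumor volume
#'
#' Solid volume is the segmentation-based tumor volume on the sequence that
#' best visualises the solid component, minus any cyst volume contained inside
#' the solid region. A zero result (fully cystic residual) is allowed but
#' flagged with a warning because percent change from it is undefined.
#'
#' @param base_volume Segmentation-base volume in cm^3.
#' @param intratumoral_cyst_volume Cyst volume inside the solid region, cm^3.
#' @return Solid volume in cm^3.
#' @export
solid_volume <- function(base_volume, intratumoral_cyst_volume = 0) {
  if (any(intratumoral_cyst_volume < 0, na.rm = TRUE) ||
      any(base_volume < 0, na.rm = TRUE)) {
    stop_volresp("volumes must be non-negative", class = "invalid_measurement")
  }
  if (any(base_volume < intratumoral_cyst_volume, na.rm = TRUE)) {
    stop_volresp("intratumoral cyst volume exceeds base volume",
                 class = "inconsistent_segmentation")
  }
  out <- base_volume - intratumoral_cyst_volume
  if (any(out == 0, na.rm = TRUE)) {
    warning("zero solid volume (degenerate: fully cystic lesion)",
            call. = FALSE)
  }
  out
}

#' Sum measurements over lesions
#'
#' In studies with multiple solid lesions, the per-lesion 2D areas or 3D
#' volumes are summed per image before comparison to baseline.
#'
#' @param values Non-empty numeric vector of non-negative per-lesion values
#'   (all cm^2 or all cm^3).
#' @return Their arithmetic sum.
#' @export
aggregate_lesions <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) == 0) {
    stop_volresp("no measurable lesion", class = "no_measurable_lesion")
  }
  if (any(values < 0)) {
    stop_volresp("lesion values must be non-negative",
                 class = "invalid_measurement")
  }
  sum(values)
}

#' Percent change from baseline
#'
#' @param current Current value (area or volume), `>= 0`.
#' @param baseline Baseline value, strictly positive.
#' @return Signed percent change, `100 * (current - baseline) / baseline`.
#' @export
percent_change <- function(current, baseline) {
  if (any(baseline <= 0, na.rm = TRUE)) {
    stop_volresp("baseline must be positive", class = "undefined_baseline")
  }
  if (any(current < 0, na.rm = TRUE)) {
    stop_volresp("current value must be non-negative",
                 class = "invalid_measurement")
  }
  100 * (current - baseline) / baseline
}

#' Resolve the baseline image of a longitudinal series
#'
#' The baseline is the earliest pretreatment image (`t_days <= 0`); when two
#' pretreatment images exist the earlier one is used. If no pretreatment image
#' is available the earliest image is used with a warning (some trial
#' participants only had baselines acquired shortly after treatment start).
#'
#' @param x A [participant_series] or a numeric vector of `t_days`.
#' @return Integer index of the baseline timepoint.
#' @export
resolve_baseline <- function(x) UseMethod("resolve_baseline")

#' @export
resolve_baseline.participant_series <- function(x) {
  resolve_baseline(x$images$t_days)
}

#' @export
resolve_baseline.numeric <- function(x) {
  if (length(x) == 0) {
    stop_volresp("empty series", class = "empty_series")
  }
  pre <- which(x <= 0)
  if (length(pre) > 0) {
    pre[which.min(x[pre])]
  } else {
    warning("no pretreatment image; using earliest post-treatment image as baseline",
            call. = FALSE)
    which.min(x)
  }
}

#' Percent change from baseline for every follow-up image
#'
#' Applies [percent_change()] to each post-baseline image of a series for the
#' requested measure. Follow-ups at which the measure is missing yield `NA`
#' rather than being dropped, so the output stays aligned with the series.
#'
#' @param series A [participant_series].
#' @param measure One of `"area2d"`, `"solid_volume"`, `"whole_volume"`,
#'   `"cyst_volume"`.
#' @return A data frame with one row per follow-up image: `t_days`, `value`,
#'   `pct` (signed percent change from baseline), `new_lesion`.
#' @export
series_percent_changes <- function(series,
                                   measure = c("area2d", "solid_volume",
                                               "whole_volume", "cyst_volume")) {
  measure <- match.arg(measure)
  stopifnot(inherits(series, "participant_series"))
  img <- series$images
  b <- series$baseline_index
  base_val <- img[[measure]][b]
  if (is.na(base_val)) {
    stop_volresp("measure '", measure, "' missing at baseline",
                 class = "missing_baseline_measure")
  }
  fu <- img[-b, , drop = FALSE]
  fu <- fu[fu$t_days > img$t_days[b], , drop = FALSE]
  data.frame(
    t_days = fu$t_days,
    value = fu[[measure]],
    pct = ifelse(is.na(fu[[measure]]), NA_real_,
                 100 * (fu[[measure]] - base_val) / base_val),
    new_lesion = fu$new_lesion,
    row.names = NULL
  )
}
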