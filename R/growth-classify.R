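# Trajectory-based response classification and responder/resistant
# comparison built on growth_fit objects.

#' Classify an image from its fitted volume trajectory
#'
#' Rule, with precedence PD then SD then PR:
#' * **PD** if the evaluated time lies beyond the 75th percentile of the
#'   posterior `t_Vmin` distribution - the tumor has clearly passed its
#'   minimum and is regrowing, regardless of whether the volume at `t_eval`
#'   exceeds baseline yet.
#' * **SD** if every observed volume up to and including `t_eval` stays within
#'   the measurement-uncertainty band around the pretreatment volume
#'   (absolute percent change `<= 100 * noise_cv`).
#' * **PR** otherwise.
#'
#' @param fit A `growth_fit` (ideally pooled over measurement bootstraps).
#' @param series The [participant_series] the fit came from.
#' @param t_eval Evaluated image time in days (an observed image time).
#' @param measure Volume measure used (default solid volume).
#' @return A `model_classification`: list with `label` (`"PR"/"SD"/"PD"`),
#'   `t_eval`, `t_vmin_q75`, `band_pct`.
#' @export
classify_trajectory <- function(fit, series, t_eval,
                                measure = "solid_volume") {
  stopifnot(inherits(fit, "growth_fit"),
            inherits(series, "participant_series"))
  img <- series$images
  b <- series$baseline_index
  v0 <- img[[measure]][b]
  if (is.na(v0) || v0 <= 0) {
    stop_volresp("baseline volume missing", class = "missing_baseline_measure")
  }
  q75 <- stats::quantile(fit$t_vmin, 0.75, names = FALSE)  # linear interp.
  band <- 100 * fit$noise_cv
  if (t_eval > q75) {
    label <- "PD"
  } else {
    upto <- img$t_days > img$t_days[b] & img$t_days <= t_eval &
      !is.na(img[[measure]])
    pct <- 100 * (img[[measure]][upto] - v0) / v0
    label <- if (all(abs(pct) <= band)) "SD" else "PR"
  }
  structure(
    list(label = label, t_eval = t_eval, t_vmin_q75 = q75, band_pct = band),
    class = "model_classification"
  )
}

#' @export
print.model_classification <- function(x, ...) {
  cat(sprintf(
    "Model classification: %s (t_eval = %g d, t_Vmin 75th pct = %.1f d, band +/-%g%%)\n",
    x$label, x$t_eval, x$t_vmin_q75, x$band_pct))
  invisible(x)
}

#' Compare fitted parameters between responding and resistant tumors
#'
#' Splits fits into responders (posterior-median `t_Vmin >= cutoff`, one year
#' by default) and resistant tumors (`t_Vmin < cutoff`) and compares the
#' posterior medians of each model parameter between groups with a Wilcoxon
#' rank-sum test. A lower resistance-onset rate `eps` among responders is the
#' signature of durable treatment effect.
#'
#' @param fits List of `growth_fit` objects.
#' @param cutoff Responder cutoff on `t_Vmin` in days (default 365).
#' @return A `responder_comparison`: data frame of per-parameter group medians
#'   and p-values, plus group sizes. Tests are skipped (`NA`) when either
#'   group has fewer than 2 fits.
#' @export
compare_responders <- function(fits, cutoff = 365) {
  stopifnot(length(fits) >= 1)
  med <- t(vapply(fits, function(f) {
    c(coef(f), t_vmin = stats::median(f$t_vmin))
  }, numeric(5)))
  responder <- med[, "t_vmin"] >= cutoff
  params <- c("lambda", "gamma0", "eps")
  rows <- lapply(params, function(p) {
    x <- med[responder, p]; y <- med[!responder, p]
    pv <- if (length(x) >= 2 && length(y) >= 2) {
      wilcoxon_rank_sum(x, y)$p_value
    } else NA_real_
    data.frame(parameter = p,
               median_responding = stats::median(x),
               median_resistant = stats::median(y),
               p_value = pv)
  })
  structure(
    list(table = do.call(rbind, rows),
         n_responding = sum(responder), n_resistant = sum(!responder),
         cutoff = cutoff, responder = responder),
    class = "responder_comparison"
  )
}

#' @export
print.responder_comparison <- function(x, ...) {
  cat(sprintf(
    "Responding (t_Vmin >= %g d): n = %d; resistant: n = %d\n",
    x$cutoff, x$n_responding, x$n_resistant))
  print(x$table, row.names = FALSE)
  if (x$n_responding < 2 || x$n_resistant < 2) {
    cat("Tests skipped: a group has fewer than 2 fits.\n")
  }
  invisible(x)
}

#' Cohort fit with a shared growth rate
#'
#' The growth rate `lambda` is treated as constant across patients. The shared
#' value is profiled in two stages: every series is first fitted with free
#' `lambda`, the cohort value is taken as the median of the per-series
#' posterior medians, and each series is then refitted with `lambda` fixed at
#' that value (per-series `gamma0`, `eps`, `V_b`). `lambda_mode = "free"`
#' skips the second stage and returns the independent fits.
#'
#' @param series_list List of [participant_series].
#' @param measure Volume measure to fit.
#' @param lambda_mode `"shared"` (default) or `"free"`.
#' @param min_points Minimum number of usable observations for a series to be
#'   fitted (default 4: baseline plus three follow-ups).
#' @param seed Integer root seed.
#' @param ... Chain settings and priors passed to [fit_growth()].
#' @return List with `fits` (named by participant; `NULL` for skipped
#'   series), `lambda_shared` (or `NA` in free mode), and `skipped` (ids with
#'   too few images).
#' @export
fit_growth_cohort <- function(series_list, measure = "solid_volume",
                              lambda_mode = c("shared", "free"),
                              min_points = 4, seed = 1, ...) {
  lambda_mode <- match.arg(lambda_mode)
  usable <- vapply(series_list, function(s) {
    sum(!is.na(s$images[[measure]]))
  }, 0L)
  skipped <- names(series_list)[usable < min_points]
  todo <- series_list[usable >= min_points]
  set.seed(seed)
  seeds1 <- sample.int(.Machine$integer.max, length(todo))
  fits <- lapply(seq_along(todo), function(i) {
    fit_growth(todo[[i]], measure = measure, seed = seeds1[i], ...)
  })
  names(fits) <- names(todo)
  lambda_shared <- NA_real_
  if (lambda_mode == "shared" && length(fits) > 0) {
    lambda_shared <- stats::median(vapply(fits, function(f) coef(f)["lambda"], 0))
    seeds2 <- sample.int(.Machine$integer.max, length(todo))
    fits <- lapply(seq_along(todo), function(i) {
      fit_growth(todo[[i]], measure = measure, seed = seeds2[i],
                 priors = growth_priors(lambda_fixed = lambda_shared), ...)
    })
    names(fits) <- names(todo)
  }
  list(fits = fits, lambda_shared = lambda_shared, skipped = skipped)
}
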