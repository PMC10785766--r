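# End-to-end analysis pipeline: per-image response classification,
# concordance of measurement-based classification with BT-RADS visual
# assessment (ROC/AUC, DeLong, threshold sweep, weighted kappa, group
# comparisons), and trajectory-model classification.

#' Pipeline configuration
#'
#' All analysis settings in one validated list. Every random element of the
#' pipeline is seeded from the single root `seed`.
#'
#' @param criteria Criteria rule sets to apply per image.
#' @param measures Measures scored against BT-RADS in the ROC stage.
#' @param n_boot Bootstrap replicates for AUC and threshold CIs.
#' @param pd_grid,pr_grid Threshold grids (signed percent) for the
#'   sensitivity sweep when detecting PD and PR.
#' @param target_sens Target sensitivity for the threshold selection rule.
#' @param growth Run the trajectory-model stage.
#' @param growth_n_boot Measurement-noise bootstrap refits per image fit
#'   (0 = fit uncertainty only).
#' @param growth_walkers,growth_steps Ensemble MCMC settings per fit.
#' @param lambda_mode `"shared"` (cohort-constant growth rate) or `"free"`.
#' @param noise_cv Assumed measurement uncertainty (CV).
#' @param min_prior_images Minimum number of images strictly before an
#'   evaluated image for that image to be model-classified.
#' @param seed Integer root seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(criteria = c("RAPNO_2D", "VOLX_RAPNO"),
                            measures = c("area2d", "solid_volume", "whole_volume"),
                            n_boot = 2000,
                            pd_grid = seq(15, 40, by = 5),
                            pr_grid = seq(-15, -65, by = -5),
                            target_sens = 0.80,
                            growth = TRUE,
                            growth_n_boot = 0,
                            growth_walkers = 16,
                            growth_steps = 600,
                            lambda_mode = c("shared", "free"),
                            noise_cv = 0.10,
                            min_prior_images = 3,
                            seed = 1) {
  stopifnot(all(criteria %in% criteria_names()), n_boot >= 1,
            length(pd_grid) >= 1, length(pr_grid) >= 1)
  lambda_mode <- match.arg(lambda_mode)
  structure(as.list(environment()), class = "pipeline_config")
}

# Assessment-image table: one row per image carrying BT-RADS reads, with the
# percent change of every measure and the consensus response category
# (reader 1 is the consensus stream).
assessment_table <- function(series_list, measures) {
  rows <- lapply(series_list, function(s) {
    img <- s$images
    has_read <- !is.na(img$btrads_reader1)
    has_read[s$baseline_index] <- FALSE
    if (!any(has_read)) return(NULL)
    out <- data.frame(participant_id = s$participant_id,
                      t_days = img$t_days[has_read],
                      btrads_reader1 = img$btrads_reader1[has_read],
                      btrads_reader2 = img$btrads_reader2[has_read],
                      new_lesion = img$new_lesion[has_read],
                      stringsAsFactors = FALSE)
    for (m in measures) {
      ch <- tryCatch(series_percent_changes(s, m), error = function(e) NULL)
      out[[paste0("pct_", m)]] <- if (is.null(ch)) NA_real_ else {
        ch$pct[match(out$t_days, ch$t_days)]
      }
    }
    out
  })
  tab <- do.call(rbind, Filter(Negate(is.null), rows))
  tab$category <- btrads_category(tab$btrads_reader1)
  rownames(tab) <- NULL
  tab
}

#' Run the full analysis pipeline
#'
#' Executes, in order: (1) per-image classification of every series under
#' each requested criteria rule set; (2) concordance of percent-change scores
#' with the BT-RADS-derived response categories on the assessment images -
#' inter-reader weighted kappa, per-measure ROC curves and stratified
#' bootstrap AUC CIs for detecting PD and PR, pairwise paired DeLong tests,
#' the solid-volume threshold sensitivity sweep with the 80%-in-CI selection
#' rule, per-group Friedman comparisons of the measures, and a one-way ANOVA
#' of cyst-volume change across groups; (3) growth-model fitting and
#' trajectory classification of every eligible assessment image, with the
#' model-vs-BT-RADS contingency table. Deterministic for a fixed root seed.
#'
#' @param series_list Named list of [participant_series] (e.g. from
#'   [read_measurements()] or [simulate_cohort()]).
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory; when given, writes `report.json`,
#'   `classifications.csv` and `threshold_table.csv` there.
#' @return A `pipeline_report` list with elements `classifications`,
#'   `assessment`, `kappa`, `roc` (per positive class and measure), `delong`,
#'   `thresholds`, `friedman`, `cyst_anova`, `growth` (or `NULL`), and
#'   `meta`.
#' @export
run_pipeline <- function(series_list, config = pipeline_config(),
                         out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  set.seed(config$seed)
  stage_seeds <- sample.int(.Machine$integer.max, 8)

  # -- stage 1: rule-based classification ---------------------------------
  cls <- do.call(rbind, lapply(names(series_list), function(id) {
    s <- series_list[[id]]
    do.call(rbind, lapply(config$criteria, function(cn) {
      spec <- response_criteria(cn)
      res <- tryCatch(classify_series(s, spec), error = function(e) NULL)
      if (is.null(res)) return(NULL)
      cbind(participant_id = id, criteria = cn, res)
    }))
  }))
  rownames(cls) <- NULL

  # -- stage 2: concordance with BT-RADS ----------------------------------
  assess <- assessment_table(series_list, config$measures)
  both <- !is.na(assess$btrads_reader1) & !is.na(assess$btrads_reader2)
  kappa <- weighted_kappa(assess$btrads_reader1[both],
                          assess$btrads_reader2[both])

  roc <- list(); delong <- list()
  for (positive in c("PD", "PR")) {
    labels <- as.character(assess$category) == positive
    sgn <- if (positive == "PD") 1 else -1
    roc[[positive]] <- list()
    for (i in seq_along(config$measures)) {
      m <- config$measures[i]
      sc <- sgn * assess[[paste0("pct_", m)]]
      keep <- !is.na(sc)
      roc[[positive]][[m]] <- auc_ci(sc[keep], labels[keep],
                                     n_boot = config$n_boot,
                                     seed = stage_seeds[1] %% 100000 + i)
    }
    prs <- utils::combn(config$measures, 2, simplify = FALSE)
    delong[[positive]] <- do.call(rbind, lapply(prs, function(pr) {
      sa <- sgn * assess[[paste0("pct_", pr[1])]]
      sb <- sgn * assess[[paste0("pct_", pr[2])]]
      keep <- !is.na(sa) & !is.na(sb)
      dt <- delong_test(sa[keep], sb[keep], labels[keep])
      data.frame(measure_a = pr[1], measure_b = pr[2], auc_a = dt$auc_a,
                 auc_b = dt$auc_b, diff = dt$diff, p_value = dt$p_value)
    }))
  }

  solid <- assess$pct_solid_volume
  keep <- !is.na(solid)
  thr_pd <- threshold_performance(solid[keep],
                                  as.character(assess$category[keep]) == "PD",
                                  config$pd_grid, config$target_sens,
                                  n_boot = config$n_boot,
                                  seed = stage_seeds[2] %% 100000)
  thr_pr <- threshold_performance(-solid[keep],
                                  as.character(assess$category[keep]) == "PR",
                                  -config$pr_grid, config$target_sens,
                                  n_boot = config$n_boot,
                                  seed = stage_seeds[3] %% 100000)
  thr_pr$threshold <- -thr_pr$threshold
  thresholds <- list(PD = thr_pd, PR = thr_pr)

  friedman <- lapply(c("PR", "SD", "PD"), function(g) {
    sub <- assess[as.character(assess$category) == g,
                  paste0("pct_", config$measures), drop = FALSE]
    sub <- sub[stats::complete.cases(sub), , drop = FALSE]
    if (nrow(sub) < 2) return(NULL)
    friedman_rank_test(as.matrix(sub))
  })
  names(friedman) <- c("PR", "SD", "PD")

  cyst_anova <- NULL
  cyst_pct <- vapply(seq_len(nrow(assess)), function(i) {
    s <- series_list[[assess$participant_id[i]]]
    ch <- tryCatch(series_percent_changes(s, "cyst_volume"),
                   error = function(e) NULL)
    if (is.null(ch)) NA_real_ else ch$pct[match(assess$t_days[i], ch$t_days)]
  }, 0)
  ok <- !is.na(cyst_pct)
  if (length(unique(assess$category[ok])) >= 2 &&
      all(table(assess$category[ok]) %in% c(0, 2:10000))) {
    cyst_anova <- tryCatch(
      one_way_anova(cyst_pct[ok], as.character(assess$category[ok])),
      error = function(e) NULL)
  }

  # -- stage 3: trajectory model ------------------------------------------
  growth <- NULL
  if (isTRUE(config$growth)) {
    lambda_fixed <- NULL
    if (config$lambda_mode == "shared") {
      cohort <- fit_growth_cohort(series_list, lambda_mode = "shared",
                                  min_points = config$min_prior_images + 1,
                                  seed = stage_seeds[4] %% 100000,
                                  n_walkers = config$growth_walkers,
                                  n_steps = config$growth_steps,
                                  noise_cv = config$noise_cv)
      lambda_fixed <- cohort$lambda_shared
    }
    set.seed(stage_seeds[5])
    fit_seeds <- sample.int(.Machine$integer.max, nrow(assess))
    labels_model <- rep(NA_character_, nrow(assess))
    skipped <- character(0)
    fits <- vector("list", nrow(assess))
    for (i in seq_len(nrow(assess))) {
      s <- series_list[[assess$participant_id[i]]]
      img <- s$images
      te <- assess$t_days[i]
      n_prior <- sum(img$t_days < te & !is.na(img$solid_volume))
      if (n_prior < config$min_prior_images ||
          is.na(img$solid_volume[s$baseline_index])) {
        skipped <- c(skipped,
                     sprintf("%s@t=%g", assess$participant_id[i], te))
        next
      }
      keep_t <- img$t_days <= te & !is.na(img$solid_volume)
      pri <- if (is.null(lambda_fixed)) growth_priors() else
        growth_priors(lambda_fixed = lambda_fixed)
      fit <- if (config$growth_n_boot > 0) {
        bootstrap_refits(img$t_days[keep_t], img$solid_volume[keep_t],
                         n_boot = config$growth_n_boot,
                         noise_cv = config$noise_cv, seed = fit_seeds[i],
                         priors = pri, n_walkers = config$growth_walkers,
                         n_steps = config$growth_steps)
      } else {
        fit_growth(img$t_days[keep_t], img$solid_volume[keep_t],
                   noise_cv = config$noise_cv, priors = pri,
                   n_walkers = config$growth_walkers,
                   n_steps = config$growth_steps, seed = fit_seeds[i])
      }
      fits[[i]] <- fit
      labels_model[i] <- classify_trajectory(fit, s, te)$label
    }
    done <- !is.na(labels_model)
    contingency <- if (any(done)) {
      congruence_table(labels_model[done], assess$category[done])
    } else NULL
    growth <- list(labels = data.frame(
      participant_id = assess$participant_id, t_days = assess$t_days,
      btrads = as.character(assess$category), model = labels_model),
      contingency = contingency, skipped = skipped,
      lambda_shared = if (config$lambda_mode == "shared") lambda_fixed else NA,
      fits = fits)
  }

  report <- structure(
    list(classifications = cls, assessment = assess, kappa = kappa,
         roc = roc, delong = delong, thresholds = thresholds,
         friedman = friedman, cyst_anova = cyst_anova, growth = growth,
         meta = list(seed = config$seed, config = unclass(config),
                     package_version = as.character(utils::packageVersion("volresp")),
                     timestamp = format(Sys.time(), tz = "UTC"))),
    class = "pipeline_report"
  )
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("Pipeline report (seed ", x$meta$seed, ")\n", sep = "")
  cat(" - ", nrow(x$assessment), " assessment images; inter-reader kappa_w = ",
      sprintf("%.3f", x$kappa$kappa_weighted), "\n", sep = "")
  for (pos in names(x$roc)) {
    aucs <- vapply(x$roc[[pos]], function(r) r$auc, 0)
    cat(" - AUC (", pos, "): ",
        paste(sprintf("%s %.3f", names(aucs), aucs), collapse = ", "),
        "\n", sep = "")
  }
  sel <- x$thresholds$PD$threshold[x$thresholds$PD$selected]
  cat(" - selected PD thresholds (solid volume): ",
      if (length(sel)) paste0(sel, "%", collapse = ", ") else "none", "\n",
      sep = "")
  if (!is.null(x$growth)) {
    n_done <- sum(!is.na(x$growth$labels$model))
    cat(" - growth model: ", n_done, " images classified, ",
        length(x$growth$skipped), " skipped (<3 prior images)\n", sep = "")
  }
  invisible(x)
}

# Serialize a pipeline report. The timestamp lives in one metadata field so
# that byte-level determinism of the rest is testable.
write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$classifications,
                   file.path(out_dir, "classifications.csv"),
                   row.names = FALSE)
  utils::write.csv(rbind(cbind(positive = "PD", report$thresholds$PD),
                         cbind(positive = "PR", report$thresholds$PR)),
                   file.path(out_dir, "threshold_table.csv"),
                   row.names = FALSE)
  json <- list(
    meta = report$meta,
    kappa = report$kappa[c("kappa_weighted", "kappa_unweighted",
                           "observed_agreement", "n")],
    auc = lapply(report$roc, function(side) {
      lapply(side, function(r) r[c("auc", "ci_low", "ci_high", "n_boot")])
    }),
    delong = report$delong,
    thresholds = report$thresholds,
    friedman = report$friedman,
    cyst_anova = report$cyst_anova,
    growth = if (!is.null(report$growth)) {
      list(labels = report$growth$labels, skipped = report$growth$skipped,
           lambda_shared = report$growth$lambda_shared)
    }
  )
  jsonlite::write_json(json, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(out_dir)
}
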