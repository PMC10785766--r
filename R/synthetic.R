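# Seeded synthetic cohort generator. Emulates the statistical structure of a
# longitudinal pLGG volumetrics trial: growth-model trajectories observed on a
# 2-month imaging cadence with 10% multiplicative measurement noise, 2D
# diameter proxies whose agreement with volume change is imperfect, cystic
# components with near-static dynamics, whole-tumor volume diluted by cyst and
# a stable edema margin, occasional new lesions in progressing tumors, and two
# simulated BT-RADS readers with substantial but imperfect agreement.

#' Synthetic cohort configuration
#'
#' Defaults encode the study conditions the generator emulates: 43
#' participants imaged every ~2 months (61 days) for up to 700 days under 10%
#' measurement noise; 65 assessment images (one "early" ~6-month image per
#' participant plus one "late" last-follow-up image for 22 of them) with an
#' exact PR/SD/PD class mix of 14/23/28; ~79% of participants with cystic
#' components; whole tumor = 1.2 x solid + cyst; 2D-3D shape distortion
#' calibrated so roughly 69% of follow-ups show sign-congruent 2D and 3D
#' change; and a second reader discordant on ~11/65 assessments.
#'
#' @param n_participants Number of participants.
#' @param cadence_days Imaging interval in days.
#' @param horizon_days Maximum follow-up time in days.
#' @param noise_cv Multiplicative measurement noise (coefficient of variation).
#' @param class_mix Named counts of assessment images per true class
#'   (`PR`, `SD`, `PD`); their sum is the number of assessment images.
#' @param n_late Number of participants with a second (late) assessment.
#' @param early_visit Index of the follow-up visit used as the early
#'   assessment (3 = ~183 days).
#' @param cyst_fraction Fraction of participants with a cystic component.
#' @param edema_multiplier Whole volume = multiplier x solid + cyst.
#' @param baseline_volume_meanlog,baseline_volume_sdlog Lognormal parameters
#'   of the baseline solid volume (cm^3).
#' @param shape_distortion_cv Per-lesion lognormal distortion of the two
#'   diameters relative to the volume-equivalent sphere diameter.
#' @param jitter_cv Per-visit re-draw jitter of the diameter distortions; this
#'   is what makes 2D change a noisy proxy of volume change.
#' @param whole_noise_cv Measurement noise of the whole-tumor (FLAIR) volume;
#'   larger than `noise_cv` because whole-tumor segmentations include
#'   peritumoral edema and are less reproducible than solid-tumor volumes.
#' @param new_lesion_prob Probability that a progressing participant develops
#'   a new lesion at its PD assessment.
#' @param reader_discordance Probability that reader 2 disagrees with reader
#'   1 on an assessment; discordant reads cross into the adjacent response
#'   category (stable vs responding/progressing), the pattern reported for
#'   real blinded double reads.
#' @param seed Integer seed (mandatory).
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_participants = 43,
                          cadence_days = 61,
                          horizon_days = 700,
                          noise_cv = 0.10,
                          class_mix = c(PR = 14, SD = 23, PD = 28),
                          n_late = 22,
                          early_visit = 3,
                          cyst_fraction = 0.791,
                          edema_multiplier = 1.2,
                          baseline_volume_meanlog = log(30),
                          baseline_volume_sdlog = 0.9,
                          shape_distortion_cv = 0.15,
                          jitter_cv = 0.24,
                          whole_noise_cv = 0.20,
                          new_lesion_prob = 0.15,
                          reader_discordance = 11 / 65,
                          seed) {
  if (missing(seed)) stop_volresp("seed is mandatory", class = "invalid_config")
  stopifnot(all(class_mix >= 0), noise_cv >= 0, shape_distortion_cv >= 0,
            n_late <= n_participants,
            sum(class_mix) == n_participants + n_late)
  structure(as.list(environment()), class = "cohort_config")
}

#' Simulate one observed volume trajectory
#'
#' Observation times are 0, `cadence`, ..., `n_followups * cadence`; each
#' observed volume is the closed-form model volume times an independent
#' lognormal factor with unit mean and coefficient of variation `noise_cv`.
#'
#' @inheritParams growth_volume
#' @param cadence_days Imaging interval in days.
#' @param horizon_days Maximum follow-up time; caps the number of visits.
#' @param n_followups Number of post-baseline visits (default: as many as fit
#'   within the horizon).
#' @param noise_cv Measurement coefficient of variation.
#' @param seed Integer seed.
#' @return Data frame with `t_days`, `volume` (observed, cm^3), and
#'   `volume_true` (noiseless).
#' @export
simulate_trajectory <- function(lambda, gamma0, eps, V_b,
                                cadence_days = 61, horizon_days = 700,
                                n_followups = floor(horizon_days / cadence_days),
                                noise_cv = 0.10, seed = 1) {
  n_followups <- min(n_followups, floor(horizon_days / cadence_days))
  t <- seq(0, n_followups) * cadence_days
  set.seed(seed)
  v_true <- growth_volume(t, lambda, gamma0, eps, V_b)
  data.frame(t_days = t, volume = v_true * rlnorm_cv(length(t), noise_cv),
             volume_true = v_true)
}

#' Derive bidimensional diameters from a volume series
#'
#' The volume-equivalent sphere diameter is `(6 V / pi)^(1/3)`. The two
#' reported diameters are that diameter times per-lesion lognormal distortion
#' factors (held fixed across visits) times per-visit lognormal jitter, then
#' ordered so `d1 >= d2`. With both distortion and jitter at zero the 2D-area
#' percent change is exactly the sphere-collapse of the volume percent change.
#'
#' @param volume Vector of (noiseless) volumes over visits, cm^3.
#' @param shape_distortion_cv CV of the fixed per-lesion distortion factors.
#' @param jitter_cv CV of the per-visit jitter.
#' @param seed Optional seed; omit when called inside a seeded simulation.
#' @return Data frame with columns `d1`, `d2` (cm), one row per visit.
#' @export
derive_2d_from_volume <- function(volume, shape_distortion_cv = 0,
                                  jitter_cv = shape_distortion_cv / 2,
                                  seed = NULL) {
  stopifnot(all(volume > 0))
  if (!is.null(seed)) set.seed(seed)
  d_sphere <- (6 * volume / pi)^(1 / 3)
  delta <- rlnorm_cv(2, shape_distortion_cv)
  n <- length(volume)
  d1 <- d_sphere * delta[1] * rlnorm_cv(n, jitter_cv)
  d2 <- d_sphere * delta[2] * rlnorm_cv(n, jitter_cv)
  data.frame(d1 = pmax(d1, d2), d2 = pmin(d1, d2))
}

# Grouped truth class from a noiseless trajectory: volume-extrapolated RAPNO
# thresholds with MinR grouped into PR (visual assessment does not
# sub-differentiate minor response).
true_class_at <- function(v_t, v_b, spec) {
  lab <- as.character(classify_change(100 * (v_t - v_b) / v_b, spec))
  ifelse(lab == "MinR", "PR", lab)
}

# Class-conditional parameter proposal ranges. Keyed by the intended class
# sequence at the assessment times; chosen (once) so that rejection sampling
# against the noiseless trajectory classification converges quickly while
# producing clinically plausible rates (units 1/day).
param_ranges_for <- function(key) {
  switch(key,
    PD       = list(lambda = c(3e-3, 1e-2), gamma0 = c(0, 4e-3),
                    eps = c(5e-3, 2e-2)),
    SD       = list(lambda = c(1e-4, 2e-3), gamma0 = c(0, 3e-3),
                    eps = c(2e-3, 2e-2)),
    PR       = list(lambda = c(1e-4, 1.2e-3), gamma0 = c(8e-3, 3e-2),
                    eps = c(5e-4, 3e-3)),
    SD_PD    = list(lambda = c(2e-3, 6e-3), gamma0 = c(2e-3, 1e-2),
                    eps = c(4e-3, 1.2e-2)),
    SD_PR    = list(lambda = c(1e-4, 6e-4), gamma0 = c(1.5e-3, 4e-3),
                    eps = c(3e-4, 8e-4)),
    PR_SD    = list(lambda = c(2e-3, 8e-3), gamma0 = c(1e-2, 3e-2),
                    eps = c(5e-3, 2e-2)),
    stop("unknown parameter range key: ", key)
  )
}

range_key <- function(classes) {
  if (length(classes) == 1 || classes[1] == classes[2]) return(classes[1])
  paste(classes, collapse = "_")
}

# Assign intended classes to assessment slots so that totals match class_mix
# exactly and every (early, late) pair is dynamically feasible under the
# model (a tumor already progressing at the early visit cannot later be
# stable or responding; a deep early response regrowing all the way past +40%
# within the horizon is excluded as well).
assign_classes <- function(config) {
  tokens <- rep(names(config$class_mix), config$class_mix)
  allowed_early <- list(PD = c("SD", "PD"), SD = c("SD", "PR"),
                        PR = c("SD", "PR"))
  for (attempt in 1:1000) {
    pool <- sample(tokens)
    pairs <- matrix(NA_character_, nrow = config$n_late, ncol = 2)
    ok <- TRUE
    for (i in seq_len(config$n_late)) {
      late <- pool[1]; pool <- pool[-1]
      cand <- which(pool %in% allowed_early[[late]])
      if (length(cand) == 0) { ok <- FALSE; break }
      j <- cand[sample.int(length(cand), 1)]
      pairs[i, ] <- c(pool[j], late)
      pool <- pool[-j]
    }
    if (ok) return(list(pairs = pairs, singles = pool))
  }
  stop_volresp("infeasible class mix", class = "infeasible_class_mix")
}

# Rejection-sample growth parameters until the noiseless trajectory yields
# the intended class(es) at the assessment time(s).
draw_params_for <- function(classes, t_assess, spec, max_tries = 20000) {
  rng <- param_ranges_for(range_key(classes))
  for (i in seq_len(max_tries)) {
    lam <- stats::runif(1, rng$lambda[1], rng$lambda[2])
    g0 <- stats::runif(1, rng$gamma0[1], rng$gamma0[2])
    ep <- stats::runif(1, rng$eps[1], rng$eps[2])
    v_rel <- growth_volume(t_assess, lam, g0, ep, V_b = 1)
    if (all(true_class_at(v_rel, 1, spec) == classes)) {
      return(c(lambda = lam, gamma0 = g0, eps = ep))
    }
  }
  stop_volresp("could not realise class sequence ",
               paste(classes, collapse = "->"),
               class = "infeasible_class_mix")
}

btrads_for_class <- function(class) {
  switch(class,
         PR = "1a",
         SD = sample(c("2", "3a", "1b", "3b"), 1, prob = c(.6, .2, .1, .1)),
         PD = sample(c("3c", "4"), 1))
}

# Discordant second reads cross a response-category boundary: subtle changes
# called stable by one reader and responding/progressing by the other. The
# discordant score is the nearest score of an adjacent response category.
perturb_read <- function(score, prob) {
  if (stats::runif(1) >= prob) return(score)
  cat <- as.character(btrads_category(score))
  target <- switch(cat,
                   PR = "SD",
                   PD = "SD",
                   SD = sample(c("PR", "PD"), 1))
  switch(target, PR = "1a", SD = if (cat == "PR") "2" else "3a", PD = "3c")
}

#' Simulate a synthetic cohort
#'
#' Draws per-participant growth parameters conditioned on an intended
#' response class at each assessment image (rejection sampling against the
#' noiseless trajectory under the volume-extrapolated RAPNO rules, minor
#' response grouped with PR), builds observed solid/whole/cyst volume series
#' and 2D diameter proxies, adds occasional new lesions in progressing
#' tumors, and simulates two BT-RADS readers at the assessment images.
#'
#' @param config A [cohort_config()].
#' @return List with `series` (named list of [participant_series]), `truth`
#'   (list with `params` and `assessments` data frames - the latent ground
#'   truth behind each series), and `config`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n <- config$n_participants
  spec <- response_criteria("VOLX_RAPNO")
  cls <- assign_classes(config)
  dual_ids <- sort(sample.int(n, config$n_late))
  single_ids <- setdiff(seq_len(n), dual_ids)

  max_fu <- floor(config$horizon_days / config$cadence_days)
  n_fu <- integer(n)
  n_fu[single_ids] <- sample(config$early_visit:min(8, max_fu),
                             length(single_ids), replace = TRUE,
                             prob = c(.40, .25, .12, .10, .08, .05)[
                               seq_len(min(8, max_fu) - config$early_visit + 1)])
  n_fu[dual_ids] <- sample((config$early_visit + 1):min(9, max_fu),
                           length(dual_ids), replace = TRUE,
                           prob = c(.45, .20, .12, .10, .08, .05)[
                             seq_len(min(9, max_fu) - config$early_visit)])

  classes <- vector("list", n)
  for (k in seq_along(single_ids)) classes[[single_ids[k]]] <- cls$singles[k]
  for (k in seq_along(dual_ids)) classes[[dual_ids[k]]] <- cls$pairs[k, ]

  rows <- list(); truth_params <- list(); truth_assess <- list()
  for (i in seq_len(n)) {
    id <- sprintf("SYN-%02d", i)
    t <- seq(0, n_fu[i]) * config$cadence_days
    t_early <- config$early_visit * config$cadence_days
    t_late <- if (i %in% dual_ids) n_fu[i] * config$cadence_days else NULL
    t_assess <- c(t_early, t_late)
    p <- draw_params_for(classes[[i]], t_assess, spec)
    V_b <- stats::rlnorm(1, config$baseline_volume_meanlog,
                         config$baseline_volume_sdlog)
    v_true <- growth_volume(t, p["lambda"], p["gamma0"], p["eps"], V_b)
    v_obs <- v_true * rlnorm_cv(length(t), config$noise_cv)
    d2d <- derive_2d_from_volume(v_true, config$shape_distortion_cv,
                                 config$jitter_cv)
    cystic <- stats::runif(1) < config$cyst_fraction
    cyst <- if (cystic) {
      c0 <- stats::rlnorm(1, log(6), 0.8)
      c0 * exp(cumsum(c(0, stats::rnorm(length(t) - 1, 0, 0.03))))
    } else rep(NA_real_, length(t))
    whole_true <- config$edema_multiplier * v_true +
      ifelse(is.na(cyst), 0, cyst)
    whole_obs <- whole_true * rlnorm_cv(length(t), config$whole_noise_cv)
    if (cystic) whole_obs <- pmax(whole_obs, cyst * 1.01)

    new_lesion <- rep(FALSE, length(t))
    assess_class <- true_class_at(growth_volume(t_assess, p["lambda"],
                                                p["gamma0"], p["eps"], 1),
                                  1, spec)
    if (any(assess_class == "PD") &&
        stats::runif(1) < config$new_lesion_prob) {
      t_pd <- t_assess[which(assess_class == "PD")[1]]
      new_lesion[t >= t_pd] <- TRUE
    }

    r1 <- r2 <- rep(NA_character_, length(t))
    for (j in seq_along(t_assess)) {
      k <- match(t_assess[j], t)
      r1[k] <- btrads_for_class(assess_class[j])
      r2[k] <- perturb_read(r1[k], config$reader_discordance)
    }

    rows[[i]] <- data.frame(
      participant_id = id, t_days = t, lesion_id = "L1",
      d1_cm = d2d$d1, d2_cm = d2d$d2,
      base_volume_cm3 = v_obs + ifelse(is.na(cyst), 0, cyst),
      cyst_in_solid_cm3 = cyst,
      whole_volume_cm3 = whole_obs, total_cyst_cm3 = cyst,
      new_lesion = new_lesion,
      btrads_reader1 = r1, btrads_reader2 = r2,
      stringsAsFactors = FALSE
    )
    tvmin <- time_of_minimum(p["lambda"], p["gamma0"], p["eps"])
    truth_params[[i]] <- data.frame(
      participant_id = id, lambda = p["lambda"], gamma0 = p["gamma0"],
      eps = p["eps"], V_b = V_b, t_vmin = tvmin, cystic = cystic,
      n_followups = n_fu[i], row.names = NULL
    )
    band <- 100 * config$noise_cv
    model_class <- vapply(seq_along(t_assess), function(j) {
      te <- t_assess[j]
      if (te > tvmin) "PD"
      else {
        pct <- 100 * (growth_volume(t[t > 0 & t <= te], p["lambda"],
                                    p["gamma0"], p["eps"], 1) - 1)
        if (all(abs(pct) <= band)) "SD" else "PR"
      }
    }, "")
    truth_assess[[i]] <- data.frame(
      participant_id = id, t_days = t_assess,
      slot = c("early", if (length(t_assess) == 2) "late"),
      true_class = assess_class, true_model_class = model_class,
      new_lesion = new_lesion[match(t_assess, t)], row.names = NULL
    )
  }

  long <- do.call(rbind, rows)
  series <- lapply(split(long, long$participant_id), participant_series)
  list(series = series,
       truth = list(params = do.call(rbind, truth_params),
                    assessments = do.call(rbind, truth_assess)),
       config = config)
}
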