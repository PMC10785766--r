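# Shared fixture builders. Everything is generated in code; no data files.

# Minimal lesion-level long table for one participant from per-image vectors.
long_table <- function(id = "P1", t_days, solid = NULL, d1 = NULL, d2 = NULL,
                       whole = NULL, cyst = NULL, new_lesion = FALSE,
                       btrads1 = NA, btrads2 = NA) {
  n <- length(t_days)
  fill <- function(x) if (is.null(x)) rep(NA_real_, n) else rep_len(x, n)
  data.frame(
    participant_id = id, t_days = t_days, lesion_id = "L1",
    d1_cm = fill(d1), d2_cm = fill(d2),
    base_volume_cm3 = fill(solid), cyst_in_solid_cm3 = rep(NA_real_, n),
    whole_volume_cm3 = fill(whole), total_cyst_cm3 = fill(cyst),
    new_lesion = rep_len(new_lesion, n),
    btrads_reader1 = rep_len(as.character(btrads1), n),
    btrads_reader2 = rep_len(as.character(btrads2), n),
    stringsAsFactors = FALSE
  )
}

# participant_series from a solid-volume vector (baseline first at t = 0).
series_from_volumes <- function(volumes, t_days = (seq_along(volumes) - 1) * 61,
                                id = "P1", new_lesion = FALSE) {
  participant_series(long_table(id, t_days, solid = volumes,
                                new_lesion = new_lesion))
}

# Hand-built growth_fit with a degenerate posterior, for testing the
# classification rules in isolation from the sampler.
fake_growth_fit <- function(lambda = 0.005, gamma0 = 0.02, eps = 0.01,
                            V_b = 10, n = 200, noise_cv = 0.10,
                            t_vmin = NULL) {
  samples <- cbind(lambda = rep(lambda, n), gamma0 = rep(gamma0, n),
                   eps = rep(eps, n), V_b = rep(V_b, n))
  tv <- if (is.null(t_vmin)) {
    time_of_minimum(samples[, 1], samples[, 2], samples[, 3])
  } else rep(t_vmin, n)
  structure(
    list(samples = samples, t_vmin = tv, v_min = rep(V_b, n),
         acceptance = 0.5, convergence_ok = TRUE,
         data = list(t = numeric(0), v = numeric(0)),
         noise_cv = noise_cv, priors = growth_priors(vb_center = V_b),
         n_walkers = 0L, n_steps = 0L, n_boot = 1L, seed = 0L),
    class = "growth_fit"
  )
}

# Exhaustive Mann-Whitney pair-counting AUC (independent oracle).
auc_pair_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + (p > q) + 0.5 * (p == q)
  }
  total / (length(pos) * length(neg))
}

# Small pipeline-scale cohort (17 assessments) for smoke/determinism tests.
small_cohort_config <- function(seed, ...) {
  cohort_config(n_participants = 12, n_late = 5,
                class_mix = c(PR = 4, SD = 6, PD = 7), seed = seed, ...)
}

fast_pipeline_config <- function(seed = 1, ...) {
  pipeline_config(n_boot = 200, growth_walkers = 16, growth_steps = 300,
                  lambda_mode = "free", seed = seed, ...)
}
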