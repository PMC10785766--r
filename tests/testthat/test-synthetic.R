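test_that("simulated trajectories are seeded and exact without noise", {
  tr <- simulate_trajectory(0.004, 0.02, 0.01, 10, n_followups = 6,
                            noise_cv = 0, seed = 1)
  expect_equal(tr$volume, growth_volume(tr$t_days, 0.004, 0.02, 0.01, 10))
  tr1 <- simulate_trajectory(0.004, 0.02, 0.01, 10, seed = 2)
  tr2 <- simulate_trajectory(0.004, 0.02, 0.01, 10, seed = 2)
  expect_identical(tr1, tr2)
  expect_false(identical(
    tr1$volume, simulate_trajectory(0.004, 0.02, 0.01, 10, seed = 3)$volume))
})

test_that("2D derivation reduces to the sphere diameter without distortion", {
  d <- derive_2d_from_volume(4.18879020478639, 0)  # unit-radius sphere
  expect_equal(d$d1, 2, tolerance = 1e-10)
  expect_equal(d$d2, 2, tolerance = 1e-10)

  # zero distortion: 2D-area change is the sphere-collapse of volume change
  v <- c(10, 14, 7)
  dd <- derive_2d_from_volume(v, 0)
  area <- dd$d1 * dd$d2
  expect_equal(area / area[1] - 1, sphere_collapse(v / v[1] - 1),
               tolerance = 1e-12)
  expect_true(all(dd$d1 >= dd$d2))
})

test_that("default cohort hits the intended class mix and cadence", {
  coh <- simulate_cohort(cohort_config(seed = 101))
  expect_length(coh$series, 43)
  counts <- table(coh$truth$assessments$true_class)
  expect_equal(unname(counts[c("PR", "SD", "PD")]), c(14, 23, 28),
               ignore_attr = TRUE)
  expect_equal(nrow(coh$truth$assessments), 65)
  expect_lte(abs(median(coh$truth$params$n_followups) - 4), 1)
  # two-month cadence on every series
  gaps <- unlist(lapply(coh$series, function(s) diff(s$images$t_days)))
  expect_true(all(gaps == 61))
})

test_that("cohorts are reproducible and CSV round-trips byte-identically", {
  c1 <- simulate_cohort(small_cohort_config(seed = 7))
  c2 <- simulate_cohort(small_cohort_config(seed = 7))
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_measurements(c1$series, f1)
  write_measurements(c2$series, f2)
  expect_identical(readLines(f1), readLines(f2))

  back <- read_measurements(f1)
  expect_equal(names(back), names(c1$series))
  for (id in names(back)) {
    expect_equal(back[[id]]$images, c1$series[[id]]$images)
  }
  unlink(c(f1, f2))
})

test_that("with all noise off, every stage recovers the ground truth", {
  cfg <- small_cohort_config(seed = 5, noise_cv = 0, whole_noise_cv = 0,
                             shape_distortion_cv = 0, jitter_cv = 0,
                             reader_discordance = 0, new_lesion_prob = 0)
  coh <- simulate_cohort(cfg)
  spec <- response_criteria("VOLX_RAPNO")
  tr <- coh$truth$assessments
  for (i in seq_len(nrow(tr))) {
    s <- coh$series[[tr$participant_id[i]]]
    cl <- classify_series(s, spec)
    lab <- as.character(cl$label[match(tr$t_days[i], cl$t_days)])
    if (lab == "MinR") lab <- "PR"
    expect_equal(lab, tr$true_class[i])
  }
  # solid-volume change separates true PD perfectly
  at <- volresp:::assessment_table(coh$series,
                                   c("area2d", "solid_volume"))
  key <- paste(at$participant_id, at$t_days)
  truecl <- tr$true_class[match(key, paste(tr$participant_id, tr$t_days))]
  expect_equal(roc_auc(at$pct_solid_volume, truecl == "PD"), 1)
  # and the simulated readers agree perfectly
  expect_equal(weighted_kappa(at$btrads_reader1,
                              at$btrads_reader2)$kappa_weighted, 1)
})

test_that("shape distortion degrades the 2D proxy but not solid volume", {
  auc_for <- function(seed, distortion, jitter) {
    coh <- simulate_cohort(small_cohort_config(
      seed = seed, shape_distortion_cv = distortion, jitter_cv = jitter))
    at <- volresp:::assessment_table(coh$series,
                                     c("area2d", "solid_volume"))
    tr <- coh$truth$assessments
    key <- paste(at$participant_id, at$t_days)
    lab <- tr$true_class[match(key, paste(tr$participant_id, tr$t_days))] == "PD"
    c(a2d = roc_auc(at$pct_area2d, lab),
      solid = roc_auc(at$pct_solid_volume, lab))
  }
  low <- vapply(1:4, function(k) auc_for(300 + k, 0.03, 0.03), c(0, 0))
  high <- vapply(1:4, function(k) auc_for(300 + k, 0.40, 0.40), c(0, 0))
  expect_gt(mean(low["a2d", ]), mean(high["a2d", ]))
  expect_gt(mean(high["solid", ]), 0.95)
})

test_that("simulated readers show substantial but imperfect agreement", {
  kaps <- vapply(1:4, function(k) {
    coh <- simulate_cohort(cohort_config(seed = 400 + k))
    at <- volresp:::assessment_table(coh$series, "solid_volume")
    weighted_kappa(at$btrads_reader1, at$btrads_reader2)$kappa_weighted
  }, 0)
  expect_gt(mean(kaps), 0.68)
  expect_lt(mean(kaps), 0.92)
})

test_that("2D and 3D change agree in sign on roughly 7 in 10 follow-ups", {
  congs <- vapply(1:4, function(k) {
    coh <- simulate_cohort(cohort_config(seed = 500 + k))
    mean(unlist(lapply(coh$series, function(s) {
      a <- series_percent_changes(s, "area2d")$pct
      b <- series_percent_changes(s, "solid_volume")$pct
      sign(a) == sign(b)
    })), na.rm = TRUE)
  }, 0)
  expect_gt(mean(congs), 0.61)
  expect_lt(mean(congs), 0.85)
})

test_that("cohort configuration is validated", {
  expect_error(cohort_config(), class = "invalid_config")
  expect_error(cohort_config(n_participants = 10, n_late = 2,
                             class_mix = c(PR = 2, SD = 3, PD = 4), seed = 1))
})
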