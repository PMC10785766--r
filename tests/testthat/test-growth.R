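test_that("closed-form volume matches the ODE and its limits", {
  # no treatment: pure exponential
  t <- seq(0, 500, by = 50)
  expect_equal(growth_volume(t, 0.004, 0, 0.01, 10), 10 * exp(0.004 * t))
  expect_equal(growth_volume(0, 0.004, 0.02, 0.01, 10), 10)
  # eps = 0 limit
  expect_equal(growth_volume(t, 0.004, 0.001, 0, 10),
               10 * exp(0.003 * t))
  expect_true(all(growth_volume(t, 0.001, 0.05, 0.002, 10) > 0))

  skip_if_not_installed("deSolve")
  rhs <- function(t, y, p) {
    list((p$lambda - p$gamma0 * exp(-p$eps * t)) * y)
  }
  sol <- deSolve::lsoda(c(V = 10), times = c(0, 100), func = rhs,
                        parms = list(lambda = 0.004, gamma0 = 0.02,
                                     eps = 0.01),
                        rtol = 1e-10, atol = 1e-12)
  expect_equal(growth_volume(100, 0.004, 0.02, 0.01, 10),
               unname(sol[2, "V"]), tolerance = 1e-8)
})

test_that("time of minimum: closed form, boundaries, global minimality", {
  expect_equal(time_of_minimum(0.01, 0.04, 0.01), log(4) / 0.01)
  expect_equal(time_of_minimum(0.01, 0.01, 0.01), 0)  # gamma0 = lambda
  expect_equal(time_of_minimum(0.02, 0.01, 0.01), 0)  # no shrinkage phase
  expect_equal(time_of_minimum(0, 0.01, 0.005), Inf)  # monotone decrease

  set.seed(23)
  tg <- seq(0, 1000, by = 1)
  for (i in 1:20) {
    lam <- runif(1, 1e-4, 0.02); g0 <- runif(1, 0, 0.05)
    ep <- runif(1, 1e-3, 0.05)
    tv <- time_of_minimum(lam, g0, ep)
    v <- growth_volume(tg, lam, g0, ep, 10)
    if (is.finite(tv) && tv <= 1000) {
      expect_lte(growth_volume(tv, lam, g0, ep, 10), min(v) + 1e-9)
      # net growth rate crosses zero exactly at t_vmin when gamma0 > lambda
      if (g0 > lam && tv > 0) {
        rate <- function(t) lam - g0 * exp(-ep * t)
        expect_lt(rate(tv - 1e-6), 0)
        expect_gt(rate(tv + 1e-6), 0)
      }
    }
  }
})

test_that("log posterior: peak at truth, scale equivariance, prior support", {
  truth <- list(lambda = 0.005, gamma0 = 0.02, eps = 0.008, V_b = 15)
  t <- (0:8) * 61
  v <- growth_volume(t, truth$lambda, truth$gamma0, truth$eps, truth$V_b)
  pri <- growth_priors(vb_center = 15)
  th0 <- c(log(truth$lambda), truth$gamma0, log(truth$eps), log(truth$V_b))
  lp0 <- growth_log_posterior(th0, t, v, noise_cv = 0.01, priors = pri)
  for (shift in list(c(0.2, 0, 0, 0), c(0, 0.005, 0, 0), c(0, 0, 0.3, 0),
                     c(0, 0, 0, 0.1))) {
    expect_lt(growth_log_posterior(th0 + shift, t, v, 0.01, pri), lp0)
  }

  # doubling volumes and V_b leaves the likelihood shape invariant
  pri2 <- growth_priors(vb_center = 30)
  th2 <- th0 + c(0, 0, 0, log(2))
  expect_equal(growth_log_posterior(th2, t, 2 * v, 0.1, pri2),
               growth_log_posterior(th0, t, v, 0.1, pri))

  # outside the prior support the density vanishes
  th_bad <- c(log(0.2), 0.02, log(0.008), log(15))
  expect_identical(growth_log_posterior(th_bad, t, v, 0.1, pri), -Inf)
  expect_error(growth_log_posterior(th0, t, c(v[-1], -1), 0.1, pri),
               class = "invalid_measurement")
})

test_that("MCMC fit is reproducible and recovers known parameters", {
  tr <- simulate_trajectory(0.006, 0.02, 0.008, 20, n_followups = 9,
                            noise_cv = 0.05, seed = 42)
  f1 <- fit_growth(tr$t_days, tr$volume, noise_cv = 0.05,
                   n_walkers = 20, n_steps = 800, seed = 7)
  f2 <- fit_growth(tr$t_days, tr$volume, noise_cv = 0.05,
                   n_walkers = 20, n_steps = 800, seed = 7)
  expect_identical(f1$samples, f2$samples)
  expect_true(f1$convergence_ok)
  cf <- coef(f1)
  expect_lt(abs(cf["gamma0"] - 0.02) / 0.02, 0.25)
  expect_lt(abs(cf["eps"] - 0.008) / 0.008, 0.30)
  expect_lt(abs(cf["V_b"] - 20) / 20, 0.15)
})

test_that("prior-only fit reproduces prior quantiles", {
  pri <- growth_priors(vb_center = 10)
  f <- fit_growth(numeric(0), numeric(0), priors = pri,
                  n_walkers = 40, n_steps = 1500, seed = 3)
  # gamma0 ~ U(0, 0.2): median 0.1; lambda log-uniform: log-median at midpoint
  expect_equal(unname(coef(f)["gamma0"]), 0.1, tolerance = 0.15)
  expect_equal(log(unname(coef(f)["lambda"])),
               mean(log(c(1e-5, 0.05))), tolerance = 0.4)
})

test_that("fit methods: predict, residuals, simulate behave", {
  tr <- simulate_trajectory(0.004, 0.015, 0.01, 12, n_followups = 7,
                            noise_cv = 0.05, seed = 5)
  f <- fit_growth(tr$t_days, tr$volume, noise_cv = 0.05,
                  n_walkers = 16, n_steps = 400, seed = 2)
  pr <- predict(f, t = c(0, 100, 200))
  expect_equal(nrow(pr), 3)
  expect_true(all(pr$lwr <= pr$fit & pr$fit <= pr$upr))
  expect_length(residuals(f), length(tr$t_days))
  sim <- simulate(f, nsim = 3, seed = 9)
  expect_equal(dim(sim), c(length(tr$t_days), 3))
  expect_true(all(sim > 0))
})

test_that("measurement bootstrap pools refits and widens t_vmin spread", {
  tr <- simulate_trajectory(0.005, 0.02, 0.008, 15, n_followups = 8,
                            noise_cv = 0.10, seed = 30)
  single <- fit_growth(tr$t_days, tr$volume, n_walkers = 16, n_steps = 400,
                       seed = 11)
  pooled <- bootstrap_refits(tr$t_days, tr$volume, n_boot = 8,
                             noise_cv = 0.10, seed = 11,
                             n_walkers = 16, n_steps = 400)
  expect_equal(pooled$n_boot, 8L)
  expect_equal(nrow(pooled$samples), 8 * nrow(single$samples))
  iqr <- function(x) diff(quantile(x, c(0.25, 0.75)))
  expect_gte(iqr(pooled$t_vmin), 0.8 * iqr(single$t_vmin))

  # degenerate bootstrap (zero perturbation) matches a single fit
  pooled0 <- bootstrap_refits(tr$t_days, tr$volume, n_boot = 3,
                              perturb_cv = 0, seed = 4,
                              n_walkers = 16, n_steps = 400)
  expect_equal(median(pooled0$samples[, "gamma0"]),
               median(single$samples[, "gamma0"]), tolerance = 0.2)
})

test_that("widening assumed noise widens the posterior", {
  tr <- simulate_trajectory(0.005, 0.02, 0.008, 15, n_followups = 8,
                            noise_cv = 0.05, seed = 77)
  widths <- vapply(c(0.05, 0.25), function(cv) {
    f <- fit_growth(tr$t_days, tr$volume, noise_cv = cv,
                    n_walkers = 20, n_steps = 600, seed = 13)
    diff(quantile(f$samples[, "gamma0"], c(0.1, 0.9)))
  }, 0)
  expect_gt(widths[2], widths[1])
})

test_that("trajectory classification follows the PD -> SD -> PR precedence", {
  flat <- series_from_volumes(c(10, 10.4, 9.7, 10.2, 9.9))
  shrink <- series_from_volumes(c(10, 9.0, 8.0, 7.0, 6.5))

  # posterior t_Vmin concentrated at 100 d, evaluated at 400 d: PD
  early_min <- fake_growth_fit(t_vmin = 100)
  expect_equal(classify_trajectory(early_min, flat, 400)$label, "PD")

  # t_eval before q75: flat series inside the +/-10% band is SD
  late_min <- fake_growth_fit(t_vmin = 1000)
  expect_equal(classify_trajectory(late_min, flat, 244)$label, "SD")

  # shrinking series (-35% at t_eval) before q75 is PR
  expect_equal(classify_trajectory(late_min, shrink, 244)$label, "PR")

  # classification is invariant to rescaling all volumes
  shrink10 <- series_from_volumes(10 * c(10, 9.0, 8.0, 7.0, 6.5))
  expect_equal(classify_trajectory(late_min, shrink10, 244)$label, "PR")

  df <- long_table("P9", c(0, 61), whole = c(12, 13))
  s_nobase <- participant_series(df)
  expect_error(classify_trajectory(late_min, s_nobase, 61),
               class = "missing_baseline_measure")
})

test_that("responder comparison separates groups on eps, not lambda", {
  set.seed(44)
  make_fit <- function(eps, lambda = 0.004) {
    fake_growth_fit(lambda = lambda * runif(1, 0.9, 1.1),
                    gamma0 = 0.02 * runif(1, 0.9, 1.1),
                    eps = eps * runif(1, 0.9, 1.1))
  }
  responders <- replicate(6, make_fit(eps = 0.0015), simplify = FALSE)
  resistant <- replicate(6, make_fit(eps = 0.006), simplify = FALSE)
  cmp <- compare_responders(c(responders, resistant), cutoff = 365)
  expect_equal(cmp$n_responding, 6)
  expect_equal(cmp$n_resistant, 6)
  tab <- cmp$table
  expect_lt(tab$p_value[tab$parameter == "eps"], 0.05)
  expect_gt(tab$p_value[tab$parameter == "lambda"], 0.05)
  expect_lt(tab$median_responding[tab$parameter == "eps"],
            tab$median_resistant[tab$parameter == "eps"])

  # identical fits: every comparison is uninformative
  same <- replicate(4, fake_growth_fit(eps = 0.002), simplify = FALSE)
  cmp2 <- compare_responders(same, cutoff = stats::median(same[[1]]$t_vmin))
  expect_true(all(is.na(cmp2$table$p_value) | cmp2$table$p_value == 1))

  # cutoff at -Inf: single group, tests skipped
  cmp3 <- compare_responders(c(responders, resistant), cutoff = -Inf)
  expect_equal(cmp3$n_resistant, 0)
  expect_true(all(is.na(cmp3$table$p_value)))
})

test_that("cohort fitting shares lambda and skips short series", {
  set.seed(55)
  mk <- function(id, n) {
    v <- growth_volume((0:n) * 61, 0.004, 0.015, 0.006, 20) *
      exp(rnorm(n + 1, 0, 0.05))
    series_from_volumes(v, id = id)
  }
  sl <- list(A = mk("A", 6), B = mk("B", 5), C = mk("C", 2))
  res <- fit_growth_cohort(sl, min_points = 4, seed = 8,
                           n_walkers = 16, n_steps = 300)
  expect_equal(res$skipped, "C")
  expect_true(is.finite(res$lambda_shared))
  for (f in res$fits) {
    expect_true(all(f$samples[, "lambda"] == res$lambda_shared))
  }
  free <- fit_growth_cohort(sl, lambda_mode = "free", min_points = 4,
                            seed = 8, n_walkers = 16, n_steps = 300)
  expect_true(is.na(free$lambda_shared))
  expect_gt(var(free$fits$A$samples[, "lambda"]), 0)
})
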