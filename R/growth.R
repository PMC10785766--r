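# Mechanistic regression-regrowth model of solid tumor volume.
#
# dV/dt = (lambda - gamma0 * exp(-eps * t)) * V
#
# lambda : exponential growth rate (1/day)
# gamma0 : initial treatment-induced shrinkage rate (1/day)
# eps    : resistance-onset rate (1/day) - the treatment effect decays as
#          exp(-eps * t), producing an optional initial dip before regrowth
# V_b    : volume at treatment start (cm^3)
#
# The ODE integrates in closed form:
#   V(t) = V_b * exp(lambda * t - (gamma0 / eps) * (1 - exp(-eps * t)))

#' Model tumor volume at time t
#'
#' Closed-form solution of the regression-regrowth model
#' `dV/dt = (lambda - gamma0 * exp(-eps * t)) * V`, describing exponential
#' growth at rate `lambda`, treatment-induced shrinkage at initial rate
#' `gamma0`, and exponential decay of the treatment effect at resistance-onset
#' rate `eps`. `eps = 0` is handled by its limit `V_b * exp((lambda - gamma0) * t)`.
#'
#' @param t Time(s) in days since treatment start.
#' @param lambda Growth rate, 1/day, `>= 0`.
#' @param gamma0 Initial shrinkage rate, 1/day, `>= 0`.
#' @param eps Resistance-onset rate, 1/day, `>= 0`.
#' @param V_b Volume at `t = 0`, cm^3, `> 0`.
#' @return Volume(s) in cm^3, strictly positive.
#' @examples
#' growth_volume(0:10 * 61, lambda = 0.004, gamma0 = 0.02, eps = 0.01, V_b = 10)
#' @export
growth_volume <- function(t, lambda, gamma0, eps, V_b) {
  stopifnot(lambda >= 0, gamma0 >= 0, eps >= 0, V_b > 0)
  if (eps == 0) {
    return(V_b * exp((lambda - gamma0) * t))
  }
  V_b * exp(lambda * t - (gamma0 / eps) * (1 - exp(-eps * t)))
}

#' Time at which the modelled volume reaches its minimum
#'
#' The net growth rate `lambda - gamma0 * exp(-eps * t)` crosses zero at
#' `t = log(gamma0 / lambda) / eps` when `gamma0 > lambda > 0`; that time is
#' the unique volume minimum. When `gamma0 <= lambda` there is no shrinkage
#' phase and the minimum sits at `t = 0`; when `lambda = 0` with `gamma0 > 0`
#' the volume decreases forever and `Inf` is returned.
#'
#' @inheritParams growth_volume
#' @return Time of minimum volume in days (0, positive, or `Inf`).
#' @export
time_of_minimum <- function(lambda, gamma0, eps) {
  stopifnot(length(lambda) == length(gamma0), length(gamma0) == length(eps))
  out <- numeric(length(lambda))
  shrink <- gamma0 > lambda
  out[shrink & lambda == 0] <- Inf
  i <- shrink & lambda > 0
  out[i] <- log(gamma0[i] / lambda[i]) / eps[i]
  out[!shrink] <- 0
  out
}

#' Prior specification for the growth model
#'
#' Defaults: log-uniform `lambda` on `[1e-5, 0.05]` /day, uniform `gamma0` on
#' `[0, 0.2]` /day, log-uniform `eps` on `[1e-4, 0.1]` /day, and lognormal
#' `V_b` centred on the first observed volume with a 20% coefficient of
#' variation. `lambda_fixed` freezes the growth rate at a known value (used
#' for the cohort-shared growth-rate mode).
#'
#' @param lambda_range,gamma0_range,eps_range Numeric length-2 support bounds.
#' @param vb_center Centre of the `V_b` prior; defaults to the first observed
#'   volume at fit time.
#' @param vb_cv Coefficient of variation of the `V_b` prior.
#' @param lambda_fixed Optional fixed value for `lambda`.
#' @return A `growth_priors` list.
#' @export
growth_priors <- function(lambda_range = c(1e-5, 0.05),
                          gamma0_range = c(0, 0.2),
                          eps_range = c(1e-4, 0.1),
                          vb_center = NULL, vb_cv = 0.2,
                          lambda_fixed = NULL) {
  stopifnot(lambda_range[1] > 0, eps_range[1] > 0, vb_cv > 0)
  structure(
    list(lambda_range = lambda_range, gamma0_range = gamma0_range,
         eps_range = eps_range, vb_center = vb_center, vb_cv = vb_cv,
         lambda_fixed = lambda_fixed),
    class = "growth_priors"
  )
}

# Sampling happens on theta = (log lambda, gamma0, log eps, log V_b); with a
# fixed lambda the first coordinate is dropped. These helpers convert.
theta_to_params <- function(theta, priors) {
  if (!is.matrix(theta)) theta <- matrix(theta, nrow = 1)
  if (is.null(priors$lambda_fixed)) {
    cbind(lambda = exp(theta[, 1]), gamma0 = theta[, 2],
          eps = exp(theta[, 3]), V_b = exp(theta[, 4]))
  } else {
    cbind(lambda = rep(priors$lambda_fixed, nrow(theta)), gamma0 = theta[, 1],
          eps = exp(theta[, 2]), V_b = exp(theta[, 3]))
  }
}

# Vectorised log prior density on the sampling scale (rows of theta).
log_prior_theta <- function(theta, priors) {
  p <- theta_to_params(theta, priors)
  lp <- numeric(nrow(p))
  ok <- p[, "lambda"] >= priors$lambda_range[1] &
    p[, "lambda"] <= priors$lambda_range[2] &
    p[, "gamma0"] >= priors$gamma0_range[1] &
    p[, "gamma0"] <= priors$gamma0_range[2] &
    p[, "eps"] >= priors$eps_range[1] & p[, "eps"] <= priors$eps_range[2]
  lp[!ok] <- -Inf
  # log-uniform on lambda/eps is flat in log space; uniform gamma0 is flat;
  # V_b lognormal in natural scale = normal in log V_b.
  s <- cv_to_sdlog(priors$vb_cv)
  lvb <- if (is.null(priors$lambda_fixed)) theta[, 4] else theta[, 3]
  lp <- lp + stats::dnorm(lvb, mean = log(priors$vb_center), sd = s, log = TRUE)
  lp
}

#' Log posterior of the growth model
#'
#' Lognormal observation model: `log(V_obs) ~ Normal(log V(t), sigma)` with
#' `sigma = noise_cv` (10% measurement uncertainty by default), plus the log
#' prior. Vectorised over parameter rows. Exposed mainly for diagnostics and
#' testing; [fit_growth()] uses it internally.
#'
#' @param theta Parameter vector or matrix on the sampling scale
#'   `(log lambda, gamma0, log eps, log V_b)` (first coordinate dropped when
#'   `priors$lambda_fixed` is set).
#' @param t,v Observation times (days) and volumes (cm^3). May be empty for a
#'   prior-only density.
#' @param noise_cv Measurement coefficient of variation used as the lognormal
#'   sigma.
#' @param priors A [growth_priors()] with `vb_center` resolved.
#' @return Log posterior density per parameter row (`-Inf` outside support).
#' @export
growth_log_posterior <- function(theta, t, v, noise_cv, priors) {
  if (!is.matrix(theta)) theta <- matrix(theta, nrow = 1)
  if (any(v <= 0)) {
    stop_volresp("observed volumes must be positive", class = "invalid_measurement")
  }
  lp <- log_prior_theta(theta, priors)
  if (length(t) == 0) return(lp)
  p <- theta_to_params(theta, priors)
  finite <- which(is.finite(lp))
  if (length(finite) == 0) return(lp)
  pf <- p[finite, , drop = FALSE]
  # log V(t): rows = parameter draws, cols = observation times
  logV <- log(pf[, "V_b"]) + outer(pf[, "lambda"], t) -
    (pf[, "gamma0"] / pf[, "eps"]) * (1 - exp(-outer(pf[, "eps"], t)))
  resid <- sweep(logV, 2, log(v))
  ll <- -0.5 * rowSums((resid / noise_cv)^2) -
    length(t) * (log(noise_cv) + 0.5 * log(2 * pi))
  lp[finite] <- lp[finite] + ll
  lp
}

# Goodman-Weare affine-invariant ensemble sampler (stretch move), the
# standard ensemble MCMC for low-dimensional ODE-parameter posteriors. The
# ensemble is split in two halves updated alternately so proposals can be
# vectorised. log_post must accept a matrix of walker positions.
stretch_sampler <- function(log_post, init, n_steps, a = 2) {
  nw <- nrow(init); d <- ncol(init)
  stopifnot(nw >= 2 * d, nw %% 2 == 0)
  halves <- list(seq_len(nw / 2), seq_len(nw / 2) + nw / 2)
  cur <- init
  lp <- log_post(cur)
  if (!any(is.finite(lp))) {
    stop_volresp("no walker initialised inside the prior support",
                 class = "bad_initialisation")
  }
  chain <- array(NA_real_, c(n_steps, nw, d))
  n_acc <- 0L
  for (s in seq_len(n_steps)) {
    for (h in 1:2) {
      idx <- halves[[h]]; other <- halves[[3 - h]]
      m <- length(idx)
      z <- ((a - 1) * stats::runif(m) + 1)^2 / a
      j <- other[sample.int(length(other), m, replace = TRUE)]
      prop <- cur[j, , drop = FALSE] +
        z * (cur[idx, , drop = FALSE] - cur[j, , drop = FALSE])
      lp_prop <- log_post(prop)
      log_r <- (d - 1) * log(z) + lp_prop - lp[idx]
      acc <- log(stats::runif(m)) < log_r
      acc[!is.finite(lp_prop)] <- FALSE
      if (any(acc)) {
        cur[idx[acc], ] <- prop[acc, , drop = FALSE]
        lp[idx[acc]] <- lp_prop[acc]
        n_acc <- n_acc + sum(acc)
      }
    }
    chain[s, , ] <- cur
  }
  list(chain = chain, acceptance = n_acc / (n_steps * nw))
}

draw_from_prior <- function(n, priors) {
  lam <- exp(stats::runif(n, log(priors$lambda_range[1]),
                          log(priors$lambda_range[2])))
  g0 <- stats::runif(n, priors$gamma0_range[1], priors$gamma0_range[2])
  ep <- exp(stats::runif(n, log(priors$eps_range[1]), log(priors$eps_range[2])))
  s <- cv_to_sdlog(priors$vb_cv)
  vb <- stats::rlnorm(n, meanlog = log(priors$vb_center), sdlog = s)
  if (is.null(priors$lambda_fixed)) {
    cbind(log(lam), g0, log(ep), log(vb))
  } else {
    cbind(g0, log(ep), log(vb))
  }
}

#' Fit the growth model to a longitudinal volume series
#'
#' Samples the posterior of `(lambda, gamma0, eps, V_b)` under the lognormal
#' observation model with ensemble (affine-invariant stretch-move) MCMC. The
#' first half of every chain is discarded as burn-in. An acceptance fraction
#' outside `[0.1, 0.9]` is flagged (`convergence_ok = FALSE`) but not fatal.
#'
#' @param x A [participant_series] or numeric vector of observation times in
#'   days.
#' @param ... Passed to methods.
#' @return A `growth_fit` object: posterior `samples` (matrix with columns
#'   `lambda`, `gamma0`, `eps`, `V_b`), derived `t_vmin` and `v_min` samples,
#'   `acceptance`, `convergence_ok`, the data, and the settings used.
#' @seealso [bootstrap_refits()] to add measurement-noise bootstrapping,
#'   [classify_trajectory()] for the trajectory-based response label.
#' @export
fit_growth <- function(x, ...) UseMethod("fit_growth")

#' @rdname fit_growth
#' @param measure Measure fitted when `x` is a series (default solid volume).
#' @param t_max Optional cutoff: only images at `t <= t_max` enter the fit.
#' @export
fit_growth.participant_series <- function(x, measure = "solid_volume",
                                          t_max = Inf, ...) {
  img <- x$images
  keep <- !is.na(img[[measure]]) & img$t_days <= t_max
  fit <- fit_growth(img$t_days[keep], img[[measure]][keep], ...)
  fit$participant_id <- x$participant_id
  fit
}

#' @rdname fit_growth
#' @param v Observed volumes in cm^3 (same length as the time vector).
#' @param noise_cv Measurement coefficient of variation (lognormal sigma).
#' @param priors A [growth_priors()]; `vb_center` defaults to the first
#'   observed volume.
#' @param n_walkers Ensemble size (even, at least twice the dimension).
#' @param n_steps Steps per walker; the first half is burn-in.
#' @param seed Integer seed (sampler is fully reproducible).
#' @export
fit_growth.default <- function(x, v, noise_cv = 0.10,
                               priors = growth_priors(),
                               n_walkers = 32, n_steps = 2000,
                               seed = 1, ...) {
  t <- as.numeric(x)
  stopifnot(length(t) == length(v), noise_cv > 0)
  if (length(t) > 0 && any(v <= 0)) {
    stop_volresp("observed volumes must be positive", class = "invalid_measurement")
  }
  if (is.null(priors$vb_center)) {
    if (length(v) == 0) {
      stop_volresp("prior-only fit needs priors with vb_center set",
                   class = "invalid_input")
    }
    priors$vb_center <- v[order(t)][1]
  }
  set.seed(seed)
  init <- draw_from_prior(n_walkers, priors)
  res <- stretch_sampler(
    function(th) growth_log_posterior(th, t, v, noise_cv, priors),
    init, n_steps
  )
  burn <- seq_len(floor(n_steps / 2))
  post <- res$chain[-burn, , , drop = FALSE]
  theta <- matrix(post, ncol = dim(post)[3])
  samples <- theta_to_params(theta, priors)
  tv <- time_of_minimum(samples[, "lambda"], samples[, "gamma0"],
                        samples[, "eps"])
  vm <- ifelse(is.finite(tv),
               samples[, "V_b"] *
                 exp(samples[, "lambda"] * tv -
                       (samples[, "gamma0"] / samples[, "eps"]) *
                       (1 - exp(-samples[, "eps"] * tv))),
               0)
  structure(
    list(samples = samples, t_vmin = tv, v_min = vm,
         acceptance = res$acceptance,
         convergence_ok = res$acceptance >= 0.1 && res$acceptance <= 0.9,
         data = list(t = t, v = v), noise_cv = noise_cv, priors = priors,
         n_walkers = n_walkers, n_steps = n_steps, n_boot = 1L, seed = seed),
    class = "growth_fit"
  )
}

#' Measurement-noise bootstrap around the growth-model fit
#'
#' Refits the model to `n_boot` perturbed copies of the series (each observed
#' volume multiplied by an independent lognormal factor with coefficient of
#' variation `noise_cv`, mean 1) and pools the posteriors, propagating volume
#' measurement uncertainty in addition to fit uncertainty. Derived `t_vmin`
#' samples come from the pooled posterior.
#'
#' @inheritParams fit_growth.default
#' @param t Observation times in days.
#' @param n_boot Number of bootstrap refits (default 200).
#' @param perturb_cv Coefficient of variation of the bootstrap perturbation
#'   factors; defaults to `noise_cv` (the same 10% uncertainty enters the
#'   likelihood and the bootstrap). Setting it to 0 degenerates to repeated
#'   fits of the unperturbed data.
#' @param ... Further arguments passed to [fit_growth()] (priors, chain
#'   settings).
#' @return A pooled `growth_fit` with `n_boot` recorded.
#' @export
bootstrap_refits <- function(t, v, n_boot = 200, noise_cv = 0.10,
                             perturb_cv = noise_cv, seed = 1, ...) {
  if (inherits(t, "participant_series")) {
    stop_volresp("pass explicit time/volume vectors; see fit_growth for series",
                 class = "invalid_input")
  }
  stopifnot(n_boot >= 1)
  set.seed(seed)
  boot_seeds <- sample.int(.Machine$integer.max, n_boot)
  noise_seeds <- sample.int(.Machine$integer.max, n_boot)
  fits <- lapply(seq_len(n_boot), function(b) {
    set.seed(noise_seeds[b])
    vb <- v * rlnorm_cv(length(v), perturb_cv)
    fit_growth(t, vb, noise_cv = noise_cv, seed = boot_seeds[b], ...)
  })
  pooled <- fits[[1]]
  pooled$samples <- do.call(rbind, lapply(fits, `[[`, "samples"))
  pooled$t_vmin <- do.call(c, lapply(fits, `[[`, "t_vmin"))
  pooled$v_min <- do.call(c, lapply(fits, `[[`, "v_min"))
  pooled$acceptance <- mean(vapply(fits, `[[`, 0, "acceptance"))
  pooled$convergence_ok <- all(vapply(fits, `[[`, TRUE, "convergence_ok"))
  pooled$data <- list(t = t, v = v)
  pooled$n_boot <- as.integer(n_boot)
  pooled$seed <- seed
  pooled
}

#' @export
print.growth_fit <- function(x, ...) {
  cat("Growth-model fit")
  if (!is.null(x$participant_id)) cat(" for participant", x$participant_id)
  cat(":", length(x$data$t), "observations,",
      nrow(x$samples), "posterior draws")
  if (x$n_boot > 1) cat(" (pooled over", x$n_boot, "measurement bootstraps)")
  cat("\n")
  print(coef(x))
  cat(sprintf("t_Vmin median %.1f d (75th percentile %.1f d); acceptance %.2f%s\n",
              stats::median(x$t_vmin),
              stats::quantile(x$t_vmin, 0.75, names = FALSE),
              x$acceptance,
              if (x$convergence_ok) "" else " [convergence flag]"))
  invisible(x)
}

#' @export
coef.growth_fit <- function(object, ...) {
  apply(object$samples, 2, stats::median)
}

#' @export
summary.growth_fit <- function(object, probs = c(0.025, 0.25, 0.5, 0.75, 0.975),
                               ...) {
  qs <- t(apply(cbind(object$samples, t_vmin = object$t_vmin), 2,
                stats::quantile, probs = probs))
  structure(list(quantiles = qs, acceptance = object$acceptance,
                 n_draws = nrow(object$samples), n_boot = object$n_boot,
                 convergence_ok = object$convergence_ok),
            class = "summary.growth_fit")
}

#' @export
print.summary.growth_fit <- function(x, ...) {
  cat("Posterior quantiles (", x$n_draws, " draws, ",
      x$n_boot, " bootstrap refits):\n", sep = "")
  print(signif(x$quantiles, 4))
  cat(sprintf("Mean acceptance fraction: %.2f%s\n", x$acceptance,
              if (x$convergence_ok) "" else " [outside 0.1-0.9]"))
  invisible(x)
}

#' @export
predict.growth_fit <- function(object, t = NULL,
                               level = 0.95, ...) {
  t <- t %||% object$data$t
  s <- object$samples
  logV <- log(s[, "V_b"]) + outer(s[, "lambda"], t) -
    (s[, "gamma0"] / s[, "eps"]) * (1 - exp(-outer(s[, "eps"], t)))
  V <- exp(logV)
  a <- (1 - level) / 2
  data.frame(
    t_days = t,
    fit = apply(V, 2, stats::median),
    lwr = apply(V, 2, stats::quantile, a),
    upr = apply(V, 2, stats::quantile, 1 - a)
  )
}

#' @export
residuals.growth_fit <- function(object, ...) {
  p <- coef(object)
  fitted <- growth_volume(object$data$t, p["lambda"], p["gamma0"], p["eps"],
                          p["V_b"])
  log(object$data$v) - log(fitted)
}

#' @export
simulate.growth_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  idx <- sample.int(nrow(object$samples), nsim, replace = TRUE)
  t <- object$data$t
  out <- vapply(idx, function(i) {
    p <- object$samples[i, ]
    growth_volume(t, p["lambda"], p["gamma0"], p["eps"], p["V_b"]) *
      rlnorm_cv(length(t), object$noise_cv)
  }, numeric(length(t)))
  out <- as.data.frame(out)
  names(out) <- paste0("sim_", seq_len(nsim))
  attr(out, "seed") <- seed
  out
}

#' @export
plot.growth_fit <- function(x, n_grid = 200, level = 0.95, ...) {
  t_grid <- seq(min(0, x$data$t), max(x$data$t), length.out = n_grid)
  pr <- predict(x, t = t_grid, level = level)
  graphics::plot(x$data$t, x$data$v, xlab = "Days from treatment start",
                 ylab = expression(Volume ~ (cm^3)),
                 ylim = range(c(x$data$v, pr$lwr, pr$upr)), ...)
  graphics::polygon(c(pr$t_days, rev(pr$t_days)), c(pr$lwr, rev(pr$upr)),
                    col = grDevices::adjustcolor("steelblue", 0.25),
                    border = NA)
  graphics::lines(pr$t_days, pr$fit, col = "steelblue", lwd = 2)
  graphics::points(x$data$t, x$data$v, pch = 19)
  invisible(x)
}
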