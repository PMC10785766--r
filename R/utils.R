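# Internal helpers shared across modules.

# Lognormal parameterisation by coefficient of variation with unit mean.
# sdlog from CV: Var(X)/E(X)^2 = exp(sdlog^2) - 1.
cv_to_sdlog <- function(cv) sqrt(log(1 + cv^2))

# Multiplicative noise factors with mean 1 and coefficient of variation `cv`.
rlnorm_cv <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  s <- cv_to_sdlog(cv)
  stats::rlnorm(n, meanlog = -s^2 / 2, sdlog = s)
}

# Round a fraction to the nearest 5 percentage points, returned in percent.
round_pct_to_5 <- function(frac) 5 * round(100 * frac / 5)

`%||%` <- function(x, y) if (is.null(x)) y else x

# Ordered response labels shared by the criteria and concordance modules.
response_levels <- function() c("PR", "MinR", "SD", "PD")

response_factor <- function(x) {
  factor(as.character(x), levels = response_levels(), ordered = TRUE)
}

stop_volresp <- function(..., class) {
  stop(errorCondition(paste0(...), class = c(class, "volresp_error")))
}
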