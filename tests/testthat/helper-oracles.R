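# Independent oracles used across the suite.

# Brute-force OLS through explicitly assembled normal equations;
# deliberately avoids every fitting path of the package.
oracle_ols <- function(X, y) {
  drop(solve(t(X) %*% X, t(X) %*% y))
}

# Analytic mean of a truncated normal via numerical integration of the
# renormalized density (independent of the package's closed form).
oracle_truncnorm_mean <- function(mean, sd, lower, upper) {
  mass <- stats::integrate(function(x) stats::dnorm(x, mean, sd),
                           lower, upper)$value
  stats::integrate(function(x) x * stats::dnorm(x, mean, sd) / mass,
                   lower, upper)$value
}

# Sample skewness (method-of-moments).
sample_skewness <- function(x) {
  m <- mean(x)
  mean((x - m)^3) / (mean((x - m)^2))^1.5
}

# Closed-form large-sample expectations for the correlation study:
# standardized independent regressors give cor(age, risk) ->
# beta / sqrt(beta^2 + a1^2 + a2^2) and proportionate effect
# beta / (beta + a1 + a2).
closed_form_corr <- function(beta, a1, a2)
  ifelse(beta + a1 + a2 == 0, 0, beta / sqrt(beta^2 + a1^2 + a2^2))
closed_form_prop <- function(beta, a1, a2)
  ifelse(beta + a1 + a2 == 0, NA_real_, beta / (beta + a1 + a2))

# Construct vectors with an exact prescribed correlation to `x`.
with_exact_cor <- function(x, rho) {
  u <- scale(x)[, 1]
  v <- stats::residuals(stats::lm(stats::rnorm(length(x)) ~ u))
  v <- v / sqrt(sum(v^2) / (length(x) - 1))
  rho * u + sqrt(1 - rho^2) * v
}
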