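test_that("fixed-effects fits match the normal-equation oracle on tiny data", {
  set.seed(21)
  for (i in 1:5) {
    n <- sample(6:10, 1)
    d <- data.frame(outcome = rnorm(n), cohort = rnorm(n),
                    period = rnorm(n))
    risk <- rnorm(n)
    fit <- fit_rpc_ols(d, risk, standardize = FALSE)
    X <- cbind(1, risk, d$cohort, d$period)
    expect_equal(unname(fit$coefficients), unname(oracle_ols(X, d$outcome)),
                 tolerance = 1e-10)
    expect_false(fit$rank_deficient)
  }
})

test_that("rank-deficient designs get the minimum-norm solution", {
  set.seed(22)
  n <- 9
  d <- data.frame(outcome = rnorm(n), period = rnorm(n))
  d$cohort <- 2 * d$period          # exact dependency
  risk <- rnorm(n)
  fit <- fit_rpc_ols(d, risk, standardize = FALSE)
  expect_true(fit$rank_deficient)
  X <- cbind(1, risk, d$cohort, d$period)
  ginv_coef <- drop(MASS::ginv(X) %*% d$outcome)  # independent oracle
  expect_equal(unname(fit$coefficients), ginv_coef, tolerance = 1e-8)
  # minimum-norm solutions still reproduce the projection
  expect_equal(fit$fitted, drop(X %*% ginv_coef), tolerance = 1e-8)
})

test_that("identity outcome gives the pure-risk solution", {
  set.seed(23)
  n <- 200
  d <- data.frame(outcome = NA, cohort = rnorm(n), period = rnorm(n))
  risk <- rnorm(n)
  d$outcome <- risk
  fit <- fit_rpc_ols(d, risk, standardize = FALSE)
  expect_equal(unname(fit$coefficients),
               c(0, 1, 0, 0), tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
})

test_that("misaligned risk and empty factor levels are rejected", {
  d <- data.frame(outcome = rnorm(20), cohort = rep(1950:1954, 4),
                  period = rep(2000:2003, 5))
  expect_error(fit_rpc_ols(d, rnorm(10)), "does not match")
  f <- factor(rep("a", 20), levels = c("a", "b"))
  d$cohort <- f
  expect_error(fit_rpc_ols(d, rnorm(20), cohort_as = "categorical"),
               "empty level")
})

test_that("RPC recovers null cohort and period effects when risk is heterogeneous", {
  cond <- sim_condition(0.6, 0.4, 0.4, gamma = 0, n = 10000, seed = 24)
  d <- simulate_study2(cond)
  fit0 <- fit_risk_model(d, c("sep", "activity"), outcome = "outcome0")
  fit <- fit_rpc_ols(d, risk_index(fit0, d))
  expect_lt(abs(fit$coefficients["cohort"]), 4 * fit$se["cohort"])
  expect_lt(abs(fit$coefficients["period"]), 4 * fit$se["period"])
  expect_false(fit$rank_deficient)
})

test_that("fully categorical APC design raises the identification error", {
  set.seed(25)
  n <- 400
  period <- sample(2000:2005, n, TRUE)
  age <- sample(40:49, n, TRUE)
  d <- data.frame(outcome = rnorm(n), age = age, period = period,
                  cohort = period - age)
  expect_error(
    fit_apc_ols(d, variant = "categorical", age_as = "categorical"),
    "singular APC design")
  # binning the cohort (or dropping a level) breaks the dependency
  d$cohort_bin <- bin_cohorts(d$cohort, width = 5)
  fit <- fit_apc_ols(d, variant = "categorical", age_as = "numeric",
                     cohort = "cohort_bin")
  expect_s3_class(fit, "rpc_fit")
  expect_false(fit$rank_deficient)
  expect_error(
    fit_apc_ols(d, drop_levels = list(cohort = "not_a_level"),
                variant = "categorical", age_as = "categorical"),
    "absent level")
})

test_that("numeric APC fit recovers the study-2 generating slopes", {
  cond <- sim_condition(0.4, 0.2, 0.2, gamma = 0.6, n = 10000, seed = 26)
  d <- simulate_study2(cond)
  fit <- fit_apc_ols(d, variant = "numeric",
                     covariates = c("sep", "activity"))
  truth <- c(0.4, 0.2, 0.2, 0.6)
  est <- fit$coefficients[c("age", "sep", "activity", "cohort")]
  expect_true(all(abs(est - truth) < 4 * fit$se[names(est)]))
})

test_that("cohort bins carry the survey-table labels", {
  expect_equal(as.character(bin_cohorts(1947, origin = 1946)),
               "1946-1950")
  b <- bin_cohorts(c(1950, 1951), origin = 1946)
  expect_equal(as.character(b), c("1946-1950", "1951-1955"))
  # earliest narrower bin labelled by its start year
  b2 <- bin_cohorts(c(1921, 1923, 1927, 1931), width = 5, origin = 1926)
  expect_equal(as.character(b2), c("1921", "1921", "1926-1930",
                                   "1931-1935"))
  expect_equal(levels(b2), c("1921", "1926-1930", "1931-1935"))
  # unit bins are identity labels
  expect_equal(as.character(bin_cohorts(c(1947, 1950), width = 1)),
               c("1947", "1950"))
  expect_error(bin_cohorts(1947.5), "integer")
})

test_that("log1p transform is exact and reduces fixture skewness", {
  expect_equal(log1p_outcome(0), 0)
  expect_equal(log1p_outcome(exp(1) - 1), 1)
  expect_error(log1p_outcome(c(1, -0.5)), "non-negative")
  d <- simulate_nhanes_like(5000, seed = 27)
  expect_lt(sample_skewness(log1p_outcome(d$score)),
            sample_skewness(d$score))
})

# crossed-design generator for the mixed-model tests; the realized
# level effects are centered and rescaled so their sample variance is
# exactly the nominal component (with few levels, the realized variance
# of raw draws would itself be noisy and the estimand ill-defined)
fix_moments <- function(x, sd_target) {
  if (sd_target == 0) return(rep(0, length(x)))
  x <- x - mean(x)
  x * sd_target / sqrt(sum(x^2) / (length(x) - 1))
}
make_crossed <- function(n, J, K, sd_period, sd_cohort, sd_res, seed,
                         beta = 0.5) {
  set.seed(seed)
  period <- sample(seq_len(J), n, TRUE)
  cohort <- sample(seq_len(K), n, TRUE)
  tau <- fix_moments(rnorm(J), sd_period)
  lam <- fix_moments(rnorm(K), sd_cohort)
  risk <- rnorm(n)
  data.frame(outcome = 1 + beta * risk + tau[period] + lam[cohort] +
               rnorm(n, 0, sd_res),
             risk = risk, period = period, cohort = cohort,
             tau = tau[period], lam = lam[cohort])
}

test_that("REML recovers crossed variance components within 25%", {
  d <- make_crossed(10000, J = 6, K = 15, sd_period = 0.5,
                    sd_cohort = 1, sd_res = 1, seed = 28)
  fit <- fit_rpc_hapc(d, d$risk)
  vc <- fit$variance_components
  expect_lt(abs(vc["period"] - 0.25) / 0.25, 0.25)
  expect_lt(abs(vc["cohort"] - 1) / 1, 0.25)
  expect_lt(abs(vc["residual"] - 1) / 1, 0.25)
  expect_equal(unname(fit$fixed_slopes[".risk"]), 0.5, tolerance = 0.05)
  # shrinkage around zero
  expect_lt(abs(mean(fit$cohort_random_intercepts)), 0.3)
  expect_lt(abs(mean(fit$period_random_intercepts)), 0.3)
})

test_that("a null period component is estimated near zero", {
  d <- make_crossed(6000, J = 6, K = 10, sd_period = 0,
                    sd_cohort = 0.8, sd_res = 1, seed = 29)
  expect_true(all(d$tau == 0))
  fit <- fit_rpc_hapc(d, d$risk)
  expect_lt(fit$variance_components["period"], 0.02)
  expect_gt(fit$variance_components["cohort"], 0.2)
})

test_that("random intercepts are shrunken relative to dummy estimates", {
  d <- make_crossed(4000, J = 5, K = 8, sd_period = 0.4,
                    sd_cohort = 0.3, sd_res = 1.2, seed = 30)
  fit <- fit_rpc_hapc(d, d$risk)
  # unshrunken per-level estimates: centered level means of the
  # outcome after removing the fixed part (balanced-ish design)
  r <- d$outcome - fit$fixed_intercept -
    fit$fixed_slopes[".risk"] * d$risk
  dummy <- tapply(r, d$cohort, mean)
  dummy <- dummy - mean(dummy)
  blup <- fit$cohort_random_intercepts[as.character(seq_len(8))]
  expect_true(all(abs(blup) <= abs(dummy) + 0.05))
  expect_gt(cor(blup, dummy), 0.9)
})

test_that("single-level classification warns and fixes the component at 0", {
  d <- make_crossed(1000, J = 1, K = 6, sd_period = 0, sd_cohort = 0.5,
                    sd_res = 1, seed = 31)
  expect_warning(fit <- fit_rpc_hapc(d, d$risk), "single level")
  expect_equal(unname(fit$variance_components["period"]), 0)
  expect_length(fit$period_random_intercepts, 0)
})
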