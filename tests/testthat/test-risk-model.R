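test_that("noiseless linear outcome is recovered exactly", {
  set.seed(10)
  d <- data.frame(age = 30:79, sep = rnorm(50), activity = rpois(50, 1))
  d$outcome <- 3 * d$age
  fit <- fit_risk_model(d, c("sep", "activity"), standardize = FALSE)
  expect_equal(fit$age_slope, 3, tolerance = 1e-9)
  expect_equal(unname(fit$cov_slopes), c(0, 0), tolerance = 1e-9)
  expect_equal(fit$intercept, 0, tolerance = 1e-7)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
})

test_that("coefficients solve the normal equations (6-record oracle)", {
  d <- data.frame(outcome = c(2.1, -0.3, 4.5, 1.2, 0.7, 3.3),
                  age = c(31, 45, 62, 38, 51, 70),
                  sep = c(0.5, -1.2, 0.3, 1.8, -0.4, 0.9),
                  activity = c(0, 2, 1, 1, 3, 0))
  fit <- fit_risk_model(d, c("sep", "activity"), standardize = FALSE)
  X <- cbind(1, d$age, d$sep, d$activity)
  expect_equal(unname(coef(fit)), unname(oracle_ols(X, d$outcome)),
               tolerance = 1e-10)
})

test_that("OLS is consistent on the generating model", {
  d <- simulate_study1(sim_condition(1, 0.2, 0.2, n = 10000, seed = 11))
  fit <- fit_risk_model(d, c("sep", "activity"))
  se <- sqrt(diag(vcov(fit$lm)))[-1]
  est <- c(fit$age_slope, unname(fit$cov_slopes))
  expect_true(all(abs(est - c(1, 0.2, 0.2)) < 3 * se))
})

test_that("risk index is the fitted value of the risk model", {
  d <- simulate_study1(sim_condition(0.6, 0.4, 0.2, n = 2000, seed = 12))
  fit <- fit_risk_model(d, c("sep", "activity"))
  risk <- risk_index(fit, d)
  # fitted-value property of least squares
  expect_equal(cor(risk, d$outcome)^2, fit$r_squared, tolerance = 1e-10)
  expect_lte(var(risk), var(d$outcome))
  # residuals orthogonal to every design column
  res <- d$outcome - risk
  for (v in c("age", "sep", "activity"))
    expect_equal(sum(res * rpcohort:::zstd(d[[v]])), 0, tolerance = 1e-6)
  # identity mapping: a model whose only signal is age returns
  # (standardized) age itself
  d2 <- d
  d2$outcome <- rpcohort:::zstd(d$age)
  fit2 <- fit_risk_model(d2, c("sep", "activity"))
  expect_equal(risk_index(fit2, d2), rpcohort:::zstd(d2$age),
               tolerance = 1e-10)
  expect_error(risk_index(fit, d[c("outcome", "age")]), "sep")
})

test_that("risk model errors are explicit", {
  set.seed(13)
  d <- data.frame(outcome = rnorm(30), age = rnorm(30), sep = rnorm(30))
  d$dup <- 2 * d$sep
  expect_error(fit_risk_model(d, c("sep", "dup"), standardize = FALSE),
               "dup")
  expect_error(fit_risk_model(d[1:4, ], "sep"), "too few rows")
  expect_error(fit_risk_model(d, "missing_col"), "missing_col")
})

test_that("predicted-age index behaves across signal regimes", {
  set.seed(14)
  # pure-noise covariates: predictions collapse to the mean age
  d <- data.frame(age = sample(30:80, 400, TRUE), x1 = rnorm(400),
                  x2 = rnorm(400))
  pa <- predicted_age_index(d, c("x1", "x2"))
  expect_equal(unname(as.numeric(pa)), rep(mean(d$age), 400),
               tolerance = 0.15)
  # deterministic relation: reproduced exactly
  d$comorb <- rpois(400, 2)
  d$age_det <- 2 * d$comorb + 40
  pa2 <- predicted_age_index(d, "comorb", age = "age_det")
  expect_equal(as.numeric(pa2), d$age_det, tolerance = 1e-9)
  expect_equal(cor(as.numeric(pa2), d$age_det), 1, tolerance = 1e-12)
  expect_error(predicted_age_index(d, c("age", "x1")), "exclude")
})

test_that("predicted-age correlation on the fixture sits in the usable band", {
  d <- simulate_nhanes_like(10000, seed = 15)
  pa <- predicted_age_index(d, c("sex", "comorbidities", "race",
                                 "income_ratio", "social_support"))
  r <- cor(as.numeric(pa), d$age)
  expect_gt(r, 0.3)
  expect_lt(r, 0.7)   # comfortably below the 0.85 threshold
  dg <- diagnose(NULL, as.numeric(pa), d$age)
  expect_true(dg$admissible)
  expect_true(is.na(dg$proportionate_age_effect))
})

test_that("diagnostics implement the signed ratio and the rounding rule", {
  # risk affine in age: correlation 1, proportionate effect 1, flagged
  d <- simulate_study1(sim_condition(0.6, 0, 0, n = 500, seed = 16))
  d$outcome <- rpcohort:::zstd(d$age) * 0.6
  fit <- fit_risk_model(d, c("sep", "activity"))
  risk <- risk_index(fit, d)
  dg <- diagnose(fit, risk, d$age)
  expect_equal(dg$age_risk_correlation, 1, tolerance = 1e-9)
  expect_equal(dg$proportionate_age_effect, 1, tolerance = 1e-9)
  expect_false(dg$admissible)
  expect_equal(dg$collinearity_margin, 0, tolerance = 1e-9)

  # direct evaluation of the ratio with signed estimates
  fake <- fit
  fake$age_slope <- 0.2
  fake$cov_slopes <- c(sep = 0.2, activity = 0.6)
  dg2 <- diagnose(fake, risk, d$age)
  expect_equal(dg2$proportionate_age_effect, 0.2, tolerance = 1e-12)

  # rounding convention at the threshold: 0.8449 admissible, 0.8549 not
  set.seed(17)
  age <- rep(30:79, 4)
  r_lo <- with_exact_cor(age, 0.8449)
  r_hi <- with_exact_cor(age, 0.8549)
  expect_true(diagnose(fit, r_lo, age)$admissible)
  expect_false(diagnose(fit, r_hi, age)$admissible)

  # degenerate all-null pattern: computed, flagged unstable, no error
  d0 <- simulate_study1(sim_condition(0, 0, 0, n = 2000, seed = 18))
  f0 <- fit_risk_model(d0, c("sep", "activity"))
  dg0 <- diagnose(f0, risk_index(f0, d0), d0$age)
  expect_true(dg0$unstable)

  expect_error(diagnose(fit, risk, rep(50, length(risk))), "constant")
  expect_error(diagnose(fit, risk[1:10], d$age), "equal length")
})

test_that("correlation is affine invariant in the risk index", {
  set.seed(19)
  d <- simulate_study1(sim_condition(0.4, 0.2, 0.2, n = 1000, seed = 19))
  fit <- fit_risk_model(d, c("sep", "activity"))
  risk <- risk_index(fit, d)
  base <- cor(d$age, risk)
  for (a in c(2.5, -1.3, 0.01))
    expect_equal(cor(d$age, a * risk + 7), sign(a) * base,
                 tolerance = 1e-12)
})

test_that("risk models persist as structured text", {
  d <- simulate_study1(sim_condition(0.6, 0.2, 0.4, n = 500, seed = 20))
  fit <- fit_risk_model(d, c("sep", "activity"))
  path <- withr::local_tempfile(fileext = ".txt")
  write_risk_model(fit, path)
  back <- read_risk_model(path)
  expect_equal(back$coefficients, coef(fit), tolerance = 1e-12)
  expect_equal(back$r_squared, fit$r_squared, tolerance = 1e-12)
  expect_true(back$standardized)
  expect_equal(back$covariates, c("sep", "activity"))
})
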