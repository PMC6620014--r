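## Data generators for the two Monte Carlo study designs and the
## survey-like demonstration fixture.  All randomness is driven by a
## single seed per dataset with a fixed draw order (age, sep, activity,
## [period,] outcome noise[, baseline noise]), so identical conditions
## give bitwise-identical tables.

#' Truncated-normal draws by inverse CDF
#'
#' Samples from a normal distribution truncated to `[lower, upper]` by
#' mapping uniforms through the quantile function of the truncated
#' interval.  Unlike rejection sampling, the number of uniforms consumed
#' is exactly `n`, which keeps downstream draws reproducible for a given
#' seed regardless of the bounds.
#'
#' @param n number of draws.
#' @param mean,sd parameters of the parent normal.
#' @param lower,upper truncation bounds (finite, `lower < upper`).
#' @return numeric vector of length `n`, all within `[lower, upper]`.
#' @keywords internal
rtruncnorm_icdf <- function(n, mean, sd, lower, upper) {
  stopifnot(is.finite(lower), is.finite(upper), lower < upper, sd > 0)
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(plo + stats::runif(n) * (phi - plo), mean, sd)
}

## analytic mean of a truncated normal, used as a test oracle elsewhere
truncnorm_mean <- function(mean, sd, lower, upper) {
  a <- (lower - mean) / sd
  b <- (upper - mean) / sd
  mean + sd * (stats::dnorm(a) - stats::dnorm(b)) /
    (stats::pnorm(b) - stats::pnorm(a))
}

## in-sample standardization (denominator n - 1); the scale on which all
## simulated outcomes are generated
zstd <- function(x) {
  s <- stats::sd(x)
  if (s == 0) stop("cannot standardize a constant column", call. = FALSE)
  (x - mean(x)) / s
}

#' Specify one slope-parameter pattern for the simulation studies
#'
#' Bundles the generative slope parameters of one Monte Carlo condition:
#' `beta` (chronological age), `alpha1` (socioeconomic position, SEP),
#' `alpha2` (physical activity) and, for the design with cohort
#' structure, `gamma` (birth cohort).  Slopes are on the standardized
#' scale.  The full experimental designs draw each slope from
#' `c(0, 0.2, 0.4, 0.6, 0.8, 1)`; arbitrary non-negative values are
#' accepted for ad-hoc use unless `strict_grid` is set.
#'
#' @param beta age slope.
#' @param alpha1 SEP slope.
#' @param alpha2 activity slope.
#' @param gamma cohort slope, or `NULL` for the cross-sectional design.
#' @param n subjects per replication (at least 10).
#' @param seed integer RNG seed.
#' @param strict_grid if `TRUE`, require every slope to lie on the
#'   six-point design grid.
#' @return an object of class `"sim_condition"`.
#' @seealso [simulate_study1()], [simulate_study2()], [study_grid()]
#' @export
#' @examples
#' sim_condition(beta = 1, alpha1 = 0.2, alpha2 = 0.2, n = 1000, seed = 1)
sim_condition <- function(beta, alpha1, alpha2, gamma = NULL,
                          n = 10000, seed = 1, strict_grid = FALSE) {
  slopes <- c(beta = beta, alpha1 = alpha1, alpha2 = alpha2,
              if (!is.null(gamma)) c(gamma = gamma))
  if (!all(is.finite(slopes))) stop("slopes must be finite numbers")
  if (any(slopes < 0))
    stop("negative slopes are not part of the design", call. = FALSE)
  if (strict_grid && !all(vapply(slopes, function(s)
    any(abs(s - slope_grid()) < 1e-9), logical(1))))
    stop("strict_grid: slopes must come from c(0, 0.2, 0.4, 0.6, 0.8, 1)",
         call. = FALSE)
  if (!is.numeric(n) || length(n) != 1 || n < 10)
    stop("n must be a single number >= 10", call. = FALSE)
  structure(list(beta = beta, alpha1 = alpha1, alpha2 = alpha2,
                 gamma = gamma, n = as.integer(n),
                 seed = as.integer(seed)),
            class = "sim_condition")
}

slope_grid <- function() c(0, 0.2, 0.4, 0.6, 0.8, 1)

#' @export
print.sim_condition <- function(x, ...) {
  cat("Simulation condition: beta =", x$beta, " alpha1 =", x$alpha1,
      " alpha2 =", x$alpha2,
      if (!is.null(x$gamma)) paste(" gamma =", x$gamma), "\n")
  cat("  n =", x$n, "  seed =", x$seed, "\n")
  invisible(x)
}

## Shared covariate draws.  Draw order is part of the reproducibility
## contract: age, sep, activity, (period,) outcome noise, (baseline noise).
draw_covariates <- function(n, with_period) {
  age <- round(rtruncnorm_icdf(n, 55, 25, 30, 80))
  sep <- stats::rnorm(n)
  activity <- stats::rpois(n, 1)
  period <- if (with_period) rtruncnorm_icdf(n, 1980, 30, 1950, 2010) else NULL
  list(age = age, sep = sep, activity = activity, period = period)
}

#' Simulate one cross-sectional dataset for the correlation study
#'
#' Generates `cond$n` subjects with chronological age from a rounded
#' truncated normal (mean 55, sd 25, bounds 30 and 80), standard-normal
#' SEP, Poisson(1) activity, and a continuous baseline outcome
#' \deqn{Y^0_i = \beta\,\tilde{age}_i + \alpha_1\,\tilde{sep}_i +
#'   \alpha_2\,\tilde{act}_i + \varepsilon_i,\qquad
#'   \varepsilon_i \sim N(0,1),}
#' where the tilde denotes in-sample standardization (mean 0, variance 1
#' within the generated sample); the intercept is 0.  The raw covariate
#' columns are returned; standardization is repeated, deterministically,
#' wherever the outcome scale is needed.
#'
#' @param cond a [sim_condition()] without `gamma`.
#' @return a `data.frame` with columns `outcome`, `age`, `sep`,
#'   `activity` and the condition attached as attribute `"condition"`.
#' @export
#' @examples
#' d <- simulate_study1(sim_condition(1, 0.2, 0.2, n = 500, seed = 7))
#' range(d$age)  # within [30, 80]
simulate_study1 <- function(cond) {
  stopifnot(inherits(cond, "sim_condition"))
  if (!is.null(cond$gamma))
    stop("condition has a cohort slope; use simulate_study2()", call. = FALSE)
  set.seed(cond$seed)
  cv <- draw_covariates(cond$n, with_period = FALSE)
  eps <- stats::rnorm(cond$n)
  outcome <- cond$beta * zstd(cv$age) + cond$alpha1 * zstd(cv$sep) +
    cond$alpha2 * zstd(cv$activity) + eps
  structure(data.frame(outcome = outcome, age = cv$age, sep = cv$sep,
                       activity = cv$activity),
            condition = cond)
}

#' Simulate one dataset with cohort structure for the recovery study
#'
#' As [simulate_study1()], plus a survey period from a truncated normal
#' (mean 1980, sd 30, bounds 1950 and 2010) and a birth cohort defined
#' exactly as `period - age` per record.  The current outcome follows
#' \deqn{Y_i = \beta\,\tilde{age}_i + \alpha_1\,\tilde{sep}_i +
#'   \alpha_2\,\tilde{act}_i + \Gamma\,\tilde{cohort}_i + \varepsilon_i,}
#' with no period effect.  A baseline outcome `outcome0` — the same
#' linear predictor without the cohort term and with an independent
#' standard-normal noise draw — is also returned; it is the default
#' training response for the internal risk model in the recovery
#' experiments.
#'
#' @param cond a [sim_condition()] with `gamma` set.
#' @return a `data.frame` with columns `outcome`, `outcome0`, `age`,
#'   `sep`, `activity`, `period`, `cohort`.
#' @export
simulate_study2 <- function(cond) {
  stopifnot(inherits(cond, "sim_condition"))
  if (is.null(cond$gamma))
    stop("condition needs a cohort slope gamma; see sim_condition()",
         call. = FALSE)
  set.seed(cond$seed)
  cv <- draw_covariates(cond$n, with_period = TRUE)
  eps <- stats::rnorm(cond$n)
  eps0 <- stats::rnorm(cond$n)
  cohort <- cv$period - cv$age
  lp <- cond$beta * zstd(cv$age) + cond$alpha1 * zstd(cv$sep) +
    cond$alpha2 * zstd(cv$activity)
  structure(data.frame(outcome = lp + cond$gamma * zstd(cohort) + eps,
                       outcome0 = lp + eps0,
                       age = cv$age, sep = cv$sep, activity = cv$activity,
                       period = cv$period, cohort = cohort),
            condition = cond)
}

#' Simulate a survey-like panel with a skewed bounded score
#'
#' Generates a synthetic cross-sectional survey panel patterned after a
#' repeated depression-screening design: six two-year survey periods
#' (2006 to 2016), a 0-27 integer questionnaire total score with strong
#' right skew (most subjects score 4 or less), and demographic
#' covariates — sex, comorbidity count (0-11), a four-level
#' race/ethnicity factor, family income-to-poverty ratio, and a binary
#' social-support indicator — that jointly predict chronological age
#' with a moderate coefficient of determination (about 0.23, so the
#' predicted-age risk index correlates with age at roughly 0.48).
#'
#' The score is generated on the log(score + 1) scale as a Gaussian
#' linear predictor, exponentiated, shifted, rounded and clipped to
#' `[0, 27]`.  On that scale an additive linear birth-cohort trend of
#' `cohort_trend` per decade and the six additive `period_effects` are
#' injected; the full set of generative parameters is recorded in the
#' `"generator"` attribute so that recovery can be tested.  This is a
#' synthetic fixture: it emulates the marginal shapes above and nothing
#' else (no survey weights, no missingness, no real response process).
#'
#' @param n number of subjects (at least 100).
#' @param seed integer RNG seed.
#' @param cohort_trend linear birth-cohort trend on the log(score + 1)
#'   scale, per decade of birth year.
#' @param period_effects numeric vector of length 6: additive effects of
#'   the periods 2006, 2008, ..., 2016 on the log(score + 1) scale
#'   (first entry is the reference and is conventionally 0).
#' @return a `data.frame` with columns `score`, `age`, `period`,
#'   `cohort`, `sex`, `comorbidities`, `race`, `income_ratio`,
#'   `social_support`.
#' @export
#' @examples
#' d <- simulate_nhanes_like(2000, seed = 1)
#' mean(d$score <= 4)  # majority of subjects
simulate_nhanes_like <- function(n, seed = 1, cohort_trend = 0.3,
                                 period_effects = c(0, 0.11, 0.10,
                                                    0.03, 0.05, 0.05)) {
  if (!is.numeric(n) || length(n) != 1 || n < 100)
    stop("n must be a single number >= 100", call. = FALSE)
  if (length(period_effects) != 6)
    stop("period_effects must have length 6 (periods 2006..2016)",
         call. = FALSE)
  set.seed(as.integer(seed))
  periods <- seq(2006, 2016, by = 2)
  period <- sample(periods, n, replace = TRUE)
  age <- round(rtruncnorm_icdf(n, 47, 20, 18, 85))
  cohort <- period - age

  sex <- stats::rbinom(n, 1, 0.515)                       # 1 = female
  comorbidities <- pmin(stats::rpois(n, exp(-2.6 + 0.042 * age)), 11L)
  race <- factor(sample(c("Hispanic", "NH White", "NH Black", "Other"),
                        n, replace = TRUE,
                        prob = c(0.25, 0.47, 0.18, 0.10)),
                 levels = c("Hispanic", "NH White", "NH Black", "Other"))
  income_ratio <- pmin(pmax(stats::rnorm(n, 1.9 + 0.011 * age, 1.45), 0), 5)
  social_support <- stats::rbinom(n, 1, stats::plogis(-0.9 + 0.022 * age))

  ## log(score + 1) scale: covariate-driven risk, injected cohort trend
  ## (per decade, anchored at 1921) and additive period effects
  b <- c(intercept = 0.35, comorbidities = 0.12, support = -0.18,
         income = -0.07, sex = 0.14)
  eta <- b["intercept"] + b["comorbidities"] * comorbidities +
    b["support"] * social_support + b["income"] * income_ratio +
    b["sex"] * sex +
    cohort_trend * (cohort - 1921) / 10 +
    period_effects[match(period, periods)] +
    stats::rnorm(n, 0, 0.85)
  score <- as.integer(pmin(pmax(round(exp(eta) - 1), 0), 27))

  structure(data.frame(score = score, age = age, period = period,
                       cohort = cohort, sex = sex,
                       comorbidities = comorbidities, race = race,
                       income_ratio = income_ratio,
                       social_support = social_support),
            generator = list(n = n, seed = as.integer(seed),
                             cohort_trend = cohort_trend,
                             cohort_origin = 1921,
                             period_effects = period_effects,
                             periods = periods,
                             score_coefficients = b,
                             noise_sd = 0.85))
}
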