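## The user-facing model: a two-stage risk-period-cohort fit behind a
## single formula interface, returning a classed object with the usual
## accessor methods.

#' Fit a risk-period-cohort model
#'
#' One-call interface to the full RPC pipeline.  The formula names the
#' outcome on the left and the risk-model covariates on the right, e.g.
#' `score ~ sex + comorbidities + race`; chronological age, period and
#' cohort are taken from the named columns of `data`.  The pipeline:
#'
#' 1. builds the age-related risk index — either the fitted values of
#'    an internal regression of the (optionally log(x+1)-transformed)
#'    outcome on age plus the covariates (`index = "outcome"`), or the
#'    predicted chronological age from a regression of age on the
#'    covariates (`index = "age"`);
#' 2. checks admissibility: the absolute age-risk correlation, rounded
#'    to two decimals, must stay below `threshold` for the second stage
#'    to be free of the age-period-cohort collinearity (a violation is
#'    reported, not fatal);
#' 3. regresses the outcome on risk, cohort and period — by OLS with
#'    cohort and period either as standardized numeric trends or as
#'    categorical terms (cohort binned into `cohort_width`-year groups,
#'    first period and earliest cohort as references), or by a
#'    cross-classified mixed model with random period and cohort
#'    intercepts (`method = "mixed"`).
#'
#' @param formula outcome ~ risk covariates.
#' @param data data frame with the outcome, covariates, age, period and
#'   cohort columns.
#' @param index `"outcome"` (internal risk model) or `"age"`
#'   (predicted chronological age).
#' @param method `"ols"` or `"mixed"`.
#' @param age,period,cohort column names.
#' @param cohort_as,period_as `"categorical"` or `"numeric"` (OLS
#'   only).
#' @param cohort_width,cohort_origin cohort binning, see
#'   [bin_cohorts()].
#' @param log_score apply [log1p_outcome()] to the outcome before
#'   modelling.
#' @param threshold admissibility threshold for the age-risk
#'   correlation.
#' @param standardize standardize regressors in the risk model and the
#'   numeric second stage (the simulation-study convention; defaults on
#'   for `index = "outcome"`).
#' @return an object of class `"rpc"` with components `risk_model`,
#'   `risk` (the index), `diagnostics`, `fit` (an `"rpc_fit"` or
#'   `"hapc_fit"`), and the resolved configuration; supports `print`,
#'   `summary`, `coef`, `fitted`, `residuals`, `predict` and `plot`.
#' @seealso [fit_risk_model()], [fit_rpc_ols()], [fit_rpc_hapc()]
#' @export
#' @examples
#' d <- simulate_nhanes_like(3000, seed = 11)
#' m <- rpc(score ~ sex + comorbidities + race + income_ratio +
#'            social_support,
#'          data = d, index = "age", log_score = TRUE,
#'          cohort_origin = 1926)
#' m
rpc <- function(formula, data, index = c("outcome", "age"),
                method = c("ols", "mixed"),
                age = "age", period = "period", cohort = "cohort",
                cohort_as = c("categorical", "numeric"),
                period_as = c("categorical", "numeric"),
                cohort_width = 5, cohort_origin = NULL,
                log_score = FALSE, threshold = 0.85,
                standardize = NULL) {
  index <- match.arg(index)
  method <- match.arg(method)
  cohort_as <- match.arg(cohort_as)
  period_as <- match.arg(period_as)
  if (is.null(standardize)) standardize <- index == "outcome"
  outcome <- all.vars(formula[[2]])
  covs <- labels(stats::terms(formula, data = data))
  missing_cols <- setdiff(c(outcome, covs, age, period, cohort),
                          names(data))
  if (length(missing_cols))
    stop("column(s) not found: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)

  work <- data
  work$.y <- if (log_score) log1p_outcome(data[[outcome]])
             else data[[outcome]]

  if (index == "outcome") {
    rm_fit <- fit_risk_model(work, covs, outcome = ".y", age = age,
                             standardize = standardize)
    risk <- risk_index(rm_fit, work)
    diag_ <- diagnose(rm_fit, risk, work[[age]], threshold = threshold)
  } else {
    risk <- predicted_age_index(work, covs, age = age)
    rm_fit <- attr(risk, "model")
    risk <- as.numeric(risk)
    diag_ <- diagnose(NULL, risk, work[[age]], threshold = threshold)
  }

  cohort_col <- if (cohort_as == "categorical")
    bin_cohorts(work[[cohort]], width = cohort_width,
                origin = cohort_origin)
  else work[[cohort]]
  second <- data.frame(.y = work$.y, .cohort = cohort_col,
                       .period = work[[period]], .age = work[[age]])

  fit <- if (method == "ols") {
    fit_rpc_ols(second, risk, cohort_as = cohort_as,
                period_as = period_as, outcome = ".y",
                cohort = ".cohort", period = ".period",
                standardize = standardize)
  } else {
    fit_rpc_hapc(second, risk, outcome = ".y", period = ".period",
                 cohort = ".cohort")
  }

  structure(list(risk_model = rm_fit, risk = risk,
                 age_values = work[[age]], diagnostics = diag_,
                 fit = fit, index = index, method = method,
                 outcome = outcome, covariates = covs,
                 age = age, period = period, cohort = cohort,
                 cohort_as = cohort_as, period_as = period_as,
                 cohort_width = cohort_width,
                 cohort_origin = cohort_origin,
                 cohort_levels = if (is.factor(cohort_col))
                   levels(cohort_col),
                 period_levels = if (period_as == "categorical")
                   levels(factor(work[[period]])),
                 log_score = log_score, standardize = standardize,
                 n = nrow(data), call = match.call()),
            class = "rpc")
}

#' @export
print.rpc <- function(x, digits = 3, ...) {
  cat("Risk-period-cohort model: ", x$outcome,
      if (x$log_score) " (log(x+1) scale)", " on ",
      if (x$index == "outcome") "outcome-scale risk index"
      else "predicted chronological age", " + cohort + period\n",
      sep = "")
  cat("n = ", x$n, ", cor(age, risk) = ",
      round(x$diagnostics$age_risk_correlation, digits),
      if (!x$diagnostics$admissible) "  [above admissibility threshold]",
      "\n\n", sep = "")
  print(x$fit, digits = digits)
  invisible(x)
}

#' @export
summary.rpc <- function(object, ...) {
  structure(object, class = c("summary.rpc", "rpc"))
}

#' @export
print.summary.rpc <- function(x, digits = 3, ...) {
  cat("== Risk model ==\n")
  if (inherits(x$risk_model, "risk_model")) print(x$risk_model, digits)
  else print(summary(x$risk_model))
  cat("\n== Diagnostics ==\n")
  print(x$diagnostics, digits)
  cat("\n== Period-cohort stage ==\n")
  print(x$fit, digits = digits)
  invisible(x)
}

#' @export
coef.rpc <- function(object, ...) {
  if (inherits(object$fit, "rpc_fit")) object$fit$coefficients
  else c("(Intercept)" = object$fit$fixed_intercept,
         object$fit$fixed_slopes)
}

#' @export
fitted.rpc <- function(object, ...) {
  if (inherits(object$fit, "rpc_fit")) object$fit$fitted
  else stats::fitted(object$fit$lmer)
}

#' @export
residuals.rpc <- function(object, ...) {
  if (inherits(object$fit, "rpc_fit")) object$fit$residuals
  else stats::residuals(object$fit$lmer)
}

#' Predict from a fitted risk-period-cohort model
#'
#' Rebuilds the risk index for `newdata` from the stored first-stage
#' model, then evaluates the second stage on the model's outcome scale
#' (log(x+1) if the model was fitted with `log_score`).
#'
#' @param object an `"rpc"` fit.
#' @param newdata data frame with the covariate, age, period and cohort
#'   columns.
#' @param ... unused.
#' @return numeric vector of predictions.
#' @export
predict.rpc <- function(object, newdata, ...) {
  if (missing(newdata)) return(fitted(object))
  risk <- if (object$index == "outcome")
    risk_index(object$risk_model, newdata)
  else unname(stats::predict(object$risk_model, newdata = newdata))
  second <- data.frame(
    .cohort = if (object$cohort_as == "categorical")
      factor(as.character(bin_cohorts(newdata[[object$cohort]],
                                      object$cohort_width,
                                      object$cohort_origin)),
             levels = object$cohort_levels)
    else newdata[[object$cohort]],
    .period = if (object$period_as == "categorical")
      factor(as.character(newdata[[object$period]]),
             levels = object$period_levels)
    else newdata[[object$period]])
  if (anyNA(second$.cohort) || anyNA(second$.period))
    stop("newdata contains cohort/period levels unseen at fit time",
         call. = FALSE)
  if (object$method == "mixed") {
    df <- second
    df$.risk <- risk
    return(unname(stats::predict(object$fit$lmer, newdata = df,
                                 allow.new.levels = FALSE)))
  }
  cf <- object$fit$coefficients
  pred <- rep(cf[["(Intercept)"]], nrow(second)) + cf[["risk"]] * risk
  add_part <- function(x, as_what, what) {
    if (as_what == "numeric") {
      pred <<- pred + cf[[what]] * x
    } else {
      nm <- paste0(what, as.character(x))
      hit <- nm %in% names(cf)
      pred <<- pred + ifelse(hit, cf[nm], 0)
    }
  }
  ## numeric second stages in rpc() are only fitted unstandardized when
  ## standardize = FALSE; refuse the ambiguous case
  if (object$standardize &&
      (object$cohort_as == "numeric" || object$period_as == "numeric"))
    stop("predict() is not defined for standardized numeric second ",
         "stages; refit with standardize = FALSE", call. = FALSE)
  add_part(second$.cohort, object$cohort_as, ".cohort")
  add_part(second$.period, object$period_as, ".period")
  unname(pred)
}

#' Plot method for risk-period-cohort fits
#'
#' With a categorical cohort stage, draws the estimated cohort
#' coefficients (with approximate 95 percent intervals for OLS fits, or
#' the random-intercept modes for mixed fits) against birth-cohort bin
#' order — the cohort-trend picture.  Otherwise draws the risk index
#' against chronological age with the admissibility correlation in the
#' title.
#'
#' @param x an `"rpc"` fit.
#' @param ... passed to the underlying plotting calls.
#' @export
plot.rpc <- function(x, ...) {
  if (x$cohort_as == "categorical" || x$method == "mixed") {
    if (x$method == "mixed") {
      est <- x$fit$cohort_random_intercepts
      se <- NULL
      lab <- names(est)
    } else {
      nm <- grep("^\\.cohort", names(x$fit$coefficients), value = TRUE)
      est <- x$fit$coefficients[nm]
      se <- x$fit$se[nm]
      lab <- sub("^\\.cohort", "", nm)
    }
    idx <- seq_along(est)
    ylim <- if (is.null(se)) range(est)
            else range(est - 1.96 * se, est + 1.96 * se)
    graphics::plot(idx, est, xaxt = "n", xlab = "birth cohort",
                   ylab = "cohort effect", ylim = ylim,
                   main = "Cohort trend", pch = 19, ...)
    graphics::axis(1, at = idx, labels = lab, las = 2, cex.axis = 0.7)
    if (!is.null(se))
      graphics::segments(idx, est - 1.96 * se, idx, est + 1.96 * se)
    graphics::abline(h = 0, lty = 3)
  } else {
    graphics::plot(x$age_values, x$risk, ...,
                   xlab = "chronological age", ylab = "age-related risk",
                   main = sprintf("cor(age, risk) = %.2f",
                                  x$diagnostics$age_risk_correlation))
  }
  invisible(x)
}
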