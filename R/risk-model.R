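## Internal risk model: OLS of a baseline outcome on chronological age
## plus covariates.  Its fitted values are the age-related risk index
## that replaces chronological age in the period-cohort regression.

#' Fit the internal risk model
#'
#' Ordinary least squares of a baseline outcome on chronological age and
#' a user-chosen set of covariates:
#' \deqn{Y^0_i = \mu + \beta\,age_i + \alpha^T X_i + \varepsilon_i.}
#' When `standardize = TRUE` (the convention of the simulation studies)
#' every numeric regressor is z-scored in-sample before fitting, so the
#' coefficients are on the standardized scale; the centers and scales
#' are stored and re-applied to new data by [risk_index()].  Factor
#' covariates are expanded through treatment contrasts and left
#' unscaled.
#'
#' The covariate list is taken as given: correct specification of the
#' risk model (no omitted confounding risk factors, appropriate scales)
#' is the analyst's responsibility and is not checked here.
#'
#' @param data a data frame containing `outcome`, `age` and the
#'   covariates.
#' @param covariates character vector of covariate column names.
#' @param outcome,age names of the outcome and age columns.
#' @param standardize z-score numeric regressors in-sample before
#'   fitting.
#' @return an object of class `"risk_model"` with components
#'   `intercept`, `age_slope`, `cov_slopes` (named vector over the
#'   expanded design), `residual_variance`, `r_squared`, `design_spec`,
#'   `standardized`, plus the underlying `lm` fit and the scaling used.
#' @seealso [risk_index()], [diagnose()], [predicted_age_index()]
#' @export
#' @examples
#' d <- simulate_study1(sim_condition(1, 0.2, 0.2, n = 2000, seed = 1))
#' fit <- fit_risk_model(d, covariates = c("sep", "activity"))
#' coef(fit)
fit_risk_model <- function(data, covariates, outcome = "outcome",
                           age = "age", standardize = TRUE) {
  vars <- c(outcome, age, covariates)
  missing_cols <- setdiff(vars, names(data))
  if (length(missing_cols))
    stop("column(s) not found in data: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  df <- data[vars]
  if (anyNA(df)) stop("risk model data contain missing values",
                      call. = FALSE)
  regressors <- c(age, covariates)
  num <- regressors[vapply(df[regressors], is.numeric, logical(1))]
  centers <- scales <- stats::setNames(numeric(0), character(0))
  if (standardize && length(num)) {
    centers <- vapply(df[num], mean, numeric(1))
    scales <- vapply(df[num], stats::sd, numeric(1))
    if (any(scales == 0))
      stop("cannot standardize constant column(s): ",
           paste(num[scales == 0], collapse = ", "), call. = FALSE)
    df[num] <- Map(function(x, m, s) (x - m) / s, df[num],
                   centers, scales)
  }
  if (nrow(df) <= length(regressors) + 2)
    stop("too few rows (", nrow(df), ") to fit ",
         length(regressors), " regressors", call. = FALSE)

  form <- stats::reformulate(regressors, response = outcome)
  mm <- stats::model.matrix(form, df)
  qr_mm <- qr(mm)
  if (qr_mm$rank < ncol(mm)) {
    dropped <- colnames(mm)[qr_mm$pivot[(qr_mm$rank + 1):ncol(mm)]]
    stop("rank-deficient risk-model design; linearly dependent column(s): ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }
  lmfit <- stats::lm(form, df)
  ## noiseless inputs are legitimate here (exact-recovery checks);
  ## silence the perfect-fit note summary() would emit for them
  lmsum <- suppressWarnings(summary(lmfit))
  cf <- stats::coef(lmfit)
  age_pos <- match(age, names(cf))
  structure(list(
    intercept = unname(cf[1]),
    age_slope = unname(cf[age_pos]),
    cov_slopes = cf[-c(1, age_pos)],
    residual_variance = lmsum$sigma^2,
    r_squared = lmsum$r.squared,
    design_spec = covariates,
    standardized = standardize,
    outcome = outcome, age = age,
    centers = centers, scales = scales,
    lm = lmfit
  ), class = "risk_model")
}

#' @export
print.risk_model <- function(x, digits = 4, ...) {
  cat("Internal risk model (",
      if (x$standardized) "standardized" else "raw", " scale)\n", sep = "")
  cat("  ", x$outcome, " ~ ", x$age, " + ",
      paste(x$design_spec, collapse = " + "), "\n", sep = "")
  print(round(coef(x), digits))
  cat("R-squared:", round(x$r_squared, digits),
      "  residual variance:", round(x$residual_variance, digits), "\n")
  invisible(x)
}

#' @export
coef.risk_model <- function(object, ...) {
  c("(Intercept)" = object$intercept,
    stats::setNames(object$age_slope, object$age),
    object$cov_slopes)
}

#' Compute the age-related risk index
#'
#' Evaluates the fitted values of a risk model for each record of
#' `data`: \eqn{Risk_i = \hat\mu + \hat\beta\,age_i + \hat\alpha^T X_i}.
#' New data are placed on the model's fitting scale first (the training
#' centers and scales are re-applied when the model was standardized).
#'
#' @param fit a [fit_risk_model()] object.
#' @param data a data frame containing every column of the model's
#'   design.
#' @return numeric vector of risk-index values, one per row of `data`.
#' @export
risk_index <- function(fit, data) {
  stopifnot(inherits(fit, "risk_model"))
  needed <- c(fit$age, fit$design_spec)
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols))
    stop("risk_index: column(s) missing from data: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  df <- data[needed]
  for (v in names(fit$centers))
    df[[v]] <- (df[[v]] - fit$centers[[v]]) / fit$scales[[v]]
  unname(stats::predict(fit$lm, newdata = df))
}

#' Predicted chronological age as the risk index
#'
#' The predicted-age variant of age-related risk: OLS of chronological
#' age on the covariates (age itself excluded), returning the fitted
#' ages.  The index is on the age scale, which makes it directly
#' interpretable, at the price of being defined independently of any
#' outcome.
#'
#' @param data a data frame with the age column and the covariates.
#' @param covariates character vector of covariate names; must not
#'   include the age column.
#' @param age name of the age column.
#' @return numeric vector of predicted ages (same units as age), with
#'   the underlying model attached as attribute `"model"` (an `lm`).
#' @export
#' @examples
#' d <- simulate_nhanes_like(1000, seed = 3)
#' pa <- predicted_age_index(d, c("sex", "comorbidities", "race",
#'                                "income_ratio", "social_support"))
#' cor(pa, d$age)
predicted_age_index <- function(data, covariates, age = "age") {
  if (age %in% covariates)
    stop("covariates must exclude the age column", call. = FALSE)
  missing_cols <- setdiff(c(age, covariates), names(data))
  if (length(missing_cols))
    stop("column(s) not found in data: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  df <- data[c(age, covariates)]
  if (anyNA(df)) stop("predicted-age data contain missing values",
                      call. = FALSE)
  if (nrow(df) <= length(covariates) + 2)
    stop("too few rows to fit the predicted-age model", call. = FALSE)
  form <- stats::reformulate(covariates, response = age)
  mm <- stats::model.matrix(form, df)
  qr_mm <- qr(mm)
  if (qr_mm$rank < ncol(mm)) {
    dropped <- colnames(mm)[qr_mm$pivot[(qr_mm$rank + 1):ncol(mm)]]
    stop("rank-deficient predicted-age design; dependent column(s): ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }
  lmfit <- stats::lm(form, df)
  structure(unname(stats::fitted(lmfit)), model = lmfit)
}

#' Admissibility diagnostics for an age-related risk index
#'
#' Computes the Pearson correlation between chronological age and the
#' risk index, the collinearity margin `1 - |correlation|`, and the
#' proportionate chronological age effect
#' \deqn{\hat\beta / (\hat\beta + \textstyle\sum_j \hat\alpha_j),}
#' the share of the risk model attributable to the age slope, using
#' signed estimates (small negative covariate slopes can push the ratio
#' above 1).  A risk index is admissible for period-cohort modelling
#' when the absolute correlation, rounded to `rounding_decimals`
#' decimals, is strictly below `threshold` (default 0.85); at or above
#' the rounded threshold the risk-period-cohort design approaches the
#' collinear system the method is meant to avoid.
#'
#' If the denominator of the proportionate effect is within machine
#' tolerance of zero it is reported as `NA` (undefined), not a number.
#' When the risk model is statistically indistinguishable from noise
#' (overall F-test p-value above 0.05) the diagnostics are still
#' computed but flagged `unstable`: with no real signal, both the
#' correlation and the proportionate effect are ratios of pure noise.
#'
#' @param fit the [fit_risk_model()] object (source of the slope
#'   estimates), or `NULL` for an index whose construction has no age
#'   slope (e.g. predicted chronological age): correlation and
#'   admissibility are then computed, the proportionate effect is
#'   `NA`.
#' @param risk numeric risk-index vector.
#' @param age chronological age vector, same length as `risk`.
#' @param threshold admissibility threshold on the absolute age-risk
#'   correlation.
#' @param rounding_decimals decimals used in the threshold comparison.
#' @return an object of class `"rpc_diagnostics"`: fields
#'   `age_risk_correlation`, `collinearity_margin`,
#'   `proportionate_age_effect`, `threshold`, `admissible`, `unstable`.
#' @export
diagnose <- function(fit, risk, age, threshold = 0.85,
                     rounding_decimals = 2) {
  stopifnot(is.null(fit) || inherits(fit, "risk_model"))
  if (length(risk) != length(age) || length(risk) < 3)
    stop("risk and age must have equal length >= 3", call. = FALSE)
  if (stats::sd(age) == 0 || stats::sd(risk) == 0)
    stop("correlation undefined: ",
         if (stats::sd(age) == 0) "age" else "risk",
         " is constant", call. = FALSE)
  r <- stats::cor(age, risk)
  if (is.null(fit)) {
    prop <- NA_real_
    pval <- 0
  } else {
    slopes <- c(fit$age_slope, fit$cov_slopes)
    denom <- sum(slopes)
    tol <- sqrt(.Machine$double.eps) * max(abs(slopes), 1)
    prop <- if (abs(denom) < tol) NA_real_ else fit$age_slope / denom
    fstat <- suppressWarnings(summary(fit$lm))$fstatistic
    pval <- stats::pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE)
  }
  structure(list(
    age_risk_correlation = r,
    collinearity_margin = 1 - abs(r),
    proportionate_age_effect = prop,
    threshold = threshold,
    rounding_decimals = rounding_decimals,
    admissible = round(abs(r), rounding_decimals) < threshold,
    unstable = unname(pval) > 0.05
  ), class = "rpc_diagnostics")
}

#' @export
print.rpc_diagnostics <- function(x, digits = 3, ...) {
  cat("Risk-index diagnostics\n")
  cat("  cor(age, risk):           ",
      round(x$age_risk_correlation, digits), "\n")
  cat("  collinearity margin:      ",
      round(x$collinearity_margin, digits), "\n")
  cat("  proportionate age effect: ",
      if (is.na(x$proportionate_age_effect)) "undefined"
      else round(x$proportionate_age_effect, digits), "\n")
  cat("  admissible (|cor| < ", x$threshold, " at ",
      x$rounding_decimals, " decimals): ", x$admissible, "\n", sep = "")
  if (x$unstable)
    cat("  note: risk model indistinguishable from noise;",
        "diagnostics unstable\n")
  invisible(x)
}

#' Persist a risk model as structured text
#'
#' Writes the coefficients, scale flag, fit statistics and scaling of a
#' risk model as `key: value` lines, and reads them back.  The restored
#' object supports [risk_index()] on new data (the underlying `lm` is
#' rebuilt from the stored coefficients).
#'
#' @param fit a `"risk_model"` object.
#' @param path file path.
#' @return `write_risk_model` returns `path` invisibly;
#'   `read_risk_model` returns a list with the stored fields.
#' @export
write_risk_model <- function(fit, path) {
  stopifnot(inherits(fit, "risk_model"))
  cf <- coef(fit)
  lines <- c(
    "type: rpcohort risk_model",
    paste0("outcome: ", fit$outcome),
    paste0("age: ", fit$age),
    paste0("covariates: ", paste(fit$design_spec, collapse = ",")),
    paste0("standardized: ", fit$standardized),
    paste0("r_squared: ", format(fit$r_squared, digits = 17)),
    paste0("residual_variance: ",
           format(fit$residual_variance, digits = 17)),
    paste0("coef ", names(cf), ": ", format(unname(cf), digits = 17)),
    if (length(fit$centers))
      paste0("center ", names(fit$centers), ": ",
             format(unname(fit$centers), digits = 17)),
    if (length(fit$scales))
      paste0("scale ", names(fit$scales), ": ",
             format(unname(fit$scales), digits = 17))
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_risk_model
#' @export
read_risk_model <- function(path) {
  lines <- readLines(path)
  kv <- regmatches(lines, regexec("^([^:]+): (.*)$", lines))
  keys <- vapply(kv, `[`, character(1), 2)
  vals <- vapply(kv, `[`, character(1), 3)
  get1 <- function(k) vals[keys == k][1]
  num_of <- function(prefix) {
    i <- startsWith(keys, prefix)
    stats::setNames(as.numeric(vals[i]),
                    sub(paste0("^", prefix, " "), "", keys[i]))
  }
  list(outcome = get1("outcome"), age = get1("age"),
       covariates = strsplit(get1("covariates"), ",")[[1]],
       standardized = as.logical(get1("standardized")),
       r_squared = as.numeric(get1("r_squared")),
       residual_variance = as.numeric(get1("residual_variance")),
       coefficients = num_of("coef"),
       centers = num_of("center"), scales = num_of("scale"))
}
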