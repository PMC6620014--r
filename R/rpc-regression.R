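## Fixed-effects RPC and APC regressions, the hierarchical (crossed
## random intercepts) variant, cohort binning and the outcome transform.

## Minimum-norm least squares via SVD.  Singular values below
## tol * largest are treated as zero, so an (exactly or numerically)
## rank-deficient design yields the unique minimum-norm solution rather
## than an error or silently dropped columns.
ols_minnorm <- function(X, y, tol = 1e-10) {
  sv <- svd(X)
  keep <- sv$d > tol * sv$d[1]
  r <- sum(keep)
  uy <- crossprod(sv$u[, keep, drop = FALSE], y)
  coef <- sv$v[, keep, drop = FALSE] %*% (uy / sv$d[keep])
  ## pseudo-variance of the coefficients: V D^-2 V' restricted to the
  ## retained singular space (classical covariance when full rank)
  xxinv_diag <- rowSums(sweep(sv$v[, keep, drop = FALSE]^2, 2,
                              sv$d[keep]^2, "/"))
  list(coef = drop(coef), rank = r, xxinv_diag = xxinv_diag,
       rank_deficient = r < ncol(X))
}

finish_linear_fit <- function(X, y, n_levels = NULL, model = "rpc",
                              call = sys.call(-1)) {
  fit <- ols_minnorm(X, y)
  fitted <- unname(drop(X %*% fit$coef))
  res <- y - fitted
  n <- length(y)
  df_res <- n - fit$rank
  sigma2 <- sum(res^2) / df_res
  se <- sqrt(sigma2 * fit$xxinv_diag)
  tval <- fit$coef / se
  pval <- 2 * stats::pt(abs(tval), df_res, lower.tail = FALSE)
  tss <- sum((y - mean(y))^2)
  r2 <- 1 - sum(res^2) / tss
  p_model <- fit$rank - 1
  structure(list(
    coefficients = stats::setNames(fit$coef, colnames(X)),
    se = stats::setNames(se, colnames(X)),
    p_values = stats::setNames(pval, colnames(X)),
    r_squared = r2,
    adj_r_squared = 1 - (1 - r2) * (n - 1) / (n - p_model - 1),
    sigma = sqrt(sigma2),
    rank = fit$rank, df_residual = df_res,
    rank_deficient = fit$rank_deficient,
    fitted = fitted, residuals = res,
    model = model, n = n, call = call
  ), class = "rpc_fit")
}

check_factor <- function(f, what) {
  f <- as.factor(f)
  if (any(table(f) == 0))
    stop("empty level(s) in ", what, ": ",
         paste(levels(f)[table(f) == 0], collapse = ", "), call. = FALSE)
  f
}

#' Fit the risk-period-cohort regression
#'
#' Regresses the outcome on the age-related risk index plus cohort and
#' period:
#' \deqn{Y_i = \mu^* + \beta^* Risk_i + \Gamma^* Cohort_i +
#'   \Lambda^* Period_i + \varepsilon_i.}
#' Cohort and period may enter as numeric trends (the simulation-study
#' convention, standardized in-sample along with the risk index when
#' `standardize = TRUE`) or as categorical factors with stated reference
#' levels (the survey-analysis convention; pass pre-binned cohorts, see
#' [bin_cohorts()]).
#'
#' A numerically near-singular design — which arises when the risk
#' index is almost a linear function of age, reinstating the
#' age = period - cohort dependency — is solved by minimum-norm least
#' squares and flagged through `rank_deficient`; the fit is never
#' silently repaired by dropping columns.
#'
#' @param data data frame with the outcome, cohort and period columns.
#' @param risk numeric risk-index vector aligned with `data` rows.
#' @param cohort_as,period_as `"numeric"` or `"categorical"`.
#' @param outcome,cohort,period column names.
#' @param standardize standardize risk and numeric cohort/period
#'   in-sample before fitting.
#' @param cohort_ref,period_ref reference levels for the categorical
#'   variants (defaults: earliest cohort level, first period level).
#' @return an object of class `"rpc_fit"`: coefficient vector with
#'   standard errors and p-values, `r_squared`, `adj_r_squared`,
#'   `rank_deficient`, residuals and fitted values.
#' @seealso [fit_apc_ols()], [fit_rpc_hapc()], [rpc()]
#' @export
fit_rpc_ols <- function(data, risk,
                        cohort_as = c("numeric", "categorical"),
                        period_as = c("numeric", "categorical"),
                        outcome = "outcome", cohort = "cohort",
                        period = "period", standardize = TRUE,
                        cohort_ref = NULL, period_ref = NULL) {
  cohort_as <- match.arg(cohort_as)
  period_as <- match.arg(period_as)
  if (length(risk) != nrow(data))
    stop("risk vector length (", length(risk),
         ") does not match data rows (", nrow(data), ")", call. = FALSE)
  missing_cols <- setdiff(c(outcome, cohort, period), names(data))
  if (length(missing_cols))
    stop("column(s) not found: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  y <- data[[outcome]]
  r <- if (standardize) zstd(risk) else risk

  part <- function(x, as_what, ref, what) {
    if (as_what == "numeric") {
      m <- cbind(if (standardize) zstd(x) else x)
      colnames(m) <- what
      m
    } else {
      f <- check_factor(x, what)
      if (!is.null(ref)) f <- stats::relevel(f, ref = as.character(ref))
      m <- stats::model.matrix(~f)[, -1, drop = FALSE]
      colnames(m) <- paste0(what, sub("^f", "", colnames(m)))
      m
    }
  }
  X <- cbind("(Intercept)" = 1, risk = r,
             part(data[[cohort]], cohort_as, cohort_ref, cohort),
             part(data[[period]], period_as, period_ref, period))
  finish_linear_fit(X, y, model = "rpc", call = sys.call())
}

#' Fit a traditional age-period-cohort regression
#'
#' The classical comparator for [fit_rpc_ols()].  Two variants:
#' \describe{
#' \item{`"numeric"`}{outcome on (standardized) age, optional numeric
#'   covariates, and cohort as linear trends — the generating-model
#'   check of the recovery study.}
#' \item{`"categorical"`}{age linear (or categorical), period and
#'   cohort categorical.  Because age = period - cohort, a fully
#'   categorical specification is inherently rank-deficient; the
#'   `drop_levels` specification (reference level per variable, plus
#'   any further levels to merge into the reference) must break the
#'   dependency, and an explicit singularity error is raised when it
#'   does not.  Extra covariates give the covariate-adjusted APC
#'   variant.}
#' }
#'
#' @param data data frame.
#' @param drop_levels named list, e.g.
#'   `list(period = "2006", cohort = "1921")`; per variable the first
#'   entry is the reference level, further entries are levels merged
#'   into the reference.
#' @param variant `"categorical"` or `"numeric"`.
#' @param age_as for the categorical variant, enter age `"numeric"`
#'   (linear slope) or `"categorical"`.
#' @param covariates optional extra covariate column names.
#' @param outcome,age,period,cohort column names.
#' @param standardize standardize regressors in the numeric variant.
#' @return an object of class `"rpc_fit"` (with `model = "apc"`).
#' @export
fit_apc_ols <- function(data, drop_levels = NULL,
                        variant = c("categorical", "numeric"),
                        age_as = c("numeric", "categorical"),
                        covariates = NULL,
                        outcome = "outcome", age = "age",
                        period = "period", cohort = "cohort",
                        standardize = TRUE) {
  variant <- match.arg(variant)
  age_as <- match.arg(age_as)
  missing_cols <- setdiff(c(outcome, age, cohort,
                            if (variant == "categorical") period,
                            covariates), names(data))
  if (length(missing_cols))
    stop("column(s) not found: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  y <- data[[outcome]]

  if (variant == "numeric") {
    z <- function(x) if (standardize) zstd(x) else x
    X <- cbind("(Intercept)" = rep(1, nrow(data)))
    for (v in c(age, covariates, cohort)) {
      X <- cbind(X, z(data[[v]]))
      colnames(X)[ncol(X)] <- v
    }
    return(finish_linear_fit(X, y, model = "apc", call = sys.call()))
  }

  fac_part <- function(x, what) {
    f <- check_factor(x, what)
    spec <- drop_levels[[what]]
    if (!is.null(spec)) {
      spec <- as.character(spec)
      bad <- setdiff(spec, levels(f))
      if (length(bad))
        stop("drop_levels for ", what, " names absent level(s): ",
             paste(bad, collapse = ", "), call. = FALSE)
      if (length(spec) > 1)   # merge extra levels into the reference
        levels(f)[levels(f) %in% spec[-1]] <- spec[1]
      f <- stats::relevel(f, ref = spec[1])
    }
    m <- stats::model.matrix(~f)[, -1, drop = FALSE]
    colnames(m) <- paste0(what, sub("^f", "", colnames(m)))
    m
  }
  X <- cbind("(Intercept)" = 1,
             if (age_as == "numeric") {
               m <- cbind(data[[age]]); colnames(m) <- age; m
             } else fac_part(data[[age]], age),
             fac_part(data[[period]], period),
             fac_part(data[[cohort]], cohort))
  for (v in covariates) {
    if (is.numeric(data[[v]])) {
      X <- cbind(X, data[[v]]); colnames(X)[ncol(X)] <- v
    } else {
      X <- cbind(X, fac_part(data[[v]], v))
    }
  }
  if (qr(X)$rank < ncol(X))
    stop("singular APC design: the drop_levels specification does not ",
         "break the age = period - cohort dependency", call. = FALSE)
  finish_linear_fit(X, y, model = "apc", call = sys.call())
}

#' @export
print.rpc_fit <- function(x, digits = 3, ...) {
  cat(toupper(x$model), "regression (n =", x$n, ")\n")
  if (x$rank_deficient)
    cat("NOTE: near-singular design; minimum-norm solution",
        "(rank", x$rank, "of", length(x$coefficients), "columns)\n")
  tab <- data.frame(Estimate = round(x$coefficients, digits),
                    SE = round(x$se, digits),
                    p = signif(x$p_values, 2))
  print(tab)
  cat("R-squared:", round(x$r_squared, 4),
      "  adjusted:", round(x$adj_r_squared, 4), "\n")
  invisible(x)
}

#' @export
coef.rpc_fit <- function(object, ...) object$coefficients

#' @export
residuals.rpc_fit <- function(object, ...) object$residuals

#' @export
fitted.rpc_fit <- function(object, ...) object$fitted

#' Hierarchical period-cohort model with a risk (or age) fixed effect
#'
#' Mixed-effects counterpart of [fit_rpc_ols()]: a within-subject model
#' with a common slope for the age-related risk index and a
#' between-subject model giving each period-by-cohort cell an intercept
#' that decomposes into a grand intercept plus crossed random intercepts
#' for period and for cohort,
#' \deqn{Y_{ijk} = \alpha_{jk} + \beta_1 Risk_i + \varepsilon_{ijk},
#'   \qquad \alpha_{jk} = \eta_0 + \tau_{0j} + \lambda_{0k}.}
#' The classification is cross-classified, not nested: a period does
#' not contain all cohorts nor vice versa.  Estimation is by restricted
#' maximum likelihood through \pkg{lme4}.  With `risk = NULL` the fixed
#' part is chronological age instead (optionally with a quadratic
#' term), giving the hierarchical APC comparator.
#'
#' A classification with a single level cannot support a variance
#' component; it is dropped with a warning and its component reported
#' as 0.
#'
#' @param data data frame with outcome, period and cohort columns.
#' @param risk numeric risk-index vector aligned with `data`, or `NULL`
#'   for the age-based comparator.
#' @param outcome,period,cohort,age column names.
#' @param quadratic_age include a quadratic age term (age comparator
#'   only).
#' @return an object of class `"hapc_fit"`: `fixed_intercept`,
#'   `fixed_slopes`, `period_random_intercepts`,
#'   `cohort_random_intercepts` (conditional modes, shrunken toward 0),
#'   `variance_components` (period, cohort, residual), and the
#'   underlying `lmerMod`.
#' @export
fit_rpc_hapc <- function(data, risk = NULL, outcome = "outcome",
                         period = "period", cohort = "cohort",
                         age = "age", quadratic_age = FALSE) {
  missing_cols <- setdiff(c(outcome, period, cohort,
                            if (is.null(risk)) age), names(data))
  if (length(missing_cols))
    stop("column(s) not found: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  df <- data.frame(.y = data[[outcome]],
                   .period = factor(data[[period]]),
                   .cohort = factor(data[[cohort]]))
  if (!is.null(risk)) {
    if (length(risk) != nrow(data))
      stop("risk vector length does not match data rows", call. = FALSE)
    df$.risk <- risk
    fixed <- ".risk"
  } else {
    ## centered age keeps the quadratic term on a comparable scale
    df$.age <- data[[age]] - mean(data[[age]])
    fixed <- ".age"
    if (quadratic_age) {
      df$.age2 <- df$.age^2
      fixed <- c(".age", ".age2")
    }
  }
  res <- c(period = ".period", cohort = ".cohort")
  keep <- vapply(res, function(v) nlevels(df[[v]]) >= 2, logical(1))
  for (v in names(res)[!keep])
    warning("classification '", v, "' has a single level; ",
            "its variance component is fixed at 0", call. = FALSE)
  if (!any(keep))
    stop("need at least one classification with >= 2 levels",
         call. = FALSE)
  rterms <- paste0("(1 | ", res[keep], ")")
  form <- stats::as.formula(paste(".y ~", paste(c(fixed, rterms),
                                                collapse = " + ")))
  mod <- lme4::lmer(form, data = df, REML = TRUE)
  vc <- as.data.frame(lme4::VarCorr(mod))
  getvc <- function(grp) {
    v <- vc$vcov[vc$grp == grp]
    if (length(v)) v else 0
  }
  re <- lme4::ranef(mod)
  getre <- function(grp) {
    if (!grp %in% names(re)) return(stats::setNames(numeric(0), character(0)))
    stats::setNames(re[[grp]][["(Intercept)"]], rownames(re[[grp]]))
  }
  fe <- lme4::fixef(mod)
  structure(list(
    fixed_intercept = unname(fe["(Intercept)"]),
    fixed_slopes = fe[-1],
    period_random_intercepts = getre(".period"),
    cohort_random_intercepts = getre(".cohort"),
    variance_components = c(period = getvc(".period"),
                            cohort = getvc(".cohort"),
                            residual = stats::sigma(mod)^2),
    lmer = mod
  ), class = "hapc_fit")
}

#' @export
print.hapc_fit <- function(x, digits = 3, ...) {
  cat("Hierarchical period-cohort model (REML, crossed random",
      "intercepts)\n")
  cat("Fixed effects:\n")
  print(round(c("(Intercept)" = x$fixed_intercept, x$fixed_slopes),
              digits))
  cat("Variance components:\n")
  print(round(x$variance_components, digits))
  cat("Random intercepts: ", length(x$period_random_intercepts),
      " periods, ", length(x$cohort_random_intercepts), " cohorts\n",
      sep = "")
  invisible(x)
}

#' Group birth years into cohort bins
#'
#' Maps each birth year to a closed integer bin of `width` years
#' anchored at `origin`, labelled `"start-end"` (for example
#' `"1946-1950"`, which contains 1946 through 1950; 1951 falls in
#' `"1951-1955"`).  Years before `origin` are collected into a single
#' earlier bin labelled by the earliest observed year, mirroring the
#' narrower reference cohort of survey tables.  `width = 1` gives
#' plain-year labels.
#'
#' @param birth_years integer vector of birth years.
#' @param width bin width in years.
#' @param origin first year of the regular bins; defaults to
#'   `min(birth_years)` (no narrower leading bin).
#' @return a factor with levels in chronological order.
#' @export
#' @examples
#' bin_cohorts(c(1921, 1947, 1950, 1951), origin = 1926)
bin_cohorts <- function(birth_years, width = 5, origin = NULL) {
  if (any(birth_years != round(birth_years), na.rm = TRUE))
    stop("birth_years must be integer years", call. = FALSE)
  if (is.null(origin)) origin <- min(birth_years, na.rm = TRUE)
  lab <- function(a, b) ifelse(a == b, as.character(a),
                               paste0(a, "-", b))
  k <- (birth_years - origin) %/% width
  a <- origin + k * width
  b <- a + width - 1
  labels <- lab(a, b)
  pre <- birth_years < origin
  if (any(pre, na.rm = TRUE))
    labels[pre] <- as.character(min(birth_years, na.rm = TRUE))
  ord <- order(ifelse(pre, min(birth_years, na.rm = TRUE), a))
  factor(labels, levels = unique(labels[ord]))
}

#' Log(score + 1) transform for skewed bounded scores
#'
#' The outcome transform used for right-skewed questionnaire totals
#' before linear modelling: `log(score + 1)`, elementwise.
#'
#' @param scores non-negative numeric vector.
#' @return transformed vector.
#' @export
log1p_outcome <- function(scores) {
  if (any(scores < 0, na.rm = TRUE))
    stop("scores must be non-negative", call. = FALSE)
  log1p(scores)
}
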