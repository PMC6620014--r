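## Monte Carlo drivers for the two simulation studies.
##
## Both drivers share one replication design: a single seed per
## replication (derived from base_seed by a fixed rule) generates one
## set of covariate and noise draws, and every slope pattern's fits are
## computed exactly from that replication's 7-column Gram matrix.  The
## per-pattern statistics are algebraically identical to generating the
## pattern's dataset with the same seed and running fit_risk_model() /
## risk_index() / fit_rpc_ols() directly (the "direct" engine, kept for
## validation) — every outcome is a linear combination of the shared
## columns, so normal equations over the Gram matrix reproduce the OLS
## solution to machine precision.  Sharing draws across patterns is a
## common-random-numbers design: per-pattern distributions are
## untouched, paper-scale grids run in seconds, and any subset of the
## grid reruns bit-identically.

#' Seed for one Monte Carlo replication
#'
#' Deterministic rule mapping `(base_seed, stream, rep)` to the seed of
#' a single replication, kept below 2^31.  Streams separate the two
#' studies (and the demonstration pipeline) so their draws never
#' overlap.
#' @keywords internal
mc_seed <- function(base_seed, stream, rep) {
  as.integer(((base_seed %% 100000) * 20011 + stream * 10007 + rep) %%
               2147483647)
}

#' Full slope-parameter grids of the simulation studies
#'
#' Every slope drawn from `c(0, 0.2, 0.4, 0.6, 0.8, 1)`: 6^3 = 216
#' patterns of (beta, alpha1, alpha2) for the correlation study, and
#' 6^4 = 1296 patterns adding gamma for the recovery study.
#'
#' @param study `"study1"` or `"study2"`.
#' @return a data.frame of slope patterns.
#' @export
study_grid <- function(study = c("study1", "study2")) {
  study <- match.arg(study)
  g <- slope_grid()
  if (study == "study1")
    expand.grid(beta = g, alpha1 = g, alpha2 = g,
                KEEP.OUT.ATTRS = FALSE)
  else
    expand.grid(beta = g, alpha1 = g, alpha2 = g, gamma = g,
                KEEP.OUT.ATTRS = FALSE)
}

as_grid <- function(grid, need_gamma) {
  if (is.list(grid) && !is.data.frame(grid) &&
      all(vapply(grid, inherits, logical(1), "sim_condition"))) {
    grid <- do.call(rbind, lapply(grid, function(cn)
      data.frame(beta = cn$beta, alpha1 = cn$alpha1, alpha2 = cn$alpha2,
                 gamma = if (is.null(cn$gamma)) NA_real_ else cn$gamma)))
    if (!need_gamma) grid$gamma <- NULL
  }
  need <- c("beta", "alpha1", "alpha2", if (need_gamma) "gamma")
  if (!is.data.frame(grid) || !all(need %in% names(grid)))
    stop("grid must be a data.frame with columns ",
         paste(need, collapse = ", "), call. = FALSE)
  if (anyNA(grid[need])) stop("grid contains missing slopes", call. = FALSE)
  grid[need]
}

## Gram pieces of one study-1 replication (matches simulate_study1 draws)
rep_gram1 <- function(n, seed) {
  set.seed(seed)
  cv <- draw_covariates(n, with_period = FALSE)
  eps <- stats::rnorm(n)
  Z <- cbind(zstd(cv$age), zstd(cv$sep), zstd(cv$activity),
             eps - mean(eps))
  crossprod(Z)
}

## Gram pieces of one study-2 replication (matches simulate_study2);
## columns: a s c h p e e0 (standardized covariates / cohort / period,
## centered noises)
rep_gram2 <- function(n, seed) {
  set.seed(seed)
  cv <- draw_covariates(n, with_period = TRUE)
  eps <- stats::rnorm(n)
  eps0 <- stats::rnorm(n)
  cohort <- cv$period - cv$age
  Z <- cbind(zstd(cv$age), zstd(cv$sep), zstd(cv$activity),
             zstd(cohort), zstd(cv$period),
             eps - mean(eps), eps0 - mean(eps0))
  crossprod(Z)
}

#' Run the age-risk correlation study
#'
#' For every slope pattern (beta, alpha1, alpha2): generate `reps`
#' cross-sectional datasets of size `n`, fit the internal risk model on
#' standardized regressors, compute the age-related risk index, and
#' average the age-risk correlation and the proportionate chronological
#' age effect over replications.  Empirical standard errors are those
#' of the Monte Carlo means (sd across replications divided by
#' sqrt(reps)).
#'
#' A pattern is flagged as high-correlation when its mean correlation,
#' rounded to 2 decimals, is at or above `threshold`; the
#' high-proportionate-effect indicator uses the same round-then-compare
#' convention at 0.60.
#'
#' @param grid data.frame of slope patterns (default: the full 216) or
#'   a list of [sim_condition()] objects.
#' @param reps Monte Carlo replications per pattern.
#' @param n subjects per replication.
#' @param base_seed integer seed driving every replication (see
#'   [mc_seed()]).
#' @param engine `"gram"` (fast, shared draws across patterns, exact)
#'   or `"direct"` (one full simulate-fit-diagnose pipeline per pattern
#'   and replication; identical results, kept for validation).
#' @param threshold correlation flag threshold.
#' @return a data.frame of class `"rpc_study1"` with one row per
#'   pattern: `mean_corr`, `mean_prop_effect`, `se_corr`, `se_prop`,
#'   `sd_corr`, `sd_prop`, `flagged_high_corr`, `high_prop_effect`.
#' @export
run_study1 <- function(grid = study_grid("study1"), reps = 1000,
                       n = 10000, base_seed = 1,
                       engine = c("gram", "direct"), threshold = 0.85) {
  engine <- match.arg(engine)
  grid <- as_grid(grid, need_gamma = FALSE)
  if (reps < 2) stop("reps must be >= 2", call. = FALSE)
  pat <- as.matrix(grid)
  np <- nrow(pat)
  s_c <- s_c2 <- s_p <- s_p2 <- numeric(np)

  if (engine == "gram") {
    A <- 1:3
    for (r in seq_len(reps)) {
      M <- rep_gram1(n, mc_seed(base_seed, 1L, r))
      d <- solve(M[A, A], M[A, 4])
      W <- pat + rep(d, each = np)
      q <- W %*% M[A, A]
      corr <- q[, 1] / sqrt(rowSums(q * W) * M[1, 1])
      prop <- W[, 1] / rowSums(W)
      s_c <- s_c + corr; s_c2 <- s_c2 + corr^2
      s_p <- s_p + prop; s_p2 <- s_p2 + prop^2
    }
  } else {
    for (k in seq_len(np)) {
      corr <- prop <- numeric(reps)
      for (r in seq_len(reps)) {
        cond <- sim_condition(pat[k, 1], pat[k, 2], pat[k, 3],
                              n = n, seed = mc_seed(base_seed, 1L, r))
        d1 <- simulate_study1(cond)
        fit <- fit_risk_model(d1, c("sep", "activity"))
        risk <- risk_index(fit, d1)
        corr[r] <- stats::cor(d1$age, risk)
        prop[r] <- fit$age_slope / (fit$age_slope + sum(fit$cov_slopes))
      }
      s_c[k] <- sum(corr); s_c2[k] <- sum(corr^2)
      s_p[k] <- sum(prop); s_p2[k] <- sum(prop^2)
    }
  }
  mc <- s_c / reps
  mp <- s_p / reps
  sd_c <- sqrt(pmax(s_c2 / reps - mc^2, 0) * reps / (reps - 1))
  sd_p <- sqrt(pmax(s_p2 / reps - mp^2, 0) * reps / (reps - 1))
  out <- data.frame(grid,
                    mean_corr = mc, mean_prop_effect = mp,
                    se_corr = sd_c / sqrt(reps),
                    se_prop = sd_p / sqrt(reps),
                    sd_corr = sd_c, sd_prop = sd_p,
                    flagged_high_corr = round(mc, 2) >= threshold,
                    high_prop_effect = round(mp, 2) >= 0.60)
  structure(out, reps = reps, n = n, base_seed = base_seed,
            threshold = threshold, engine = engine,
            class = c("rpc_study1", "data.frame"))
}

## vectorized 3x3 Cramer solve for the stage-2 normal equations;
## g11, v1, v2, v3 vary over patterns, the rest are scalars
stage2_coefs <- function(g11, g12, g13, g22, g23, g33, v1, v2, v3) {
  det0 <- g11 * (g22 * g33 - g23^2) - g12 * (g12 * g33 - g23 * g13) +
    g13 * (g12 * g23 - g22 * g13)
  x2 <- (g11 * (v2 * g33 - g23 * v3) - v1 * (g12 * g33 - g23 * g13) +
           g13 * (g12 * v3 - v2 * g13)) / det0
  x3 <- (g11 * (g22 * v3 - g23 * v2) - g12 * (g12 * v3 - v2 * g13) +
           v1 * (g12 * g23 - g22 * g13)) / det0
  list(cohort = x2, period = x3)
}

#' Run the cohort/period-effect recovery study
#'
#' For every slope pattern (beta, alpha1, alpha2, gamma): generate
#' `reps` datasets of size `n` with cohort structure, fit the internal
#' risk model (by default on the baseline outcome — same slopes,
#' independent noise, no cohort term), compute the risk index, fit the
#' risk-period-cohort regression on standardized risk, cohort and
#' period, and accumulate the cohort-effect difference
#' gamma - gamma_hat* and the spurious period effect lambda_hat*.
#'
#' The reported recovery statistics are the absolute Monte Carlo means
#' `cohort_diff = |mean(gamma - gamma*)|` and
#' `period_effect = |mean(lambda*)|`; a pattern is flagged when either
#' exceeds 0.01.  (The per-replication means of absolute values are
#' also returned, as `mean_abs_*` columns, but are not used for
#' flagging: with n = 10000 the sampling noise of a single replication
#' alone exceeds 0.01 for every pattern, so a mean-of-absolutes
#' criterion would flag the entire grid; the absolute-mean statistic
#' measures the systematic bias the flag is meant to detect.)
#'
#' @inheritParams run_study1
#' @param risk_on `"baseline"` fits the risk model on the auxiliary
#'   baseline outcome (the default convention); `"current"` fits it on
#'   the cohort-bearing outcome itself.
#' @return a data.frame of class `"rpc_study2"` with one row per
#'   pattern: `cohort_diff`, `period_effect`, `mean_abs_cohort_diff`,
#'   `mean_abs_period_effect`, `se_cohort_diff`, `se_period_effect`,
#'   `flagged`.
#' @export
run_study2 <- function(grid = study_grid("study2"), reps = 1000,
                       n = 10000, base_seed = 1,
                       engine = c("gram", "direct"),
                       risk_on = c("baseline", "current")) {
  engine <- match.arg(engine)
  risk_on <- match.arg(risk_on)
  grid <- as_grid(grid, need_gamma = TRUE)
  if (reps < 2) stop("reps must be >= 2", call. = FALSE)

  if (engine == "direct") return(
    run_study2_direct(grid, reps, n, base_seed, risk_on))

  ## gamma - gamma* is invariant in gamma when the risk model is fit on
  ## the baseline outcome (cohort is a design column, so adding
  ## gamma * cohort to the outcome shifts gamma* by exactly gamma); the
  ## distinct computations are then the (beta, alpha1, alpha2) combos.
  combos <- unique(grid[c("beta", "alpha1", "alpha2")])
  key <- function(df) paste(df$beta, df$alpha1, df$alpha2)
  if (risk_on == "current")
    combos <- unique(grid)   # risk model sees gamma: no invariance
  pat <- as.matrix(combos[c("beta", "alpha1", "alpha2")])
  gam <- if (risk_on == "current") combos$gamma else rep(0, nrow(pat))
  np <- nrow(pat)
  s_g <- s_g2 <- s_ga <- s_p <- s_p2 <- s_pa <- numeric(np)
  A <- 1:3

  for (r in seq_len(reps)) {
    M <- rep_gram2(n, mc_seed(base_seed, 2L, r))
    noise <- if (risk_on == "baseline") 7L else 6L   # e0 vs e column
    d0 <- solve(M[A, A], M[A, noise])
    dh <- solve(M[A, A], M[A, 4])
    W <- pat + rep(d0, each = np)
    if (risk_on == "current") W <- W + gam * rep(dh, each = np)
    q <- W %*% M[A, A]
    g11 <- rowSums(q * W)
    g12 <- drop(W %*% M[A, 4]); g13 <- drop(W %*% M[A, 5])
    ## y = pat.(a,s,c) + gam*h + e
    v1 <- rowSums(q * pat) + gam * g12 + drop(W %*% M[A, 6])
    v2 <- drop(pat %*% M[A, 4]) + gam * M[4, 4] + M[4, 6]
    v3 <- drop(pat %*% M[A, 5]) + gam * M[4, 5] + M[5, 6]
    cf <- stage2_coefs(g11, g12, g13, M[4, 4], M[4, 5], M[5, 5],
                       v1, v2, v3)
    gd <- gam - cf$cohort
    pd <- cf$period
    s_g <- s_g + gd; s_g2 <- s_g2 + gd^2; s_ga <- s_ga + abs(gd)
    s_p <- s_p + pd; s_p2 <- s_p2 + pd^2; s_pa <- s_pa + abs(pd)
  }

  mg <- s_g / reps; mp <- s_p / reps
  sd_g <- sqrt(pmax(s_g2 / reps - mg^2, 0) * reps / (reps - 1))
  sd_p <- sqrt(pmax(s_p2 / reps - mp^2, 0) * reps / (reps - 1))
  combo_rows <- data.frame(
    cohort_diff = abs(mg), period_effect = abs(mp),
    mean_abs_cohort_diff = s_ga / reps,
    mean_abs_period_effect = s_pa / reps,
    se_cohort_diff = sd_g / sqrt(reps),
    se_period_effect = sd_p / sqrt(reps))
  idx <- if (risk_on == "current") match(key(grid) %+% grid$gamma,
                                         key(combos) %+% combos$gamma)
         else match(key(grid), key(combos))
  out <- data.frame(grid, combo_rows[idx, , drop = FALSE],
                    row.names = NULL)
  out$flagged <- out$cohort_diff > 0.01 | out$period_effect > 0.01
  structure(out, reps = reps, n = n, base_seed = base_seed,
            risk_on = risk_on, engine = engine,
            class = c("rpc_study2", "data.frame"))
}

`%+%` <- function(a, b) paste(a, b)

run_study2_direct <- function(grid, reps, n, base_seed, risk_on) {
  np <- nrow(grid)
  cols <- c("cohort_diff", "period_effect", "mean_abs_cohort_diff",
            "mean_abs_period_effect", "se_cohort_diff",
            "se_period_effect")
  acc <- matrix(0, np, length(cols), dimnames = list(NULL, cols))
  for (k in seq_len(np)) {
    gd <- pd <- numeric(reps)
    for (r in seq_len(reps)) {
      cond <- sim_condition(grid$beta[k], grid$alpha1[k], grid$alpha2[k],
                            gamma = grid$gamma[k], n = n,
                            seed = mc_seed(base_seed, 2L, r))
      d2 <- simulate_study2(cond)
      fit <- fit_risk_model(d2, c("sep", "activity"),
                            outcome = if (risk_on == "baseline")
                              "outcome0" else "outcome")
      risk <- risk_index(fit, d2)
      rfit <- fit_rpc_ols(d2, risk)
      gd[r] <- grid$gamma[k] - rfit$coefficients["cohort"]
      pd[r] <- rfit$coefficients["period"]
    }
    acc[k, ] <- c(abs(mean(gd)), abs(mean(pd)), mean(abs(gd)),
                  mean(abs(pd)), stats::sd(gd) / sqrt(reps),
                  stats::sd(pd) / sqrt(reps))
  }
  out <- data.frame(grid, acc, row.names = NULL)
  out$flagged <- out$cohort_diff > 0.01 | out$period_effect > 0.01
  structure(out, reps = reps, n = n, base_seed = base_seed,
            risk_on = risk_on, engine = "direct",
            class = c("rpc_study2", "data.frame"))
}

#' @export
print.rpc_study1 <- function(x, ...) {
  if (!is.null(attr(x, "reps")))
    cat("Age-risk correlation study: ", nrow(x), " patterns, ",
        attr(x, "reps"), " replications of n = ", attr(x, "n"), "\n",
        "Patterns at or above the ", attr(x, "threshold"),
        " correlation threshold: ", sum(x$flagged_high_corr), "\n",
        sep = "")
  NextMethod()
}

#' @export
print.rpc_study2 <- function(x, ...) {
  if (!is.null(attr(x, "reps")))
    cat("Cohort/period recovery study: ", nrow(x), " patterns, ",
        attr(x, "reps"), " replications of n = ", attr(x, "n"), "\n",
        "Patterns failing the 0.01 recovery criterion: ",
        sum(x$flagged), " (", nrow(x) - sum(x$flagged),
        " recovered)\n", sep = "")
  NextMethod()
}

#' Summary tables of a Monte Carlo study run
#'
#' Produces the reporting tables of a study run: for the correlation
#' study, the flagged patterns sorted by decreasing mean correlation
#' plus a full-grid scatter export (mean correlation vs proportionate
#' effect grouped by beta, ready for plotting); for the recovery study,
#' the flagged patterns with their recovery statistics.  Tables are
#' returned as data.frames and, when `dir` is given, written as CSV.
#'
#' @param rows output of [run_study1()] or [run_study2()].
#' @param dir optional output directory for delimited exports.
#' @return a list of data.frames (`flagged` and, for the correlation
#'   study, `scatter`), invisibly carrying conservation counts.
#' @export
summarize_study <- function(rows, dir = NULL) {
  if (inherits(rows, "rpc_study1")) {
    flagged <- rows[rows$flagged_high_corr, c("beta", "alpha1", "alpha2",
                                              "mean_corr",
                                              "mean_prop_effect")]
    flagged <- flagged[order(-flagged$mean_corr, flagged$beta,
                             flagged$alpha1, flagged$alpha2), ]
    scatter <- rows[c("beta", "alpha1", "alpha2", "mean_corr",
                      "mean_prop_effect")]
    out <- list(flagged = flagged, scatter = scatter)
    files <- c(flagged = "study1_flagged.csv",
               scatter = "study1_scatter.csv")
  } else if (inherits(rows, "rpc_study2")) {
    flagged <- rows[rows$flagged, c("beta", "alpha1", "alpha2", "gamma",
                                    "cohort_diff", "period_effect")]
    flagged <- flagged[order(flagged$beta, flagged$alpha1,
                             flagged$alpha2, flagged$gamma), ]
    out <- list(flagged = flagged)
    files <- c(flagged = "study2_flagged.csv")
  } else stop("rows must come from run_study1() or run_study2()",
              call. = FALSE)
  rownames(out$flagged) <- NULL
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(files))
      utils::write.csv(out[[nm]], file.path(dir, files[nm]),
                       row.names = FALSE)
  }
  out
}
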