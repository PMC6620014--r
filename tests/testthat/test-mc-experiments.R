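# The Gram-matrix engine must be exactly the composition of
# simulate -> fit_risk_model -> risk_index -> fit_rpc_ols / diagnose;
# the direct engine runs that composition literally.

test_that("study-1 engines agree to numerical precision", {
  g <- data.frame(beta = c(0, 0.4, 1), alpha1 = c(0, 0.2, 0),
                  alpha2 = c(0, 0, 0.2))
  fast <- run_study1(g, reps = 4, n = 1500, base_seed = 33)
  slow <- run_study1(g, reps = 4, n = 1500, base_seed = 33,
                     engine = "direct")
  expect_equal(fast$mean_corr, slow$mean_corr, tolerance = 1e-9)
  expect_equal(fast$mean_prop_effect, slow$mean_prop_effect,
               tolerance = 1e-9)
  expect_equal(fast$sd_corr, slow$sd_corr, tolerance = 1e-8)
})

test_that("study-2 engines agree under both risk-model conventions", {
  g <- data.frame(beta = c(0.2, 0.6, 0.6), alpha1 = c(0, 0.2, 0.2),
                  alpha2 = c(0, 0.4, 0.4), gamma = c(0.2, 1, 0.4))
  for (ro in c("baseline", "current")) {
    fast <- run_study2(g, reps = 4, n = 1500, base_seed = 34,
                       risk_on = ro)
    slow <- run_study2(g, reps = 4, n = 1500, base_seed = 34,
                       engine = "direct", risk_on = ro)
    expect_equal(fast$cohort_diff, slow$cohort_diff, tolerance = 1e-8)
    expect_equal(fast$period_effect, slow$period_effect,
                 tolerance = 1e-8)
    expect_equal(fast$mean_abs_cohort_diff, slow$mean_abs_cohort_diff,
                 tolerance = 1e-8)
  }
})

test_that("runs are reproducible and conserve the grid", {
  g <- study_grid("study1")[seq(1, 216, 9), ]
  a <- run_study1(g, reps = 3, n = 1000, base_seed = 35)
  b <- run_study1(g, reps = 3, n = 1000, base_seed = 35)
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_equal(nrow(a), nrow(g))
  expect_false(anyNA(a$flagged_high_corr))
  g2 <- study_grid("study2")
  expect_equal(nrow(g2), 1296)
  expect_equal(nrow(study_grid("study1")), 216)
  # per-replication seeds stay valid 32-bit integers
  seeds <- vapply(1:50, function(r)
    rpcohort:::mc_seed(123456789, 2L, r), integer(1))
  expect_true(all(seeds >= 0 & seeds < 2^31))
  expect_false(anyDuplicated(seeds) > 0)
})

test_that("study-1 means match the closed-form oracles over the grid", {
  # 2000 replications: the second-order bias of the proportionate
  # effect at the smallest slope sums is ~0.005, so the Monte Carlo
  # error must be well below that for the 0.01 band
  s1 <- run_study1(reps = 2000, n = 10000, base_seed = 36)
  oc <- closed_form_corr(s1$beta, s1$alpha1, s1$alpha2)
  op <- closed_form_prop(s1$beta, s1$alpha1, s1$alpha2)
  nonnull <- s1$beta + s1$alpha1 + s1$alpha2 > 0
  expect_true(all(abs(s1$mean_corr[nonnull] - oc[nonnull]) < 0.01))
  expect_true(all(abs(s1$mean_prop_effect[nonnull] - op[nonnull]) <
                    0.01))
  # monotonicity: fixed (alpha1, alpha2), mean correlation
  # non-decreasing in beta
  for (sp in split(s1, list(s1$alpha1, s1$alpha2))) {
    sp <- sp[order(sp$beta), ]
    expect_true(all(diff(sp$mean_corr) > -1e-3))
  }
})

test_that("summary tables mirror the flag sets", {
  s1 <- run_study1(reps = 40, n = 4000, base_seed = 37)
  rep1 <- summarize_study(s1)
  expect_equal(nrow(rep1$flagged), sum(s1$flagged_high_corr))
  expect_equal(nrow(rep1$scatter), nrow(s1))
  # sorted by decreasing mean correlation; top row is a pure-age pattern
  expect_true(all(diff(rep1$flagged$mean_corr) <= 1e-12))
  top <- rep1$flagged[1, ]
  expect_equal(top$alpha1 + top$alpha2, 0)
  expect_equal(round(top$mean_corr, 2), 1)

  g2 <- data.frame(beta = 0.2, alpha1 = c(0.4, 0.6), alpha2 = 0.4,
                   gamma = 0.2)
  s2 <- run_study2(g2, reps = 60, n = 4000, base_seed = 38)
  rep2 <- summarize_study(s2)
  expect_equal(nrow(rep2$flagged), sum(s2$flagged))

  dir <- withr::local_tempdir()
  summarize_study(s1, dir = dir)
  expect_true(file.exists(file.path(dir, "study1_flagged.csv")))
  expect_true(file.exists(file.path(dir, "study1_scatter.csv")))
  expect_error(summarize_study(data.frame(x = 1)), "run_study")
})

test_that("an empty flag set gives an empty table, not an error", {
  g <- data.frame(beta = 0.4, alpha1 = 0.6, alpha2 = 0.6, gamma = 0.4)
  s2 <- run_study2(g, reps = 200, n = 10000, base_seed = 39)
  expect_false(any(s2$flagged))
  rep2 <- summarize_study(s2)
  expect_equal(nrow(rep2$flagged), 0)
})

test_that("recovery bias grows with beta for the pathological patterns", {
  g <- data.frame(beta = c(0.2, 0.6, 1), alpha1 = 0, alpha2 = 0,
                  gamma = 0.4)
  s2 <- run_study2(g, reps = 120, n = 10000, base_seed = 40)
  expect_true(all(s2$flagged))
  expect_true(all(diff(s2$cohort_diff) > 0))
  expect_true(all(diff(s2$period_effect) > 0))
})
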