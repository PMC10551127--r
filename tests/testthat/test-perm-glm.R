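two_group_design <- function(n1, n2) {
  structure(cbind(intercept = 1,
                  group = rep(c(1, 0), c(n1, n2))),
            contrast = "group")
}

test_that("design matrix encodes the contrast and flags collinearity", {
  ph <- fixed_pheno(5, 6)
  x <- design_matrix(ph)
  expect_equal(colnames(x), c("intercept", "group", "age", "sex",
                              "mean_fd", "cortex_volume"))
  expect_equal(unname(x[, "group"]),
               as.numeric(ph$group == "patient"))
  ph2 <- ph
  ph2$cortex_volume <- 2 * ph2$age + 1  # exact collinearity with age
  expect_error(design_matrix(ph2), "cortex_volume")
})

test_that("GLM t equals the pooled two-sample t without covariates", {
  x <- two_group_design(3, 3)
  y <- c(1, 2, 3, 4, 5, 6)
  t1 <- glm_tstat(y, x)
  # mean diff -3, pooled sd 1, se = sqrt(2/3)
  expect_equal(abs(t1), 3 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(abs(t1), abs(unname(stats::t.test(
    y[1:3], y[4:6], var.equal = TRUE)$statistic)), tolerance = 1e-12)
  # constant outcome: t = 0 by convention
  expect_equal(glm_tstat(rep(2, 6), x), 0)
})

test_that("a covariate orthogonal to group and outcome only changes df", {
  set.seed(1)
  n <- 24
  x0 <- two_group_design(12, 12)
  y <- rnorm(n) + x0[, "group"]
  # build a covariate orthogonal to both the design columns and y
  raw <- rnorm(n)
  z <- stats::resid(stats::lm(raw ~ x0 + y))
  x1 <- structure(cbind(x0, cov = z), contrast = "group")
  f0 <- glm_tstats(y, x0)
  f1 <- glm_tstats(y, x1)
  expect_equal(f1$df, f0$df - 1L)
  # identical contrast estimate; t rescaled only through the df change
  expect_equal(f1$t * sqrt(f0$df / f1$df), f0$t, tolerance = 1e-10)
})

test_that("Freedman-Lane nulls behave as permutation distributions", {
  ph <- fixed_pheno(10, 10)
  x <- design_matrix(ph)
  set.seed(2)
  y <- matrix(rnorm(20 * 3), 20, 3)
  null <- freedman_lane_permute(y, x, n_perm = 400, seed = 5)
  expect_equal(dim(null), c(400L, 3L))
  # under H0 the null t's are centred at zero
  for (j in 1:3) {
    expect_lt(abs(mean(null[, j])), 3 * sd(null[, j]) / sqrt(400))
  }
  # identical seed, identical null
  null2 <- freedman_lane_permute(y, x, n_perm = 400, seed = 5)
  expect_identical(null, null2)

  # nuisance-free design: FL equals plain group-label permutation
  x0 <- two_group_design(5, 5)
  y0 <- matrix(rnorm(10), 10, 1)
  fl <- freedman_lane_permute(y0, x0, n_perm = 50, seed = 11)
  set.seed(11)
  manual <- vapply(1:50, function(b) {
    idx <- sample.int(10)
    # permuting intercept-residualized y and adding the mean back is
    # exactly a permutation of y
    glm_tstats(y0[idx, , drop = FALSE], x0)$t
  }, numeric(1))
  expect_equal(drop(fl), manual, tolerance = 1e-12)
})

test_that("max-statistic p-values follow the add-one formula", {
  t_obs <- c(a = 5, b = 0.1)
  set.seed(3)
  t_null <- matrix(rnorm(1000 * 2), 1000, 2)
  res <- maxstat_pvalues(t_obs, t_null)
  # observed exceeding every null maximum sits at the formula boundary
  expect_equal(res$p_maxstat[1L], 1 / 1001, tolerance = 1e-12)
  expect_true(all(res$p_maxstat >= res$p_uncorrected))
  expect_true(all(res$q_fdr >= res$p_uncorrected))
  expect_true(all(res$p_maxstat > 0 & res$p_maxstat <= 1))

  # observed at the null median: corrected p near 0.5 for one outcome
  med <- stats::median(abs(t_null[, 1L]))
  res1 <- maxstat_pvalues(c(m = med),
                          t_null[, 1L, drop = FALSE])
  expect_equal(res1$p_maxstat, 0.5, tolerance = 0.05)
  # singleton family: corrected equals uncorrected
  expect_equal(res1$p_maxstat, res1$p_uncorrected, tolerance = 1e-12)

  # non-finite outcomes are dropped with a warning
  expect_warning(
    res2 <- maxstat_pvalues(c(a = 2, b = NaN), t_null),
    "dropped")
  expect_equal(nrow(res2), 1L)
})

test_that("doubling the permutation count barely moves corrected p", {
  ph <- fixed_pheno(8, 8)
  x <- design_matrix(ph)
  set.seed(21)
  y <- matrix(rnorm(16 * 4), 16, 4)
  obs <- glm_tstats(y, x)$t
  m <- 500L
  n1 <- freedman_lane_permute(y, x, m, seed = 9)
  n2 <- freedman_lane_permute(y, x, 2L * m, seed = 9)
  # the first m permutations are the same draw sequence
  expect_equal(n1, n2[seq_len(m), ], tolerance = 1e-12)
  p1 <- maxstat_pvalues(obs, n1)$p_maxstat
  p2 <- maxstat_pvalues(obs, n2)$p_maxstat
  expect_true(all(abs(p1 - p2) < 2 / (m + 1) + 0.05))
})

test_that("BH q-values match the step-up construction", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.037), 0.037)
  expect_equal(bh_fdr(c(1, 1, 1)), c(1, 1, 1))
  p <- c(0.001, 0.008, 0.039, 0.041, 0.042, 0.06, 0.074, 0.205)
  q <- bh_fdr(p)
  manual <- vapply(seq_along(p), function(i) {
    min(sort(p)[i:length(p)] * length(p) / (i:length(p)))
  }, numeric(1))[rank(p)]
  expect_equal(q, manual, tolerance = 1e-12)
})

test_that("metric_group_test reports the expected families", {
  coh <- small_cohort(n_patients = 6, n_controls = 6, n_timepoints = 60,
                      seed = 29)
  fc <- build_fc_stack(coh$timeseries)
  mets <- cohort_metrics(fc, densities = density_grid(0.2, 0.3, 0.02),
                         n_null = 2L, seed = 4)
  gt <- metric_group_test(mets, coh$phenotypes, n_perm = 199,
                          seed = 8, atlas = synthetic_atlas(14L))
  expect_setequal(gt$global$outcome,
                  c("Cp", "Lp", "gamma", "lambda", "sigma", "Eglob",
                    "Eloc", "assortativity"))
  expect_equal(nrow(gt$nodal), 3L * 14L)
  expect_true(all(c("degree", "betweenness", "efficiency") %in%
                    gt$nodal$metric))
  expect_true(all(gt$nodal$network %in% yeo7_networks))
  expect_true(all(gt$global$p_maxstat >= gt$global$p_uncorrected))
})

test_that("a diffuse clustering increase is detected by the max-stat test", {
  # denser within-network patient covariance (Cohen's d ~ 1.2 on the
  # Cp AUC at n = 35/40) should be flagged in >= 80% of runs
  at <- synthetic_atlas(40L)
  eb <- data.frame(network_a = yeo7_networks,
                   network_b = yeo7_networks, delta_r = 0.035)
  hits <- 0L
  for (r in 1:30) {
    coh <- sample_cohort(cohort_spec(atlas = at, n_patients = 35,
                                     n_controls = 40,
                                     effect_blocks = eb,
                                     seed = 130000 + r))
    fc <- build_fc_stack(coh$timeseries)
    mets <- cohort_metrics(fc, n_null = 2L, include_nodal = FALSE,
                           seed = 140000 + r)
    gt <- metric_group_test(mets, coh$phenotypes, n_perm = 1000L,
                            seed = 150000 + r)
    hits <- hits +
      (gt$global$p_maxstat[gt$global$outcome == "Cp"] < 0.05)
  }
  expect_gte(hits, 24L)
})
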