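test_that("hybrid test agrees with the reference single-feature tests", {
  set.seed(41)
  g <- factor(rep(1:3, c(8, 10, 7)))
  X <- matrix(rnorm(25 * 20), 25, 20)
  X[, 3] <- round(X[, 3], 1) # introduce ties to exercise the correction
  res <- hybrid_test(X, g)
  for (j in c(1, 2, 3, 10, 20)) {
    expect_equal(res$p_anova[j],
                 oneway.test(X[, j] ~ g, var.equal = TRUE)$p.value,
                 tolerance = 1e-12)
    expect_equal(res$p_kw[j], kruskal.test(X[, j], g)$p.value,
                 tolerance = 1e-12)
  }
  expect_equal(res$q_anova, p.adjust(res$p_anova, "BH"))
  expect_equal(res$mean_1, unname(colMeans(X[g == 1, ])))
})

test_that("hybrid significance requires both tests and a planted shift passes", {
  sim <- generate_cohort(cohort5_spec())
  pre <- run_preprocess(sim$intensities, preprocess_params(seed = 6))
  res <- hybrid_test(pre$log_matrix, sim$truth$labels)
  planted <- res$feature %in% sim$truth$differential_features
  expect_gt(mean(res$significant[planted]), 0.95)
  # permutation sanity on one planted feature: effect far beyond chance
  f <- which(planted)[1]
  x <- pre$log_matrix$values[, f]
  obs_f <- oneway.test(x ~ factor(sim$truth$labels),
                       var.equal = TRUE)$statistic
  perm_f <- sapply(1:500, function(i) {
    set.seed(i)
    oneway.test(x ~ factor(sample(sim$truth$labels)),
                var.equal = TRUE)$statistic
  })
  expect_lt(mean(perm_f >= obs_f), 0.001 + 1e-9)
})

test_that("an outlier that passes ANOVA alone is not called differential", {
  x <- c(0.2, 60, 0.1, -0.3, 0.4, -0.2, 0.3, 0, -0.4, 0.25, -0.15, 0.05)
  g <- rep(1:2, c(2, 10))
  res <- hybrid_test(matrix(x, ncol = 1), g)
  expect_lt(res$p_anova, 0.05)
  expect_gt(res$p_kw, 0.05)
  expect_false(res$significant)
  # constant features are degenerate, never significant
  cst <- hybrid_test(cbind(a = rep(3, 12), b = x), g)
  expect_true(cst$degenerate[1])
  expect_equal(cst$p_anova[1], 1)
  expect_equal(cst$p_kw[1], 1)
  expect_false(cst$significant[1])
  # under-filled groups are flagged loudly
  expect_warning(hybrid_test(matrix(rnorm(5), ncol = 1), c(1, 1, 1, 1, 2)),
                 "fewer than 2")
})

test_that("the intersection rule is conservative under the global null", {
  set.seed(17)
  g <- rep(1:3, each = 12)
  frac <- replicate(40, mean(hybrid_test(matrix(rnorm(36 * 150), 36), g,
                                         alpha = 0.05)$significant))
  expect_lte(mean(frac), 0.05)
})

test_that("BH adjustment reproduces the step-up worked example", {
  out <- adjust_bh(c(0.01, 0.02, 0.03, 0.04), 0.05)
  expect_equal(out$adjusted, rep(0.04, 4))
  expect_true(all(out$rejected))
  expect_equal(adjust_bh(1)$adjusted, 1)
  expect_false(adjust_bh(1)$rejected)
  expect_equal(adjust_bh(0.3)$adjusted, 0.3) # single p unchanged
  expect_length(adjust_bh(numeric(0))$adjusted, 0)
  # monotone in sorted order and permutation invariant
  set.seed(2)
  p <- runif(30)
  a <- adjust_bh(p)$adjusted
  expect_true(all(diff(a[order(p)]) >= -1e-12))
  perm <- sample(30)
  expect_equal(adjust_bh(p[perm])$adjusted, a[perm])
  expect_error(adjust_bh(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("exact KW p-values match full permutation enumeration at small n", {
  set.seed(23)
  for (sizes in list(c(3, 3), c(3, 2, 2), c(4, 3))) {
    x <- rnorm(sum(sizes))
    g <- rep(seq_along(sizes), sizes)
    ours <- kw_exact_p(x, g)
    oracle <- kw_perm_oracle(x, g)
    expect_equal(ours$statistic, oracle$statistic, tolerance = 1e-12)
    expect_equal(ours$p_exact, oracle$p_exact, tolerance = 1e-12)
    # the H statistic is the same one stats::kruskal.test reports
    expect_equal(ours$statistic, unname(kruskal.test(x, factor(g))$statistic),
                 tolerance = 1e-12)
  }
  # ties handled identically in both routes
  xt <- c(1, 1, 2, 3, 3, 4, 5)
  gt <- c(1, 1, 1, 2, 2, 3, 3)
  expect_equal(kw_exact_p(xt, gt)$p_exact, kw_perm_oracle(xt, gt)$p_exact)
})

test_that("clinical comparisons use Kruskal-Wallis with star codes", {
  set.seed(3)
  g <- rep(1:3, each = 10)
  cov <- data.frame(noise = rnorm(30), sep = g + rnorm(30, sd = 0.05),
                    label = sample(letters, 30, TRUE))
  expect_warning(res <- clinical_kw(cov, g), "non-numeric")
  expect_equal(res$variable, c("noise", "sep"))
  expect_lt(res$p[res$variable == "sep"], 0.001)
  expect_equal(res$stars[res$variable == "sep"], "***")
  expect_equal(res$p[1], kruskal.test(cov$noise, factor(g))$p.value)
  # two groups: KW coincides with the Mann-Whitney U test
  g2 <- rep(1:2, each = 5)
  x2 <- rnorm(10)
  kw <- kruskal.test(x2, factor(g2))$p.value
  mw <- wilcox.test(x2[g2 == 1], x2[g2 == 2], exact = FALSE,
                    correct = FALSE)$p.value
  expect_equal(clinical_kw(data.frame(v = x2), g2)$p, kw)
  expect_equal(kw, mw, tolerance = 1e-12)
})

test_that("Spearman correlations hit the monotone limits and flag constants", {
  x <- matrix(1:10, 10, 1, dimnames = list(NULL, "up"))
  cv <- data.frame(inc = (1:10)^2, dec = -(1:10)^3, flat = rep(1, 10))
  res <- spearman_covariates(x, cv)
  expect_equal(res$rho[res$covariate == "inc"], 1)
  expect_equal(res$rho[res$covariate == "dec"], -1)
  expect_true(is.na(res$rho[res$covariate == "flat"]))
  # synthetic covariates correlate positively with their driving features
  signs <- sapply(1:20, function(s) {
    sim <- generate_cohort(cohort_spec(seed = s, n_features = 60,
                                       effect_features_per_cluster = 10,
                                       censor_quantile = 0))
    drive <- rowMeans(sim$truth$log_abundances[, sim$truth$differential_features])
    r <- spearman_covariates(matrix(drive, ncol = 1,
                                    dimnames = list(NULL, "drive")),
                             sim$truth$covariates["C1"])
    r$rho[1]
  })
  expect_gt(mean(signs > 0), 0.9)
  # within-metabotype stratification returns one row per stratum
  g <- rep(1:2, each = 5)
  rs <- spearman_covariates(x, cv["inc"], groups = g)
  expect_equal(nrow(rs), 2)
  expect_equal(rs$rho, c(1, 1))
})

test_that("longitudinal contrasts detect a shifted responder group", {
  set.seed(61)
  g <- rep(1:2, each = 17)
  base <- rnorm(34, 120, 5)
  # group 2 loses 3 pooled SDs more than group 1 at both follow-ups
  m3 <- base - 5 - (g == 2) * 6 + rnorm(34, sd = 2)
  m6 <- base - 8 - (g == 2) * 6 + rnorm(34, sd = 2)
  outcomes <- cbind(baseline = base, month3 = m3, month6 = m6)
  res <- longitudinal_contrasts(outcomes, g)
  expect_equal(nrow(res), 2) # one pair x two timepoints
  expect_true(all(res$q < 0.05))
  expect_true(all(res$estimate > 0)) # group 1 minus group 2 deltas
  expect_equal(res$q, p.adjust(res$p, "BH"))
  # single timepoint, two groups: exactly one contrast, Welch by default
  one <- longitudinal_contrasts(outcomes[, 1:2], g)
  expect_equal(nrow(one), 1)
  expect_equal(one$p, t.test((m3 - base)[g == 1], (m3 - base)[g == 2])$p.value)
  # under-observed contrasts are skipped with a warning
  gg <- c(1, rep(2, 33))
  expect_warning(res2 <- longitudinal_contrasts(outcomes, gg), "skipped")
  expect_equal(nrow(res2), 0)
})
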