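test_that("prefilter keeps features at or below the missingness threshold", {
  # 8 samples: feature A fully observed, B missing 2/8 (25%), C missing 3/8
  vals <- matrix(10, 8, 3, dimnames = list(paste0("s", 1:8), c("A", "B", "C")))
  vals[1:2, 2] <- NA
  vals[1:3, 3] <- NA
  kept <- prefilter(intensity_matrix(vals), 0.25)
  expect_identical(colnames(kept), c("A", "B"))
  expect_equal(max(colMeans(is.na(kept))), 0.25)
  # fully observed matrix passes through unchanged
  full <- tiny_intensities()
  expect_equal(unclass(prefilter(full, 0.25)), unclass(full))
  # all features dropped is an explicit error
  allna <- intensity_matrix(matrix(c(NA, NA, 1, NA), 2, 2))
  expect_error(prefilter(allna, 0), "every feature")
  # retained set grows with the threshold
  m <- intensity_matrix(vals)
  sets <- lapply(c(0, 0.25, 0.5), function(q) colnames(prefilter(m, q)))
  expect_true(all(sets[[1]] %in% sets[[2]]))
  expect_true(all(sets[[2]] %in% sets[[3]]))
})

test_that("log transform records observed-data moments and rejects zeros", {
  m <- intensity_matrix(matrix(c(8, 1, NA, 4), 2, 2,
                               dimnames = list(c("s1", "s2"), c("f1", "f2"))))
  lm <- log_transform(m, 2)
  expect_equal(lm$values[1, 1], 3)
  expect_equal(lm$values[2, 1], 0)
  expect_true(is.na(lm$values[1, 2]))
  expect_equal(lm$mu, mean(c(3, 0, 2)))
  expect_equal(lm$sigma, sd(c(3, 0, 2)))
  bad <- intensity_matrix(matrix(c(0, 1, 2, 3), 2, 2,
                                 dimnames = list(c("s1", "s2"), c("f1", "f2"))))
  expect_error(log_transform(bad), "s1.*f1")
})

test_that("down-shifted imputation has the stated moments and touches only gaps", {
  set.seed(99) # fixture construction only; imputation seeds are explicit
  n_miss <- 1e5
  obs <- rnorm(2e4)
  obs <- (obs - mean(obs)) / sd(obs) * 2 + 10 # exact mean 10, sd 2
  vals <- c(obs, rep(NA_real_, n_miss))[sample.int(2e4 + n_miss)]
  m <- intensity_matrix(matrix(2^vals, 400, 300))
  lm <- log_transform(m, 2)
  expect_equal(lm$mu, 10, tolerance = 1e-12)
  expect_equal(lm$sigma, 2, tolerance = 1e-12)
  imp <- impute_downshift(lm, seed = 11)
  filled <- imp$values[imp$imputed]
  expect_length(filled, n_miss)
  expect_equal(mean(filled), 10 - 2.5 * 2, tolerance = 0.02)
  expect_equal((lm$mu - mean(filled)) / lm$sigma, 2.5, tolerance = 0.02)
  expect_equal(sd(filled) / lm$sigma, 0.5, tolerance = 0.02)
  # observed entries never change
  expect_identical(imp$values[imp$observed], lm$values[lm$observed])
  # deterministic given seed; different seed differs
  expect_identical(impute_downshift(lm, seed = 11)$values, imp$values)
  expect_false(identical(impute_downshift(lm, seed = 12)$values, imp$values))
})

test_that("imputation degenerate cases behave as contracted", {
  m <- intensity_matrix(matrix(c(2, 4, 8, 16), 2, 2))
  lm <- log_transform(m, 2)
  expect_identical(impute_downshift(lm, seed = 1), lm) # nothing to fill
  gap <- intensity_matrix(matrix(c(2, 4, NA, 16), 2, 2))
  lg <- log_transform(gap, 2)
  w0 <- impute_downshift(lg, width_sd = 0, seed = 1)
  expect_equal(w0$values[is.na(lg$values)], lg$mu - 2.5 * lg$sigma)
  flat <- intensity_matrix(matrix(c(4, 4, NA, 4), 2, 2))
  expect_error(impute_downshift(log_transform(flat, 2), seed = 1), "zero spread")
})

test_that("total-signal normalization equalizes totals at the minimum", {
  m <- intensity_matrix(matrix(c(60, 30, 40, 20), 2, 2,
                               dimnames = list(c("s1", "s2"), c("f1", "f2"))))
  nt <- normalize_tic(m)
  expect_equal(unname(nt$record$correction_factor), c(2, 1))
  expect_equal(nt$record$reference_total, 50)
  expect_equal(unname(rowSums(nt$matrix)), c(50, 50))
  expect_equal(min(nt$record$correction_factor), 1)
  # single sample and equal totals are identities
  one <- intensity_matrix(matrix(c(1, 2), 1, 2))
  expect_equal(unclass(normalize_tic(one)$matrix), unclass(one))
  # idempotence
  again <- normalize_tic(nt$matrix)
  expect_equal(unclass(again$matrix), unclass(nt$matrix), tolerance = 1e-12)
  # per-sample scaling equivariance on complete matrices: identical row
  # profiles, equal up to the constant set by the reference sample
  set.seed(5)
  X <- matrix(rexp(40, 1 / 100), 8, 5)
  D <- runif(8, 0.5, 2)
  a <- unclass(normalize_tic(intensity_matrix(X))$matrix)
  b <- unclass(normalize_tic(intensity_matrix(D * X))$matrix)
  expect_equal(a / rowSums(a), b / rowSums(b), tolerance = 1e-12)
  expect_equal(a * sum(b) / sum(a), b, tolerance = 1e-10)
  # zero-total sample errors
  z <- intensity_matrix(matrix(c(0, 1, 0, 2), 2, 2))
  expect_error(normalize_tic(z), "zero total")
})

test_that("run_preprocess composes the stage contracts", {
  sim <- generate_cohort(cohort5_spec())
  pre <- run_preprocess(sim$intensities, preprocess_params(seed = 3))
  expect_false(anyNA(pre$log_matrix$values))
  # raw-scale totals over originally observed entries all equal the minimum
  back <- 2^pre$log_matrix$values
  back[!pre$log_matrix$observed] <- NA
  tots <- rowSums(back, na.rm = TRUE)
  expect_equal(unname(tots), rep(min(tots), length(tots)), tolerance = 1e-9)
  # determinism
  pre2 <- run_preprocess(sim$intensities, preprocess_params(seed = 3))
  expect_identical(pre$log_matrix$values, pre2$log_matrix$values)
  # strict prefilter keeps only fully observed features
  strict <- run_preprocess(sim$intensities,
                           preprocess_params(max_missing_fraction = 0))
  expect_true(all(colSums(is.na(
    unclass(sim$intensities)[, strict$kept_features, drop = FALSE])) == 0))
  # the literal stage order (normalize after imputation) also runs clean
  alt <- run_preprocess(sim$intensities,
                        preprocess_params(normalize_stage = "after_impute_on_intensity",
                                          seed = 3))
  expect_false(anyNA(alt$log_matrix$values))
  expect_equal(unname(rowSums(2^alt$log_matrix$values)),
               rep(min(rowSums(2^alt$log_matrix$values)), 106),
               tolerance = 1e-9)
})
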