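#' Preprocessing parameters
#'
#' Bundles the matrix-level preprocessing knobs: the missingness prefilter
#' threshold (features with more than `max_missing_fraction` missing values
#' are dropped), the log base, and the down-shifted Gaussian imputation of
#' left-censored values, which draws each missing entry from
#' `Normal(mu - shift_sd * sigma, (width_sd * sigma)^2)` where `mu` and
#' `sigma` are the mean and SD of the observed log intensities — a small
#' distribution placed 2.5 SDs below the data mean with 0.5 SD width by
#' default, emulating the instrument's lower detection range.
#'
#' @param max_missing_fraction Per-feature missingness tolerance (default 0.25).
#' @param log_base Log base: 2 (default), `exp(1)` or 10.
#' @param shift_sd Down-shift of the imputation distribution, in observed
#'   SDs (default 2.5).
#' @param width_sd Width of the imputation distribution, in observed SDs
#'   (default 0.5).
#' @param mean_scope `"global"` (default; whole-matrix `mu`/`sigma` over
#'   observed entries) or `"per_feature"` (feature-wise moments, falling
#'   back to global ones for features with fewer than 3 observations).
#' @param normalize_stage `"raw_before_log"` (default: total-signal
#'   normalization of raw intensities before log/imputation) or
#'   `"after_impute_on_intensity"` (impute first, back-transform to the
#'   intensity scale, normalize, re-log).
#' @param seed Integer seed for the imputation draws.
#' @return An object of class `"preprocess_params"`.
#' @export
preprocess_params <- function(max_missing_fraction = 0.25,
                              log_base = 2,
                              shift_sd = 2.5,
                              width_sd = 0.5,
                              mean_scope = c("global", "per_feature"),
                              normalize_stage = c("raw_before_log",
                                                  "after_impute_on_intensity"),
                              seed = 1L) {
  if (max_missing_fraction < 0 || max_missing_fraction > 1)
    stopf("max_missing_fraction must be in [0, 1]")
  if (shift_sd < 0 || width_sd < 0)
    stopf("shift_sd and width_sd must be >= 0")
  structure(list(max_missing_fraction = max_missing_fraction,
                 log_base = log_base, shift_sd = shift_sd,
                 width_sd = width_sd,
                 mean_scope = match.arg(mean_scope),
                 normalize_stage = match.arg(normalize_stage),
                 seed = as.integer(seed)),
            class = "preprocess_params")
}

#' Drop features with excessive missingness
#'
#' Retains features whose fraction of missing values across samples is at
#' most `max_missing_fraction`; sample axis and feature order are unchanged.
#'
#' @param x Intensity matrix.
#' @param max_missing_fraction Tolerated missing fraction (default 0.25).
#' @return The filtered [intensity_matrix()].
#' @export
prefilter <- function(x, max_missing_fraction = 0.25) {
  m <- as_plain_matrix(x)
  keep <- colMeans(is.na(m)) <= max_missing_fraction
  if (!any(keep))
    stopf("prefilter removed every feature (max_missing_fraction = %g)",
          max_missing_fraction)
  intensity_matrix(m[, keep, drop = FALSE], rownames(m), colnames(m)[keep])
}

#' Log-transform observed intensities
#'
#' Transforms all observed entries to the log scale and records the global
#' mean `mu` and standard deviation `sigma` of the observed (pre-imputation)
#' log intensities, which anchor the down-shifted imputation.
#'
#' @param x Intensity matrix with strictly positive observed values.
#' @param log_base Log base (default 2).
#' @return An object of class `"log_matrix"`: list with `values` (log-scale
#'   matrix, `NA` where missing), `observed` (logical matrix, `TRUE` where
#'   originally measured), `imputed` (logical matrix, all `FALSE` here),
#'   `log_base`, `mu`, `sigma`.
#' @export
log_transform <- function(x, log_base = 2) {
  m <- as_plain_matrix(x)
  bad <- which(!is.na(m) & m <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0)
    stopf("non-positive intensity at sample '%s', feature '%s'; log undefined",
          rownames(m)[bad[1, 1]], colnames(m)[bad[1, 2]])
  v <- log(m, base = log_base)
  obs <- !is.na(m)
  structure(list(values = v, observed = obs,
                 imputed = matrix(FALSE, nrow(m), ncol(m), dimnames = dimnames(m)),
                 log_base = log_base,
                 mu = mean(v[obs]), sigma = stats::sd(v[obs])),
            class = "log_matrix")
}

#' @export
print.log_matrix <- function(x, ...) {
  cat(sprintf("<log_matrix> %d x %d (base %g), mu = %.3f, sigma = %.3f, %d imputed\n",
              nrow(x$values), ncol(x$values), x$log_base, x$mu, x$sigma,
              sum(x$imputed)))
  invisible(x)
}

#' Impute left-censored values from a down-shifted Gaussian
#'
#' Replaces each missing entry with an independent draw from
#' `Normal(mu - shift_sd * sigma, (width_sd * sigma)^2)`. Observed entries
#' are never modified. Deterministic given `seed`.
#'
#' @param logmat A `"log_matrix"` from [log_transform()].
#' @param shift_sd,width_sd Down-shift and width in observed SDs (defaults
#'   2.5 and 0.5).
#' @param seed Integer seed.
#' @param mean_scope `"global"` or `"per_feature"` (see [preprocess_params()]).
#' @return The `"log_matrix"` with no remaining `NA`s and `imputed` marking
#'   the filled entries.
#' @export
impute_downshift <- function(logmat, shift_sd = 2.5, width_sd = 0.5,
                             seed = 1L, mean_scope = "global") {
  stopifnot(inherits(logmat, "log_matrix"))
  miss <- which(!logmat$observed & is.na(logmat$values))
  if (length(miss) == 0) return(logmat)
  if (!is.finite(logmat$sigma) || logmat$sigma == 0)
    stopf("degenerate data: observed log intensities have zero spread")
  v <- logmat$values
  if (mean_scope == "per_feature") {
    fmu <- apply(v, 2, function(col) mean(col, na.rm = TRUE))
    fsd <- apply(v, 2, function(col) stats::sd(col, na.rm = TRUE))
    nobs <- colSums(logmat$observed)
    fmu[nobs < 3] <- logmat$mu
    fsd[nobs < 3 | !is.finite(fsd) | fsd == 0] <- logmat$sigma
    col_of <- ((miss - 1L) %/% nrow(v)) + 1L
    centre <- fmu[col_of] - shift_sd * fsd[col_of]
    width  <- width_sd * fsd[col_of]
  } else {
    centre <- logmat$mu - shift_sd * logmat$sigma
    width  <- width_sd * logmat$sigma
  }
  v[miss] <- with_seed(seed, stats::rnorm(length(miss), centre, width))
  logmat$values <- v
  logmat$imputed[miss] <- TRUE
  logmat
}

#' Total-signal (TIC) correction-factor normalization
#'
#' Each sample is a separate injection on the mass spectrometer, so total
#' loaded signal varies between samples. The total ion intensity of each
#' sample is summed over its observed entries, the sample with the lowest
#' total is taken as reference, and every sample is divided by its
#' correction factor `total_signal_i / lowest_total_signal`. After
#' normalization every sample's observed total equals the reference total.
#'
#' @param x Intensity matrix; every sample must have at least one observed,
#'   positive entry.
#' @return List with `matrix` (the normalized [intensity_matrix()]) and
#'   `record` (class `"normalization_record"`: per-sample `total_signal`,
#'   `correction_factor`, and the `reference_total`).
#' @export
normalize_tic <- function(x) {
  m <- as_plain_matrix(x)
  totals <- rowSums(m, na.rm = TRUE)
  if (any(totals <= 0))
    stopf("sample '%s' has zero total signal", rownames(m)[which(totals <= 0)[1]])
  ref <- min(totals)
  cf <- totals / ref
  norm <- m / cf
  record <- structure(list(total_signal = totals,
                           reference_total = ref,
                           correction_factor = cf),
                      class = "normalization_record")
  list(matrix = intensity_matrix(norm, rownames(m), colnames(m)),
       record = record)
}

#' @export
print.normalization_record <- function(x, ...) {
  cat(sprintf("<normalization_record> %d samples, reference total %.4g, correction factors %.3f..%.3f\n",
              length(x$total_signal), x$reference_total,
              min(x$correction_factor), max(x$correction_factor)))
  invisible(x)
}

#' Run the full preprocessing pipeline
#'
#' Applies, in order: missingness prefilter, total-signal normalization,
#' log transformation and down-shifted imputation. By default normalization
#' acts on raw intensities (totals are meaningful on the intensity scale and
#' are then untouched by imputed values); `normalize_stage =
#' "after_impute_on_intensity"` instead imputes first, back-transforms to
#' the intensity scale, normalizes and re-logs.
#'
#' @param x Intensity matrix.
#' @param params A [preprocess_params()].
#' @return List with `log_matrix` (analysis-ready, fully imputed),
#'   `normalization` (the `"normalization_record"`), and `kept_features`.
#' @examples
#' sim <- generate_cohort(cohort5_spec())
#' pre <- run_preprocess(sim$intensities, preprocess_params())
#' pre$log_matrix
#' @export
run_preprocess <- function(x, params = preprocess_params()) {
  stopifnot(inherits(params, "preprocess_params"))
  filt <- prefilter(x, params$max_missing_fraction)
  if (params$normalize_stage == "raw_before_log") {
    nt <- normalize_tic(filt)
    lm <- log_transform(nt$matrix, params$log_base)
    lm <- impute_downshift(lm, params$shift_sd, params$width_sd,
                           params$seed, params$mean_scope)
  } else {
    lm <- log_transform(filt, params$log_base)
    lm <- impute_downshift(lm, params$shift_sd, params$width_sd,
                           params$seed, params$mean_scope)
    back <- intensity_matrix(params$log_base^lm$values,
                             rownames(lm$values), colnames(lm$values))
    nt <- normalize_tic(back)
    lm$values <- log(as_plain_matrix(nt$matrix), base = params$log_base)
  }
  list(log_matrix = lm, normalization = nt$record,
       kept_features = colnames(lm$values))
}
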