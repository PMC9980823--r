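#' Specify a synthetic metabolomics cohort
#'
#' Defines the generative model for a synthetic cohort: log-normal metabolite
#' intensities with planted cluster structure, left-censored (below detection
#' limit) missingness, and per-sample injection-scaling factors. On the log2
#' scale, sample j in cluster c has
#' `x[j, f] = base_mean + delta[c, f] + Normal(0, base_sd^2)` where the effect
#' matrix `delta` shifts a disjoint block of `effect_features_per_cluster`
#' features per cluster by `effect_size * base_sd`. Raw intensities are
#' `2^x * s[j]` with `s[j] ~ Uniform(scale_low, scale_high)`, and entries
#' below the global `censor_quantile` of the pre-masking intensity
#' distribution are masked as missing.
#'
#' @param n_samples Number of samples; must equal `sum(cluster_sizes)`.
#' @param n_features Number of metabolite features.
#' @param cluster_sizes Integer vector of planted group sizes.
#' @param effect_features_per_cluster Number of features shifted per cluster
#'   (blocks are disjoint; `K * effect_features_per_cluster <= n_features`).
#' @param effect_size Cluster mean shift in units of the within-cluster SD,
#'   on the log scale.
#' @param base_mean,base_sd Log2-scale grand mean and within-cluster SD
#'   (`base_sd > 0`).
#' @param censor_quantile Fraction of the intensity distribution masked as
#'   below the detection limit, in `[0, 1]`.
#' @param scale_low,scale_high Bounds of the uniform per-sample injection
#'   factors (`0 < scale_low <= scale_high`).
#' @param covariate_loading Strength with which synthetic clinical covariates
#'   load on the mean of each sample's differential features.
#' @param seed Integer seed; the cohort is a deterministic function of the
#'   spec including the seed.
#' @return An object of class `"cohort_spec"`.
#' @seealso [cohort5_spec()] for the frozen default scenario,
#'   [generate_cohort()].
#' @export
cohort_spec <- function(n_samples = sum(cluster_sizes),
                        n_features = 300L,
                        cluster_sizes = c(17L, 29L, 25L, 18L, 17L),
                        effect_features_per_cluster = 40L,
                        effect_size = 3,
                        base_mean = 20,
                        base_sd = 2,
                        censor_quantile = 0.05,
                        scale_low = 0.7,
                        scale_high = 1.3,
                        covariate_loading = 1,
                        seed = 42L) {
  spec <- list(n_samples = as.integer(n_samples),
               n_features = as.integer(n_features),
               cluster_sizes = as.integer(cluster_sizes),
               effect_features_per_cluster = as.integer(effect_features_per_cluster),
               effect_size = effect_size, base_mean = base_mean,
               base_sd = base_sd, censor_quantile = censor_quantile,
               scale_low = scale_low, scale_high = scale_high,
               covariate_loading = covariate_loading, seed = as.integer(seed))
  if (sum(spec$cluster_sizes) != spec$n_samples)
    stopf("invalid cohort spec: sum(cluster_sizes) (%d) != n_samples (%d)",
          sum(spec$cluster_sizes), spec$n_samples)
  K <- length(spec$cluster_sizes)
  if (K * spec$effect_features_per_cluster > spec$n_features)
    stopf("invalid cohort spec: effect_features_per_cluster * n_clusters exceeds n_features")
  if (spec$base_sd <= 0)
    stopf("invalid cohort spec: base_sd must be > 0")
  if (spec$censor_quantile < 0 || spec$censor_quantile > 1)
    stopf("invalid cohort spec: censor_quantile must be in [0, 1]")
  if (spec$scale_low <= 0 || spec$scale_low > spec$scale_high)
    stopf("invalid cohort spec: need 0 < scale_low <= scale_high")
  if (any(spec$cluster_sizes < 1))
    stopf("invalid cohort spec: cluster_sizes must be positive")
  class(spec) <- "cohort_spec"
  spec
}

#' The frozen "cohort5" scenario
#'
#' Five planted metabotypes with sizes 17/29/25/18/17 (106 samples), 300
#' log-normal features, 40 differential features per cluster shifted by 3
#' within-cluster SDs, 5% left-censoring and Uniform(0.7, 1.3) injection
#' factors. This is the package's reference scenario for end-to-end
#' validation of the metabotyping pipeline.
#'
#' @param seed Integer seed (default 42).
#' @return A [cohort_spec()].
#' @export
cohort5_spec <- function(seed = 42L) cohort_spec(seed = seed)

#' Generate a synthetic cohort
#'
#' Draws a cohort from the generative model in [cohort_spec()] and returns
#' both the observable intensity matrix (with censored entries masked) and
#' the ground truth used to plant it.
#'
#' @param spec A [cohort_spec()].
#' @return A list with components:
#'   \describe{
#'     \item{intensities}{[intensity_matrix()] with left-censored entries as `NA`.}
#'     \item{truth}{Class `"cohort_truth"`: `labels` (named integer vector of
#'       planted cluster ids), `effect_matrix` (clusters x features log2
#'       shifts), `differential_features` (ids of features with any planted
#'       shift), `censor_threshold` (intensity-scale detection limit),
#'       `injection_factors`, `covariates` (data.frame, see
#'       [make_covariates()]), and `log_abundances` (the uncensored log2
#'       matrix before injection scaling).}
#'   }
#' @examples
#' sim <- generate_cohort(cohort5_spec())
#' table(sim$truth$labels)
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  K <- length(spec$cluster_sizes)
  n <- spec$n_samples; F <- spec$n_features
  labels <- rep(seq_len(K), spec$cluster_sizes)
  sample_ids  <- sprintf("S%03d", seq_len(n))
  feature_ids <- sprintf("F%04d", seq_len(F))
  names(labels) <- sample_ids

  delta <- matrix(0, K, F, dimnames = list(NULL, feature_ids))
  m <- spec$effect_features_per_cluster
  if (m > 0 && spec$effect_size != 0)
    for (c in seq_len(K))
      delta[c, ((c - 1L) * m + 1L):(c * m)] <- spec$effect_size * spec$base_sd

  out <- with_seed(spec$seed, {
    x <- spec$base_mean + delta[labels, , drop = FALSE] +
      matrix(stats::rnorm(n * F, 0, spec$base_sd), n, F)
    s <- stats::runif(n, spec$scale_low, spec$scale_high)
    list(x = x, s = s)
  })
  dimnames(out$x) <- list(sample_ids, feature_ids)
  names(out$s) <- sample_ids

  raw <- intensity_matrix(2^out$x * out$s, sample_ids, feature_ids)
  censored <- apply_censoring(raw, spec$censor_quantile)

  diff_feats <- feature_ids[colSums(abs(delta)) > 0]
  truth <- structure(list(
    labels = labels,
    effect_matrix = delta,
    differential_features = diff_feats,
    censor_threshold = attr(censored, "censor_threshold"),
    injection_factors = out$s,
    log_abundances = out$x
  ), class = "cohort_truth")
  truth$covariates <- make_covariates(truth, spec)
  list(intensities = censored, truth = truth)
}

#' Left-censor an intensity matrix at a global quantile
#'
#' Models an instrument detection limit: all entries strictly below the
#' global `censor_quantile` of the observed intensity distribution are
#' masked as missing. With `censor_quantile = 0` no entry is masked; with
#' `censor_quantile = 1` the detection limit lies above the whole measured
#' range and every entry is masked.
#'
#' @param x Intensity matrix (may already contain `NA`s, which are ignored
#'   when locating the threshold).
#' @param censor_quantile Quantile in `[0, 1]`.
#' @return The censored [intensity_matrix()], with the intensity-scale
#'   threshold attached as attribute `"censor_threshold"`.
#' @export
apply_censoring <- function(x, censor_quantile) {
  if (!is.numeric(censor_quantile) || censor_quantile < 0 || censor_quantile > 1)
    stopf("censor_quantile must be in [0, 1]")
  m <- as_plain_matrix(x)
  tau <- if (censor_quantile >= 1) Inf
         else stats::quantile(m, censor_quantile, na.rm = TRUE, names = FALSE)
  m[!is.na(m) & m < tau] <- NA_real_
  out <- intensity_matrix(m, rownames(m), colnames(m))
  attr(out, "censor_threshold") <- tau
  out
}

#' Generate synthetic clinical covariates
#'
#' Each covariate is a linear readout of the sample's metabolic state plus
#' Gaussian noise: `covariate = covariate_loading * mean(log2 abundance over
#' the differential features) + Normal(0, 1)`. With `covariate_loading = 0`
#' covariates are independent of the metabolome.
#'
#' @param truth A `"cohort_truth"` object from [generate_cohort()].
#' @param spec The matching [cohort_spec()].
#' @param n_covariates Number of covariate columns (default 3).
#' @return data.frame of `n_samples` rows, columns `C1..Cn`, rownames the
#'   sample ids; deterministic given `spec$seed`.
#' @export
make_covariates <- function(truth, spec, n_covariates = 3L) {
  stopifnot(inherits(truth, "cohort_truth"), inherits(spec, "cohort_spec"))
  n <- spec$n_samples
  drive <- if (length(truth$differential_features))
    rowMeans(truth$log_abundances[, truth$differential_features, drop = FALSE])
  else rep(0, n)
  cov <- with_seed(spec$seed + 1L, {
    vapply(seq_len(n_covariates),
           function(j) spec$covariate_loading * drive + stats::rnorm(n),
           numeric(n))
  })
  colnames(cov) <- sprintf("C%d", seq_len(n_covariates))
  as.data.frame(cov, row.names = names(truth$labels))
}
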