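#' Run the full metabotyping pipeline
#'
#' Orchestrates the end-to-end analysis: (optional) synthetic-cohort
#' simulation or matrix input, preprocessing, SOM fitting, cluster-number
#' selection on the codebook, sample-level metabotype assignment, and
#' differential statistics. All stage seeds derive deterministically from
#' the global `seed` (stage i uses `seed * 10 + i`), so a run is a pure
#' function of its inputs and configuration.
#'
#' @param input An [intensity_matrix()], a path readable by
#'   [read_intensity_matrix()], or `NULL` to simulate from `spec`.
#' @param spec [cohort_spec()] used when `input` is `NULL` (default the
#'   frozen cohort5 scenario).
#' @param covariates Optional data.frame of clinical covariates (defaults
#'   to the simulated ones when simulating).
#' @param preprocess A [preprocess_params()]; its seed is overridden by the
#'   derived stage seed.
#' @param som A [som_config()]; seed overridden likewise.
#' @param cluster A [cluster_config()]; seed overridden likewise.
#' @param alpha Significance level for the hybrid differential test.
#' @param seed Global integer seed.
#' @param out_dir Optional directory; when given, stage outputs (intensity
#'   TSV, preprocessed TSV, model JSON, selection trace TSV, assignment TSV,
#'   differential-feature TSV) and a JSON run manifest with per-file MD5
#'   hashes are written there.
#' @return List of class `"somtyper_run"` with `intensities`, `truth` (when
#'   simulated), `preprocessed`, `model`, `selection`, `metabotypes`,
#'   `diff_features`, `clinical` (when covariates are available), and
#'   `manifest`.
#' @examples
#' run <- run_pipeline(seed = 42)
#' run$selection$chosen_k
#' run$metabotypes
#' @export
run_pipeline <- function(input = NULL, spec = cohort5_spec(),
                         covariates = NULL,
                         preprocess = preprocess_params(),
                         som = som_config(),
                         cluster = cluster_config(restarts = 25L, k_max = 15L),
                         alpha = 0.05, seed = 42L, out_dir = NULL) {
  seed <- as.integer(seed)
  truth <- NULL
  if (is.null(input)) {
    spec$seed <- seed * 10L + 1L
    sim <- generate_cohort(spec)
    intens <- sim$intensities
    truth <- sim$truth
    if (is.null(covariates)) covariates <- truth$covariates
  } else if (is.character(input)) {
    if (!file.exists(input)) stopf("input path does not exist: %s", input)
    intens <- read_intensity_matrix(input)
  } else {
    intens <- intensity_matrix(as_plain_matrix(input))
  }

  preprocess$seed <- seed * 10L + 2L
  pre <- run_preprocess(intens, preprocess)

  som$seed <- seed * 10L + 3L
  model <- som_fit(pre$log_matrix, som)

  cluster$seed <- seed * 10L + 4L
  sel <- select_k(model$codebook, cluster)
  mtypes <- assign_metabotypes(sel$partition, model$bmu)

  diff <- hybrid_test(pre$log_matrix, mtypes$assignments$metabotype, alpha)
  clinical <- if (!is.null(covariates))
    clinical_kw(covariates, mtypes$assignments$metabotype)

  run <- structure(list(intensities = intens, truth = truth,
                        preprocessed = pre, model = model, selection = sel,
                        metabotypes = mtypes, diff_features = diff,
                        clinical = clinical, seed = seed),
                   class = "somtyper_run")
  if (!is.null(out_dir)) run$manifest <- write_run(run, out_dir)
  run
}

#' @export
print.somtyper_run <- function(x, ...) {
  cat(sprintf("<somtyper_run> seed %d\n", x$seed))
  cat(sprintf("  %d samples x %d features (%d after prefilter)\n",
              nrow(x$intensities), ncol(x$intensities),
              length(x$preprocessed$kept_features)))
  cat(sprintf("  map %d x %d, chosen k = %d, metabotype sizes: %s\n",
              x$model$grid[1], x$model$grid[2], x$selection$chosen_k,
              paste(x$metabotypes$sizes, collapse = "/")))
  cat(sprintf("  %d differential features at the hybrid rule\n",
              sum(x$diff_features$significant)))
  invisible(x)
}

# Write stage artifacts plus a manifest of MD5 content hashes.
write_run <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(intensities = file.path(out_dir, "intensities.tsv"),
             preprocessed = file.path(out_dir, "preprocessed.tsv"),
             model = file.path(out_dir, "som_model.json"),
             trace = file.path(out_dir, "selection_trace.tsv"),
             assignments = file.path(out_dir, "metabotypes.tsv"),
             diff = file.path(out_dir, "diff_features.tsv"))
  write_intensity_matrix(run$intensities, paths["intensities"])
  lm <- run$preprocessed$log_matrix$values
  utils::write.table(data.frame(sample_id = rownames(lm), lm,
                                check.names = FALSE),
                     paths["preprocessed"], sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  som_write_json(run$model, paths["model"])
  utils::write.table(run$selection$trace, paths["trace"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(run$metabotypes$assignments, paths["assignments"],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(run$diff_features, paths["diff"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  manifest <- list(package_version = as.character(utils::packageVersion("somtyper")),
                   seed = run$seed,
                   timestamp = format(Sys.time(), tz = "UTC"),
                   chosen_k = run$selection$chosen_k,
                   hashes = as.list(tools::md5sum(unname(paths))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest
}
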