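#' Construct a sample-by-feature intensity matrix
#'
#' The package's basic container for untargeted metabolomics data: a numeric
#' matrix with samples as rows and features (metabolites) as columns. Missing
#' entries — intensities below the instrument's detection limit — are stored
#' as `NA`; all observed entries must be finite and non-negative.
#'
#' @param values Numeric matrix (samples x features). `NA` marks a missing
#'   (censored) measurement.
#' @param sample_ids,feature_ids Optional character vectors of unique row and
#'   column identifiers; default to existing dimnames or generated ids.
#' @return A numeric matrix of class `"intensity_matrix"` with sample ids as
#'   rownames and feature ids as colnames.
#' @examples
#' m <- intensity_matrix(matrix(c(1, 2, NA, 4), 2, 2))
#' is.na(m)
#' @export
intensity_matrix <- function(values, sample_ids = NULL, feature_ids = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stopf("`values` must be a numeric matrix")
  sample_ids  <- sample_ids  %||% rownames(values) %||%
    sprintf("S%03d", seq_len(nrow(values)))
  feature_ids <- feature_ids %||% colnames(values) %||%
    sprintf("F%04d", seq_len(ncol(values)))
  if (anyDuplicated(sample_ids))  stopf("duplicate sample ids")
  if (anyDuplicated(feature_ids)) stopf("duplicate feature ids")
  if (length(sample_ids) != nrow(values) || length(feature_ids) != ncol(values))
    stopf("id lengths do not match matrix dimensions")
  obs <- values[!is.na(values)]
  if (any(!is.finite(obs))) stopf("observed intensities must be finite")
  if (any(obs < 0)) stopf("observed intensities must be non-negative")
  dimnames(values) <- list(sample_ids, feature_ids)
  class(values) <- c("intensity_matrix", class(values))
  values
}

#' @export
print.intensity_matrix <- function(x, ...) {
  cat(sprintf("<intensity_matrix> %d samples x %d features, %.1f%% missing\n",
              nrow(x), ncol(x), 100 * mean(is.na(x))))
  invisible(x)
}

# Strip the class so plain-matrix semantics apply internally.
as_plain_matrix <- function(x) {
  if (inherits(x, "log_matrix")) return(x$values)
  y <- unclass(x)
  attr(y, "censor_threshold") <- NULL
  y
}

#' Read an intensity matrix from delimited text
#'
#' Expects a header row of feature ids and a first column of sample ids.
#' Empty cells, `NA` and `NaN` are read as missing values. The delimiter is
#' auto-detected (tab or comma) unless given.
#'
#' @param path File path.
#' @param sep Field delimiter; `NULL` (default) auto-detects `"\t"` vs `","`
#'   from the header line.
#' @return An [intensity_matrix()].
#' @export
read_intensity_matrix <- function(path, sep = NULL) {
  if (!file.exists(path)) stopf("input file not found: %s", path)
  header <- readLines(path, n = 1L)
  if (is.null(sep))
    sep <- if (lengths(regmatches(header, gregexpr("\t", header))) > 0) "\t" else ","
  raw <- utils::read.table(path, sep = sep, header = TRUE, row.names = NULL,
                           colClasses = "character", check.names = FALSE,
                           quote = "\"", comment.char = "")
  if (ncol(raw) < 2) stopf("expected a sample-id column plus >=1 feature column")
  ids <- raw[[1]]
  if (anyDuplicated(ids)) stopf("duplicate sample id in %s: %s", path,
                                ids[duplicated(ids)][1])
  feats <- colnames(raw)[-1]
  if (anyDuplicated(feats)) stopf("duplicate feature id in %s: %s", path,
                                  feats[duplicated(feats)][1])
  vals <- matrix(NA_real_, nrow(raw), length(feats))
  for (j in seq_along(feats)) {
    cell <- trimws(raw[[j + 1]])
    miss <- cell == "" | toupper(cell) %in% c("NA", "NAN")
    num <- suppressWarnings(as.numeric(cell))
    bad <- which(!miss & is.na(num))
    if (length(bad))
      stopf("non-numeric cell at line %d, column '%s': '%s'",
            bad[1] + 1L, feats[j], cell[bad[1]])
    num[miss] <- NA_real_
    vals[, j] <- num
  }
  intensity_matrix(vals, sample_ids = ids, feature_ids = feats)
}

#' Write an intensity matrix as delimited text
#'
#' Missing entries are written as empty cells; the first column holds sample
#' ids under the header `sample_id`. [read_intensity_matrix()] round-trips
#' the result exactly.
#'
#' @param x Intensity matrix.
#' @param path Output path.
#' @param sep Field delimiter (default tab).
#' @export
write_intensity_matrix <- function(x, path, sep = "\t") {
  m <- as_plain_matrix(x)
  df <- data.frame(sample_id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}
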