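#' Self-organizing map configuration
#'
#' Training schedule and geometry for the batch SOM. Batch training runs a
#' rough phase followed by a fine phase; within each phase the Gaussian
#' neighborhood radius decays linearly between the stated endpoints.
#'
#' @param grid Optional `c(rows, cols)`; when `NULL` the grid is sized by
#'   the `5 * sqrt(N)` heuristic via [som_grid_size()].
#' @param aspect_ratio Target rows:cols ratio for the heuristic (default 1.25).
#' @param lattice `"hexagonal"` (default) or `"rectangular"`.
#' @param rough_epochs,fine_epochs Epoch counts for the two phases
#'   (defaults 10 and 40).
#' @param radius_start Initial neighborhood radius in lattice units;
#'   defaults to `max(rows, cols) / 4` (at least `radius_rough_end`).
#' @param radius_rough_end,radius_fine_end Radii at the end of the rough and
#'   fine phases (both default 1, the classic batch-SOM schedule: the fine
#'   phase refines at unit radius so neighboring units keep sharing weight
#'   and the codebook stays smooth; shrink `radius_fine_end` toward 0 for a
#'   near-k-means quantization instead).
#' @param feature_standardize Z-score each feature by its training mean/SD
#'   before Euclidean comparison (default `TRUE`); the stored statistics are
#'   reused when projecting new samples.
#' @param seed Integer seed (used only by the random-initialization fallback
#'   for rank-deficient data).
#' @return An object of class `"som_config"`.
#' @export
som_config <- function(grid = NULL, aspect_ratio = 1.25,
                       lattice = c("hexagonal", "rectangular"),
                       rough_epochs = 10L, fine_epochs = 40L,
                       radius_start = NULL, radius_rough_end = 1,
                       radius_fine_end = 1,
                       feature_standardize = TRUE, seed = 1L) {
  lattice <- match.arg(lattice)
  if (rough_epochs < 1 || fine_epochs < 1) stopf("epoch counts must be >= 1")
  if (radius_fine_end <= 0) stopf("radius_fine_end must be > 0")
  if (radius_rough_end < radius_fine_end)
    stopf("need radius_rough_end >= radius_fine_end")
  structure(list(grid = if (!is.null(grid)) as.integer(grid),
                 aspect_ratio = aspect_ratio, lattice = lattice,
                 rough_epochs = as.integer(rough_epochs),
                 fine_epochs = as.integer(fine_epochs),
                 radius_start = radius_start,
                 radius_rough_end = radius_rough_end,
                 radius_fine_end = radius_fine_end,
                 feature_standardize = isTRUE(feature_standardize),
                 seed = as.integer(seed)),
            class = "som_config")
}

#' Heuristic map sizing
#'
#' Number of map units from the classic heuristic `munits = round(5 *
#' sqrt(n_samples))`, split into a rows-by-cols grid near the requested
#' aspect ratio. For hexagonal lattices the row count absorbs the
#' `sqrt(0.75)` vertical pitch of the hex packing.
#'
#' @param n_samples Number of input vectors (>= 2).
#' @param aspect_ratio Target rows:cols ratio (default 1).
#' @param lattice `"hexagonal"` (default) or `"rectangular"`.
#' @return Integer vector `c(rows, cols)`.
#' @examples
#' som_grid_size(106) # 7 x 7
#' @export
som_grid_size <- function(n_samples, aspect_ratio = 1,
                          lattice = c("hexagonal", "rectangular")) {
  lattice <- match.arg(lattice)
  if (n_samples < 2) stopf("need at least 2 samples to size a map")
  munits <- round(5 * sqrt(n_samples))
  f <- if (lattice == "hexagonal") sqrt(0.75) else 1
  rows <- max(1L, as.integer(round(sqrt(munits / aspect_ratio * f))))
  cols <- max(1L, as.integer(round(munits / rows)))
  c(rows = rows, cols = cols)
}

# Cartesian unit positions, units numbered row-major starting at unit 1.
# Hexagonal rows are vertically spaced by sqrt(3)/2 with every second row
# offset +0.5 in x, so lattice neighbors sit at distance 1.
som_unit_positions <- function(rows, cols, lattice = "hexagonal") {
  r <- rep(seq_len(rows), each = cols) - 1L
  c <- rep(seq_len(cols), times = rows) - 1L
  if (lattice == "hexagonal")
    cbind(x = c + 0.5 * (r %% 2), y = r * sqrt(3) / 2)
  else cbind(x = as.numeric(c), y = as.numeric(r))
}

# Squared Euclidean distances between all rows of a and b (complete data).
cross_dist2 <- function(a, b) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  pmax(d2, 0)
}

#' Initialize a codebook along the data's principal plane
#'
#' Linear initialization: grid coordinates are mapped onto the span of the
#' first two principal axes of the (standardized) data, scaled by the
#' corresponding standard deviations. Deterministic for data of rank >= 2;
#' rank-deficient data fall back to seeded sampling of data rows.
#'
#' @param data Numeric sample-by-feature matrix (>= 2 samples).
#' @param positions Unit position matrix from the map geometry.
#' @param seed Seed for the random fallback.
#' @return Units-by-features codebook matrix.
#' @export
som_init_codebook <- function(data, positions, seed = 1L) {
  if (nrow(data) < 2) stopf("need at least 2 samples to initialize a codebook")
  U <- nrow(positions)
  centre <- colMeans(data)
  pc <- tryCatch(stats::prcomp(data, center = TRUE, scale. = FALSE),
                 error = function(e) NULL)
  rank2 <- !is.null(pc) && length(pc$sdev) >= 2 && pc$sdev[2] > 1e-10
  if (rank2) {
    # grid coordinates rescaled to [-1, 1] on each axis
    co <- positions * 0
    for (j in 1:2) {
      p <- positions[, j]
      if (diff(range(p)) > 0) co[, j] <- 2 * (p - min(p)) / diff(range(p)) - 1
    }
    cb <- matrix(centre, U, ncol(data), byrow = TRUE) +
      co[, 1] %o% (pc$rotation[, 1] * pc$sdev[1]) +
      co[, 2] %o% (pc$rotation[, 2] * pc$sdev[2])
  } else {
    cb <- with_seed(seed, {
      idx <- sample.int(nrow(data), U, replace = TRUE)
      data[idx, , drop = FALSE] +
        matrix(stats::rnorm(U * ncol(data), 0, 1e-4), U)
    })
  }
  dimnames(cb) <- list(NULL, colnames(data))
  cb
}

#' Best-matching unit of a single vector
#'
#' Returns the index of the codebook row with smallest Euclidean distance to
#' `x`, computed over the non-missing components of `x`; exact ties resolve
#' to the lowest unit index.
#'
#' @param codebook Units-by-features matrix.
#' @param x Feature vector, possibly with `NA` (masked) components.
#' @return Integer unit index (1-based) with attribute `"distance"`.
#' @export
find_bmu <- function(codebook, x) {
  ok <- !is.na(x)
  if (!any(ok)) stopf("cannot find a BMU: all components are masked")
  d2 <- colSums((t(codebook[, ok, drop = FALSE]) - x[ok])^2)
  i <- which.min(d2) # which.min takes the first minimum: lowest-index tie rule
  structure(as.integer(i), distance = sqrt(d2[i]))
}

# BMUs for all rows of X; fast path for complete data.
find_bmu_all <- function(codebook, X) {
  if (!anyNA(X)) {
    d2 <- cross_dist2(X, codebook)
    bmu <- max.col(-d2, ties.method = "first")
    dist <- sqrt(d2[cbind(seq_len(nrow(X)), bmu)])
  } else {
    bmu <- integer(nrow(X)); dist <- numeric(nrow(X))
    for (j in seq_len(nrow(X))) {
      b <- find_bmu(codebook, X[j, ])
      bmu[j] <- b; dist[j] <- attr(b, "distance")
    }
  }
  list(bmu = bmu, distance = dist)
}

#' One batch-training epoch
#'
#' Recomputes every codebook vector as the neighborhood-weighted average of
#' all samples: `m_i = sum_j h(c_j, i) x_j / sum_j h(c_j, i)` with Gaussian
#' neighborhood `h(c, i) = exp(-d(r_c, r_i)^2 / (2 sigma^2))` on the unit
#' positions and `c_j` the BMU of sample `j` under the current codebook.
#' Units receiving no weight keep their previous vector. As `sigma -> 0`
#' the update collapses to per-BMU sample means (the k-means fixed-point
#' form).
#'
#' @param codebook Current units-by-features codebook.
#' @param X Complete sample-by-feature matrix.
#' @param positions Unit positions.
#' @param sigma Neighborhood radius (> 0, lattice units).
#' @return Updated codebook.
#' @export
som_epoch <- function(codebook, X, positions, sigma) {
  a <- find_bmu_all(codebook, X)
  D2 <- cross_dist2(positions, positions)
  H <- exp(-D2[a$bmu, , drop = FALSE] / (2 * sigma^2)) # samples x units
  den <- colSums(H)
  num <- crossprod(H, X)
  upd <- den > 1e-300
  codebook[upd, ] <- num[upd, , drop = FALSE] / den[upd]
  codebook
}

#' Batch-train a self-organizing map
#'
#' Standardizes features (optionally), initializes the codebook along the
#' data's principal plane, and runs rough then fine batch-training phases
#' with a linearly decaying Gaussian neighborhood. Batch training is
#' order-free: permuting the samples leaves the trained codebook unchanged.
#'
#' @param data Sample-by-feature matrix or a `"log_matrix"` from
#'   [run_preprocess()]. Must be complete (impute first).
#' @param config A [som_config()].
#' @return An object of class `"som_model"`: `codebook` (units x features),
#'   `positions`, `grid`, `lattice`, `config`, `feature_ids`,
#'   `feature_mean`/`feature_sd` (standardization statistics, reused by
#'   [som_project()]), `bmu` (training assignments, a data.frame of
#'   `sample_id`, `bmu`, `distance`), and `quality`
#'   (`quantization_error`, `topographic_error`, plus the rough-phase
#'   quantization error `qe_rough`).
#' @examples
#' sim <- generate_cohort(cohort5_spec())
#' pre <- run_preprocess(sim$intensities)
#' model <- som_fit(pre$log_matrix, som_config(seed = 1))
#' model
#' @export
som_fit <- function(data, config = som_config()) {
  stopifnot(inherits(config, "som_config"))
  X <- as_plain_matrix(data)
  if (anyNA(X)) stopf("training data must be complete; impute missing values first")
  if (any(!is.finite(X))) stopf("training data must be finite")
  if (nrow(X) < 2) stopf("need at least 2 samples to train a map")

  fmean <- colMeans(X)
  fsd <- apply(X, 2, stats::sd)
  fsd[!is.finite(fsd) | fsd == 0] <- 1
  Z <- if (config$feature_standardize) sweep(sweep(X, 2, fmean), 2, fsd, "/") else X

  grid <- config$grid %||% som_grid_size(nrow(X), config$aspect_ratio, config$lattice)
  rows <- grid[1]; cols <- grid[2]
  positions <- som_unit_positions(rows, cols, config$lattice)
  cb <- som_init_codebook(Z, positions, config$seed)

  r0 <- config$radius_start %||% max(max(rows, cols) / 4, config$radius_rough_end)
  rough <- seq(r0, config$radius_rough_end, length.out = config$rough_epochs)
  fine  <- seq(config$radius_rough_end, config$radius_fine_end,
               length.out = config$fine_epochs)
  for (sigma in rough) cb <- som_epoch(cb, Z, positions, sigma)
  qe_rough <- mean(find_bmu_all(cb, Z)$distance)
  for (sigma in fine) cb <- som_epoch(cb, Z, positions, sigma)

  assign <- find_bmu_all(cb, Z)
  model <- structure(list(codebook = cb, positions = positions,
                          grid = c(rows = rows, cols = cols),
                          lattice = config$lattice, config = config,
                          feature_ids = colnames(X),
                          feature_mean = fmean, feature_sd = fsd,
                          bmu = data.frame(sample_id = rownames(X) %||%
                                             sprintf("S%03d", seq_len(nrow(X))),
                                           bmu = assign$bmu,
                                           distance = assign$distance)),
                     class = "som_model")
  q <- som_quality(model, X)
  model$quality <- c(q, qe_rough = qe_rough)
  model
}

#' @export
print.som_model <- function(x, ...) {
  cat(sprintf("<som_model> %d x %d %s grid (%d units), %d features\n",
              x$grid[1], x$grid[2], x$lattice,
              nrow(x$codebook), ncol(x$codebook)))
  cat(sprintf("  quantization error %.4f, topographic error %.4f\n",
              x$quality["quantization_error"], x$quality["topographic_error"]))
  invisible(x)
}

# Standardize a (possibly new) matrix with a model's stored statistics,
# reconciling features by id; features absent from the new data stay NA.
standardize_for_model <- function(model, data) {
  X <- as_plain_matrix(data)
  if (!is.null(colnames(X)) && length(model$feature_ids)) {
    common <- intersect(model$feature_ids, colnames(X))
    if (length(common) == 0) stopf("no overlapping features with the model")
    full <- matrix(NA_real_, nrow(X), length(model$feature_ids),
                   dimnames = list(rownames(X), model$feature_ids))
    full[, common] <- X[, common, drop = FALSE]
    X <- full
  } else if (ncol(X) != ncol(model$codebook)) {
    stopf("feature dimension (%d) does not match the model (%d)",
          ncol(X), ncol(model$codebook))
  }
  if (model$config$feature_standardize)
    X <- sweep(sweep(X, 2, model$feature_mean), 2, model$feature_sd, "/")
  X
}

#' Project samples onto a trained map
#'
#' Maps new metabolome profiles onto a frozen map without retraining:
#' samples are standardized with the model's stored feature statistics and
#' assigned to their best-matching units. Distances are computed on the
#' observed feature subspace, so partially missing profiles project cleanly.
#'
#' @param model A `"som_model"`.
#' @param data Sample-by-feature matrix, [intensity_matrix()] on the same
#'   scale as the training data, or `"log_matrix"`. Features are matched by
#'   id when column names are present.
#' @return data.frame with `sample_id`, `bmu` (unit index) and `distance`.
#' @export
som_project <- function(model, data) {
  stopifnot(inherits(model, "som_model"))
  Z <- standardize_for_model(model, data)
  a <- find_bmu_all(model$codebook, Z)
  data.frame(sample_id = rownames(Z) %||% sprintf("S%03d", seq_len(nrow(Z))),
             bmu = a$bmu, distance = a$distance)
}

#' Map quality diagnostics
#'
#' Quantization error is the mean Euclidean distance of samples to their
#' best-matching units; topographic error is the fraction of samples whose
#' first and second BMUs are not lattice neighbors (unit-distance adjacency;
#' 0 by convention on a single-unit map).
#'
#' @param model A `"som_model"`.
#' @param data The data to evaluate (training scale).
#' @return Named numeric vector `c(quantization_error, topographic_error)`.
#' @export
som_quality <- function(model, data) {
  Z <- standardize_for_model(model, data)
  U <- nrow(model$codebook)
  if (anyNA(Z)) Z <- Z[stats::complete.cases(Z), , drop = FALSE]
  d2 <- cross_dist2(Z, model$codebook)
  ord1 <- max.col(-d2, ties.method = "first")
  qe <- mean(sqrt(d2[cbind(seq_len(nrow(Z)), ord1)]))
  if (U == 1) return(c(quantization_error = qe, topographic_error = 0))
  d2b <- d2; d2b[cbind(seq_len(nrow(Z)), ord1)] <- Inf
  ord2 <- max.col(-d2b, ties.method = "first")
  pd <- sqrt(rowSums((model$positions[ord1, , drop = FALSE] -
                        model$positions[ord2, , drop = FALSE])^2))
  te <- mean(pd > 1 + 1e-6)
  c(quantization_error = qe, topographic_error = te)
}

#' Serialize a SOM model to JSON
#'
#' Writes the geometry, configuration, standardization statistics, codebook
#' and training assignments to a JSON file that [som_read_json()] restores
#' exactly.
#'
#' @param model A `"som_model"`.
#' @param path Output path.
#' @export
som_write_json <- function(model, path) {
  payload <- list(grid = as.integer(model$grid), lattice = model$lattice,
                  config = model$config[setdiff(names(model$config), "grid")],
                  feature_ids = model$feature_ids,
                  feature_mean = model$feature_mean,
                  feature_sd = model$feature_sd,
                  codebook = model$codebook,
                  positions = model$positions,
                  bmu = model$bmu, quality = as.list(model$quality))
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' Restore a SOM model from JSON
#'
#' @param path Path written by [som_write_json()].
#' @return A `"som_model"`.
#' @export
som_read_json <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- do.call(som_config, c(list(grid = p$grid), p$config))
  cb <- p$codebook; colnames(cb) <- p$feature_ids
  structure(list(codebook = cb,
                 positions = {
                   pos <- p$positions
                   colnames(pos) <- c("x", "y"); pos
                 },
                 grid = c(rows = p$grid[1], cols = p$grid[2]),
                 lattice = p$lattice, config = cfg,
                 feature_ids = p$feature_ids,
                 feature_mean = stats::setNames(p$feature_mean, p$feature_ids),
                 feature_sd = stats::setNames(p$feature_sd, p$feature_ids),
                 bmu = p$bmu,
                 quality = unlist(p$quality)),
            class = "som_model")
}
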