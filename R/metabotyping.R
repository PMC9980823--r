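#' Codebook clustering configuration
#'
#' Controls the repeated-restart k-means sweep over the map codebook and the
#' Davies-Bouldin model selection. k-means is sensitive to initialization,
#' so each candidate k is fit from `restarts` seeded random initializations
#' (sampling k distinct codebook rows) and the restart with the lowest
#' within-cluster sum of squares is kept.
#'
#' @param k_min,k_max Candidate cluster-number range; `k_max = NULL` means
#'   the unit count. The Davies-Bouldin index is undefined at k = 1, so
#'   `k_min >= 2`; k = 1 is still reported in the selection trace with an
#'   undefined index.
#' @param restarts Random restarts per k (default 100).
#' @param max_iter Maximum Lloyd iterations per restart (default 300).
#' @param tol Relative SSE change declaring convergence (default 1e-6).
#' @param seed Integer seed driving all restarts.
#' @return An object of class `"cluster_config"`.
#' @export
cluster_config <- function(k_min = 2L, k_max = NULL, restarts = 100L,
                           max_iter = 300L, tol = 1e-6, seed = 1L) {
  if (k_min < 2) stopf("k_min must be >= 2 (Davies-Bouldin is undefined at k = 1)")
  if (!is.null(k_max) && k_max < k_min) stopf("k_max must be >= k_min")
  if (restarts < 1) stopf("restarts must be >= 1")
  structure(list(k_min = as.integer(k_min),
                 k_max = if (!is.null(k_max)) as.integer(k_max),
                 restarts = as.integer(restarts),
                 max_iter = as.integer(max_iter), tol = tol,
                 seed = as.integer(seed)),
            class = "cluster_config")
}

# One Lloyd run from given initial centers; empty clusters are re-seeded
# from the point currently farthest from its assigned centroid.
lloyd_once <- function(points, centers, max_iter, tol) {
  n <- nrow(points); k <- nrow(centers)
  sse_prev <- Inf
  for (it in seq_len(max_iter)) {
    d2 <- cross_dist2(points, centers)
    lab <- max.col(-d2, ties.method = "first")
    repeat {
      sizes <- tabulate(lab, k)
      empty <- which(sizes == 0L)
      if (length(empty) == 0L) break
      # donate the point farthest from its centroid, never from a singleton
      own <- d2[cbind(seq_len(n), lab)]
      own[sizes[lab] < 2L] <- -Inf
      lab[which.max(own)] <- empty[1]
    }
    for (c in seq_len(k))
      centers[c, ] <- colMeans(points[lab == c, , drop = FALSE])
    sse <- sum(cross_dist2(points, centers)[cbind(seq_len(n), lab)])
    if (is.finite(sse_prev) && sse_prev - sse <= tol * max(sse_prev, 1e-300))
      break
    sse_prev <- sse
  }
  list(cluster = lab, centers = centers, sse = sse)
}

#' Best-of-restarts k-means
#'
#' Lloyd's algorithm from `restarts` seeded random initializations (k
#' distinct rows of `points`), returning the run with the minimal
#' within-cluster sum of squared Euclidean distances (the error criterion).
#' Deterministic given `config$seed`.
#'
#' @param points Numeric matrix to partition (typically a SOM codebook,
#'   units as rows).
#' @param k Number of clusters (`2 <= k <= nrow(points)` allowed down to 1).
#' @param config A [cluster_config()]; its `k_min`/`k_max` are ignored here.
#' @return An object of class `"codebook_partition"`: `k`, `cluster`
#'   (row labels 1..k), `centers`, `sse`, `restarts`.
#' @export
kmeans_best <- function(points, k, config = cluster_config()) {
  points <- as.matrix(points)
  if (k > nrow(points)) stopf("k (%d) exceeds the number of points (%d)", k,
                              nrow(points))
  if (any(!is.finite(points))) stopf("points must be finite")
  if (k == 1) {
    ctr <- matrix(colMeans(points), 1)
    return(structure(list(k = 1L, cluster = rep(1L, nrow(points)),
                          centers = ctr,
                          sse = sum(cross_dist2(points, ctr)),
                          restarts = config$restarts),
                     class = "codebook_partition"))
  }
  best <- NULL
  with_seed(config$seed, {
    for (r in seq_len(config$restarts)) {
      init <- points[sample.int(nrow(points), k), , drop = FALSE]
      fit <- lloyd_once(points, init, config$max_iter, config$tol)
      if (is.null(best) || fit$sse < best$sse) best <- fit
    }
  })
  structure(list(k = as.integer(k), cluster = best$cluster,
                 centers = best$centers, sse = best$sse,
                 restarts = config$restarts),
            class = "codebook_partition")
}

#' Davies-Bouldin cluster validity index
#'
#' The index averages, over clusters, the worst-case ratio of summed
#' within-cluster scatters to between-centroid separation: with
#' `S_i` the mean Euclidean distance of cluster-i members to their centroid
#' and `M_ij` the distance between centroids i and j,
#' `DB = mean_i max_{j != i} (S_i + S_j) / M_ij`. Lower values indicate
#' compact, well-separated partitions; the best clustering scheme minimizes
#' the index.
#'
#' @param points Numeric matrix of clustered points.
#' @param labels Integer cluster labels 1..k; every cluster must be
#'   non-empty and k >= 2.
#' @return List with `db` (the index) and the breakdown: `S` (per-cluster
#'   scatter), `M` (pairwise centroid separations), `R` (pairwise ratios).
#' @examples
#' pts <- rbind(c(0, 0), c(0, 1), c(10, 10), c(10, 11))
#' davies_bouldin(pts, c(1, 1, 2, 2))$db # 1 / sqrt(200)
#' @export
davies_bouldin <- function(points, labels) {
  points <- as.matrix(points)
  labels <- as.integer(labels)
  k <- max(labels)
  if (k < 2) stopf("Davies-Bouldin index is undefined for k < 2")
  if (!setequal(unique(labels), seq_len(k)))
    stopf("labels must cover 1..k with every cluster non-empty")
  centers <- t(vapply(seq_len(k),
                      function(c) colMeans(points[labels == c, , drop = FALSE]),
                      numeric(ncol(points))))
  S <- vapply(seq_len(k), function(c) {
    mean(sqrt(rowSums(sweep(points[labels == c, , drop = FALSE],
                            2, centers[c, ])^2)))
  }, 0)
  M <- sqrt(cross_dist2(centers, centers))
  if (any(M[upper.tri(M)] < 1e-12))
    stopf("degenerate partition: coincident cluster centroids")
  R <- outer(S, S, "+") / M
  diag(R) <- -Inf
  list(db = mean(apply(R, 1, max)), S = S, M = M,
       R = {
         diag(R) <- NA_real_
         R
       })
}

#' Select the number of metabotypes by Davies-Bouldin minimization
#'
#' For each candidate k, fits best-of-restarts k-means on the codebook and
#' scores the winning partition with the Davies-Bouldin index; the chosen k
#' minimizes the index (ties resolve to the smaller k, by parsimony). A
#' k = 1 row is included in the trace for completeness with an undefined
#' index; k values whose best partition has coincident centroids are
#' recorded as undefined and never chosen.
#'
#' @param points Codebook matrix (units as rows).
#' @param config A [cluster_config()].
#' @return An object of class `"model_selection"`: `trace` (data.frame of
#'   `k`, `sse`, `db`), `breakdown` (per-k Davies-Bouldin components),
#'   `chosen_k`, and `partition` (the winning `"codebook_partition"`).
#' @export
select_k <- function(points, config = cluster_config()) {
  stopifnot(inherits(config, "cluster_config"))
  points <- as.matrix(points)
  k_max <- config$k_max %||% nrow(points)
  if (k_max > nrow(points)) stopf("k_max exceeds the number of points")
  ks <- config$k_min:k_max
  parts <- vector("list", length(ks))
  dbs <- rep(NA_real_, length(ks))
  breakdown <- vector("list", length(ks))
  names(breakdown) <- paste0("k", ks)
  for (i in seq_along(ks)) {
    cfg_k <- config
    cfg_k$seed <- config$seed + ks[i] # independent restart streams per k
    parts[[i]] <- kmeans_best(points, ks[i], cfg_k)
    v <- tryCatch(davies_bouldin(points, parts[[i]]$cluster),
                  error = function(e) NULL)
    if (!is.null(v)) {
      dbs[i] <- v$db
      breakdown[[i]] <- v
    }
  }
  if (all(is.na(dbs)))
    stopf("Davies-Bouldin index undefined for every candidate k")
  chosen <- ks[which.min(replace(dbs, is.na(dbs), Inf))]
  one <- kmeans_best(points, 1L, config)
  trace <- data.frame(k = c(1L, ks),
                      sse = c(one$sse, vapply(parts, `[[`, 0, "sse")),
                      db = c(NA_real_, dbs))
  structure(list(trace = trace, breakdown = breakdown,
                 chosen_k = chosen,
                 partition = parts[[match(chosen, ks)]]),
            class = "model_selection")
}

#' @export
print.model_selection <- function(x, ...) {
  cat(sprintf("<model_selection> chosen k = %d (Davies-Bouldin minimum)\n",
              x$chosen_k))
  print(x$trace, row.names = FALSE)
  invisible(x)
}

#' Assign metabotype labels to samples
#'
#' Each sample inherits the cluster label of its best-matching unit, turning
#' the two-stage clustering (SOM then k-means on the codebook) into a
#' sample-level stratification. Metabotypes left empty by the BMU mapping
#' are still reported with size zero.
#'
#' @param partition A `"codebook_partition"` over the model's units.
#' @param bmus Training assignments from a `"som_model"` (`model$bmu`) or a
#'   projection from [som_project()].
#' @return An object of class `"metabotype_assignment"`: `assignments`
#'   (data.frame `sample_id`, `bmu`, `metabotype`) and `sizes` (named
#'   integer vector over all metabotypes 1..k).
#' @export
assign_metabotypes <- function(partition, bmus) {
  stopifnot(inherits(partition, "codebook_partition"))
  if (inherits(bmus, "som_model")) bmus <- bmus$bmu
  if (any(bmus$bmu < 1 | bmus$bmu > length(partition$cluster)))
    stopf("BMU index outside the partitioned codebook")
  lab <- partition$cluster[bmus$bmu]
  sizes <- tabulate(lab, nbins = partition$k)
  names(sizes) <- as.character(seq_len(partition$k))
  structure(list(assignments = data.frame(sample_id = bmus$sample_id,
                                          bmu = bmus$bmu, metabotype = lab),
                 sizes = sizes),
            class = "metabotype_assignment")
}

#' @export
print.metabotype_assignment <- function(x, ...) {
  cat(sprintf("<metabotype_assignment> %d samples in %d metabotypes\n",
              nrow(x$assignments), length(x$sizes)))
  print(x$sizes)
  invisible(x)
}
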