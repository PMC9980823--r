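#' Hybrid ANOVA / Kruskal-Wallis differential features
#'
#' Tests every feature for differential abundance across metabotypes with
#' two one-way tests — the parametric ANOVA F-test and the non-parametric,
#' tie-corrected Kruskal-Wallis test — and flags a feature as significant
#' only when BOTH raw p-values fall below `alpha` (the intersection rule,
#' robust against single-test artifacts such as one extreme outlier passing
#' ANOVA alone). Benjamini-Hochberg adjusted q-values are reported per test
#' family. Both p-values are computed in vectorized matrix form and agree
#' with `stats::oneway.test(var.equal = TRUE)` and `stats::kruskal.test`
#' to full precision.
#'
#' Features that are constant across all samples have an undefined test
#' statistic; they are reported with p = 1 and `degenerate = TRUE` rather
#' than erroring, so pipelines proceed. Groups with fewer than 2 members
#' trigger a warning (the ANOVA within-group variance then leans on the
#' remaining groups).
#'
#' @param x Sample-by-feature matrix or `"log_matrix"`.
#' @param groups Metabotype labels: a `"metabotype_assignment"`, factor, or
#'   vector with one entry per sample.
#' @param alpha Significance level for the intersection rule (default 0.05).
#' @return data.frame with one row per feature: `feature`, `p_anova`,
#'   `p_kw`, `q_anova`, `q_kw`, `significant`, `degenerate`, and
#'   per-metabotype means (`mean_1`, `mean_2`, ...).
#' @export
hybrid_test <- function(x, groups, alpha = 0.05) {
  if (alpha <= 0 || alpha >= 1) stopf("alpha must be in (0, 1)")
  X <- as_plain_matrix(x)
  g <- as_group_factor(groups, nrow(X))
  if (nlevels(g) < 2) stopf("need at least 2 metabotypes")
  if (any(table(g) < 2))
    warning("metabotype(s) with fewer than 2 members: ",
            paste(names(which(table(g) < 2)), collapse = ", "))
  n <- nrow(X); k <- nlevels(g)
  G <- stats::model.matrix(~ g - 1)
  ng <- colSums(G)

  gm <- crossprod(G, X) / ng
  mu <- colMeans(X)
  ssb <- colSums(ng * (gm - rep(mu, each = k))^2)
  sst <- colSums((X - rep(mu, each = n))^2)
  ssw <- pmax(sst - ssb, 0)
  degenerate <- sst < 1e-24
  Fstat <- (ssb / (k - 1)) / (ssw / (n - k))
  p_anova <- stats::pf(Fstat, k - 1, n - k, lower.tail = FALSE)
  p_anova[degenerate | !is.finite(Fstat)] <- 1

  R <- apply(X, 2, rank)
  Rg <- crossprod(G, R)
  H <- 12 / (n * (n + 1)) * colSums(Rg^2 / ng) - 3 * (n + 1)
  tied <- vapply(seq_len(ncol(X)),
                 function(j) anyDuplicated(X[, j]) > 0L, NA)
  if (any(tied)) {
    corr <- vapply(which(tied), function(j) {
      t <- rle(sort(X[, j]))$lengths
      1 - sum(t^3 - t) / (n^3 - n)
    }, 0)
    H[tied] <- H[tied] / corr
  }
  p_kw <- stats::pchisq(H, k - 1, lower.tail = FALSE)
  p_kw[degenerate | !is.finite(H)] <- 1

  means <- t(gm)
  colnames(means) <- paste0("mean_", levels(g))
  out <- data.frame(feature = colnames(X) %||% sprintf("F%04d", seq_len(ncol(X))),
                    p_anova = p_anova, p_kw = p_kw,
                    q_anova = stats::p.adjust(p_anova, "BH"),
                    q_kw = stats::p.adjust(p_kw, "BH"),
                    degenerate = degenerate)
  out$significant <- !degenerate & p_anova < alpha & p_kw < alpha
  cbind(out, means)
}

as_group_factor <- function(groups, n) {
  if (inherits(groups, "metabotype_assignment"))
    groups <- groups$assignments$metabotype
  g <- factor(groups)
  if (length(g) != n)
    stopf("group labels (%d) do not match the number of samples (%d)",
          length(g), n)
  droplevels(g)
}

#' Benjamini-Hochberg adjustment with rejection flags
#'
#' Step-up BH adjusted p-values (monotone, capped at 1) via
#' [stats::p.adjust()], plus the rejection set at `q_level`.
#'
#' @param pvals Numeric vector of p-values in `[0, 1]`.
#' @param q_level Nominal false discovery rate (default 0.05).
#' @return List with `adjusted` and logical `rejected`.
#' @export
adjust_bh <- function(pvals, q_level = 0.05) {
  if (length(pvals) == 0)
    return(list(adjusted = numeric(0), rejected = logical(0)))
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE))
    stopf("p-values must lie in [0, 1]")
  adj <- stats::p.adjust(pvals, method = "BH")
  list(adjusted = adj, rejected = !is.na(adj) & adj <= q_level)
}

#' Exact-permutation Kruskal-Wallis p-value
#'
#' Computes the Kruskal-Wallis H statistic and its exact permutation
#' p-value by enumerating every distinct assignment of the observations to
#' the group-size pattern (feasible up to n of about 10). The large-sample
#' chi-square approximation used by [hybrid_test()] and
#' [stats::kruskal.test()] can deviate from the exact tail probability by
#' ~0.1 at n = 8; this function provides the exact reference for small
#' groups.
#'
#' @param x Numeric vector of observations.
#' @param g Group labels.
#' @return List with `statistic` (tie-corrected H) and `p_exact`
#'   (`Pr(H >= observed)` over the permutation distribution).
#' @export
kw_exact_p <- function(x, g) {
  g <- factor(g)
  n <- length(x)
  if (length(g) != n) stopf("x and g lengths differ")
  if (n > 10) stopf("exact enumeration supported only for n <= 10")
  ng <- as.integer(table(g))
  r <- rank(x)
  tie_corr <- {
    t <- rle(sort(x))$lengths
    1 - sum(t^3 - t) / (n^3 - n)
  }
  hstat <- function(rk, lab) {
    Rg <- vapply(split(rk, lab), sum, 0)
    (12 / (n * (n + 1)) * sum(Rg^2 / ng) - 3 * (n + 1)) / tie_corr
  }
  H0 <- hstat(r, g)
  # enumerate all distinct multiset assignments of indices to groups
  acc <- list(list(lab = integer(n), left = seq_len(n)))
  for (gi in seq_along(ng)[-length(ng)]) {
    nxt <- list()
    for (st in acc) {
      picks <- utils::combn(length(st$left), ng[gi], simplify = FALSE)
      for (pi in picks) {
        p <- st$left[pi]
        lab <- st$lab; lab[p] <- gi
        nxt[[length(nxt) + 1L]] <- list(lab = lab, left = setdiff(st$left, p))
      }
    }
    acc <- nxt
  }
  Hs <- vapply(acc, function(st) {
    lab <- st$lab; lab[st$left] <- length(ng)
    hstat(r, factor(lab))
  }, 0)
  list(statistic = H0, p_exact = mean(Hs >= H0 - 1e-9))
}

#' Kruskal-Wallis comparison of clinical variables across metabotypes
#'
#' Applies the Kruskal-Wallis test (the extension of the Mann-Whitney U
#' test to multiple groups) to each numeric clinical variable across
#' metabotypes, with conventional significance stars.
#'
#' @param covariates data.frame of clinical variables (one row per sample).
#' @param groups Metabotype labels (see [hybrid_test()]).
#' @return data.frame with `variable`, `statistic`, `df`, `p`, `stars`.
#'   Non-numeric columns are skipped with a warning.
#' @export
clinical_kw <- function(covariates, groups) {
  g <- as_group_factor(groups, nrow(covariates))
  num <- vapply(covariates, is.numeric, NA)
  if (any(!num))
    warning("skipping non-numeric variable(s): ",
            paste(names(covariates)[!num], collapse = ", "))
  vars <- names(covariates)[num]
  rows <- lapply(vars, function(v) {
    kt <- stats::kruskal.test(covariates[[v]], g)
    data.frame(variable = v, statistic = unname(kt$statistic),
               df = unname(kt$parameter), p = kt$p.value)
  })
  out <- do.call(rbind, rows)
  out$stars <- signif_stars(out$p)
  out
}

#' Spearman correlation of features with clinical covariates
#'
#' Computes Spearman's rho with tie-corrected p-value for every
#' feature-by-covariate pair (optionally stratified within metabotypes),
#' with Benjamini-Hochberg q-values across the whole grid and significance
#' stars at the 0.05 / 0.01 / 0.001 thresholds. Constant features or
#' covariates have undefined rho and are reported as `NA`.
#'
#' @param features Sample-by-feature matrix or `"log_matrix"`.
#' @param covariates data.frame or matrix of numeric covariates.
#' @param groups Optional metabotype labels; when given, correlations are
#'   computed within each metabotype.
#' @return data.frame with `feature`, `covariate`, optional `metabotype`,
#'   `n`, `rho`, `p`, `q`, `stars`.
#' @export
spearman_covariates <- function(features, covariates, groups = NULL) {
  X <- as_plain_matrix(features)
  C <- as.matrix(covariates)
  if (nrow(C) != nrow(X)) stopf("features and covariates must share samples")
  strata <- if (is.null(groups)) list(all = seq_len(nrow(X)))
            else split(seq_len(nrow(X)), as_group_factor(groups, nrow(X)))
  rows <- list()
  for (s in names(strata)) {
    idx <- strata[[s]]
    for (j in seq_len(ncol(X))) for (v in seq_len(ncol(C))) {
      xi <- X[idx, j]; ci <- C[idx, v]
      ok <- stats::complete.cases(xi, ci)
      res <- if (sum(ok) < 3 || stats::sd(xi[ok]) == 0 || stats::sd(ci[ok]) == 0)
        c(NA_real_, NA_real_)
      else {
        ct <- suppressWarnings(
          stats::cor.test(xi[ok], ci[ok], method = "spearman", exact = FALSE))
        c(unname(ct$estimate), ct$p.value)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        feature = colnames(X)[j] %||% paste0("F", j),
        covariate = colnames(C)[v] %||% paste0("C", v),
        metabotype = s, n = sum(ok), rho = res[1], p = res[2])
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(groups)) out$metabotype <- NULL
  out$q <- stats::p.adjust(out$p, "BH")
  out$stars <- signif_stars(out$p)
  out
}

#' Pairwise longitudinal contrasts between metabotypes
#'
#' For an anthropometric outcome followed over time (e.g. weight after
#' surgery), computes the change from baseline at each later timepoint and
#' compares every pair of metabotypes with a two-sample t-test (Welch by
#' default), adjusting with Benjamini-Hochberg across all pairs and
#' timepoints.
#'
#' @param outcomes Sample-by-timepoint numeric matrix; the first column is
#'   the baseline unless `baseline` names another column.
#' @param groups Metabotype labels.
#' @param baseline Baseline column name or index (default first column).
#' @param var_equal Use the pooled-variance t-test instead of Welch
#'   (default `FALSE`).
#' @return data.frame with `timepoint`, `group1`, `group2`, `estimate`
#'   (mean delta difference), `statistic`, `p`, `q`, `stars`. Contrasts
#'   with fewer than 2 observations in either group are skipped with a
#'   warning.
#' @export
longitudinal_contrasts <- function(outcomes, groups, baseline = 1L,
                                   var_equal = FALSE) {
  M <- as.matrix(outcomes)
  g <- as_group_factor(groups, nrow(M))
  bl <- if (is.character(baseline)) match(baseline, colnames(M)) else baseline
  if (is.na(bl)) stopf("baseline column not found")
  deltas <- M[, -bl, drop = FALSE] - M[, bl]
  tps <- colnames(deltas) %||% paste0("T", seq_len(ncol(deltas)))
  lev <- levels(g)
  rows <- list(); skipped <- character(0)
  for (t in seq_len(ncol(deltas))) {
    for (a in seq_along(lev)) for (b in seq_along(lev)) {
      if (b <= a) next
      xa <- deltas[g == lev[a], t]; xb <- deltas[g == lev[b], t]
      xa <- xa[!is.na(xa)]; xb <- xb[!is.na(xb)]
      if (length(xa) < 2 || length(xb) < 2) {
        skipped <- c(skipped, sprintf("%s: %s vs %s", tps[t], lev[a], lev[b]))
        next
      }
      tt <- stats::t.test(xa, xb, var.equal = var_equal)
      rows[[length(rows) + 1L]] <- data.frame(
        timepoint = tps[t], group1 = lev[a], group2 = lev[b],
        estimate = mean(xa) - mean(xb),
        statistic = unname(tt$statistic), p = tt$p.value)
    }
  }
  if (length(skipped))
    warning("skipped contrast(s) with < 2 observations: ",
            paste(skipped, collapse = "; "))
  if (length(rows) == 0)
    return(data.frame(timepoint = character(0), group1 = character(0),
                      group2 = character(0), estimate = numeric(0),
                      statistic = numeric(0), p = numeric(0),
                      q = numeric(0), stars = character(0)))
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, "BH")
  out$stars <- signif_stars(out$p)
  out
}

#' Simulate false-discovery control of the differential stage
#'
#' Monte-Carlo check of the hybrid differential stage under a partial null:
#' each replicate draws a cohort of `sum(group_sizes)` samples with
#' `n_features` standard-normal features, plants a location shift of
#' `effect_size` SDs in one (randomly chosen) group for the first
#' `n_effect` features, runs [hybrid_test()], and calls a feature
#' differential when both Benjamini-Hochberg adjusted p-values are at or
#' below `q_level`. The false discovery proportion (null features among
#' discoveries) is recorded per replicate.
#'
#' @param n_replicates Number of simulation replicates (default 200).
#' @param group_sizes Group sizes (default the cohort5 sizes).
#' @param n_features Features per replicate (default 1000).
#' @param n_effect Number of features with a planted effect (default 100).
#' @param effect_size Planted shift in within-group SDs (default 1.5).
#' @param q_level Nominal FDR level (default 0.05).
#' @param seed Integer seed.
#' @return List with `fdp` (per-replicate false discovery proportions),
#'   `mean_fdp`, `mean_discoveries` and `mean_power`.
#' @export
fdr_simulation <- function(n_replicates = 200L,
                           group_sizes = c(17L, 29L, 25L, 18L, 17L),
                           n_features = 1000L, n_effect = 100L,
                           effect_size = 1.5, q_level = 0.05, seed = 1L) {
  g <- factor(rep(seq_along(group_sizes), group_sizes))
  n <- length(g); k <- nlevels(g)
  fdp <- power <- ndisc <- numeric(n_replicates)
  eff <- seq_len(n_effect)
  with_seed(seed, {
    for (r in seq_len(n_replicates)) {
      X <- matrix(stats::rnorm(n * n_features), n, n_features)
      tg <- sample.int(k, n_effect, replace = TRUE)
      for (j in eff) X[g == tg[j], j] <- X[g == tg[j], j] + effect_size
      res <- hybrid_test(X, g)
      rej <- !res$degenerate & res$q_anova <= q_level & res$q_kw <= q_level
      ndisc[r] <- sum(rej)
      fdp[r] <- sum(rej[-eff]) / max(1L, sum(rej))
      power[r] <- mean(rej[eff])
    }
  })
  list(fdp = fdp, mean_fdp = mean(fdp),
       mean_discoveries = mean(ndisc), mean_power = mean(power))
}
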