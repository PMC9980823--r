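# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's internal code paths.

# Davies-Bouldin by direct evaluation of the definition with explicit loops.
db_brute <- function(points, labels) {
  k <- max(labels)
  cent <- lapply(seq_len(k), function(c) colMeans(points[labels == c, , drop = FALSE]))
  S <- sapply(seq_len(k), function(c) {
    mem <- points[labels == c, , drop = FALSE]
    mean(apply(mem, 1, function(p) sqrt(sum((p - cent[[c]])^2))))
  })
  worst <- sapply(seq_len(k), function(i) {
    max(sapply(setdiff(seq_len(k), i), function(j) {
      (S[i] + S[j]) / sqrt(sum((cent[[i]] - cent[[j]])^2))
    }))
  })
  mean(worst)
}

# Exhaustive permutation distribution of the Kruskal-Wallis statistic,
# enumerating all n! index orders (feasible for n <= 7).
kw_perm_oracle <- function(x, g) {
  n <- length(x)
  g <- factor(g)
  ng <- as.integer(table(g))
  h_of <- function(xx) {
    r <- rank(xx)
    Rg <- vapply(split(r, g), sum, 0)
    t <- rle(sort(xx))$lengths
    H <- 12 / (n * (n + 1)) * sum(Rg^2 / ng) - 3 * (n + 1)
    H / (1 - sum(t^3 - t) / (n^3 - n))
  }
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    out
  }
  H0 <- h_of(x)
  Hs <- vapply(perms(seq_len(n)), function(p) h_of(x[p]), 0)
  list(statistic = H0, p_exact = mean(Hs >= H0 - 1e-9))
}

# Small complete intensity fixture with a known layout.
tiny_intensities <- function() {
  intensity_matrix(matrix(c(10, 20, 30, 40,
                            1, 2, 3, 4,
                            5, 6, 7, 8), nrow = 3, byrow = TRUE,
                          dimnames = list(c("a", "b", "c"),
                                          c("m1", "m2", "m3", "m4"))))
}
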