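#' @keywords internal
"_PACKAGE"

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Significance star codes at the conventional 0.05 / 0.01 / 0.001 cut-offs.
signif_stars <- function(p) {
  out <- character(length(p))
  out[!is.na(p) & p <= 0.05]  <- "*"
  out[!is.na(p) & p <= 0.01]  <- "**"
  out[!is.na(p) & p <= 0.001] <- "***"
  out[is.na(p)] <- NA_character_
  out
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
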