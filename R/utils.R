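# internal helpers shared across modules

# Run `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched. seed = NULL runs expr with the ambient stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Derive `n` independent sub-seeds (< 2^31) from one user seed.
spawn_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

is_wholenumber <- function(x, tol = 1e-8) {
  is.numeric(x) & !is.na(x) & abs(x - round(x)) < tol
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Quantiles by linear interpolation (Hyndman & Fan definition 7).
quantile_hf7 <- function(x, probs) {
  stats::quantile(x, probs = probs, type = 7, names = FALSE, na.rm = TRUE)
}

# variance with n-1 denominator, optionally frequency-weighted (weights are
# replication counts; denominator sum(w) - 1)
weighted_var <- function(x, w = NULL) {
  if (is.null(w)) return(stats::var(x))
  sw <- sum(w)
  if (sw <= 1) return(0)
  m <- sum(w * x) / sw
  sum(w * (x - m)^2) / (sw - 1)
}
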