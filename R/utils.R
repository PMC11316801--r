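# internal helpers

# Evaluate expr under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed %% .Machine$integer.max))
  }
  force(expr)
}

# Derive a child seed from a master seed and a stage label (stable scheme,
# stays below 2^31).
derive_seed <- function(seed, stage) {
  if (is.null(seed)) return(NULL)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647L)
}

# First run of TRUE with length >= min_len; returns c(start, length) or NULL.
find_run <- function(flags, min_len) {
  flags[is.na(flags)] <- FALSE
  r <- rle(flags)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ok <- which(r$values & r$lengths >= min_len)
  if (!length(ok)) return(NULL)
  c(start = starts[ok[1]], length = r$lengths[ok[1]])
}

# odd/even split of trial indices in 1-based order ("odd trials" = 1st, 3rd, ...)
odd_idx <- function(n) seq(1L, n, by = 2L)
even_idx <- function(n) if (n >= 2L) seq(2L, n, by = 2L) else integer(0)

# safe Pearson correlation: NA if either side has zero variance
safe_cor <- function(x, y) {
  if (any(!is.finite(x)) || any(!is.finite(y))) return(NA_real_)
  if (sd(x) == 0 || sd(y) == 0) return(NA_real_)
  cor(x, y)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(...) stop(sprintf(...), call. = FALSE)
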