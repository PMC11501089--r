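# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG state afterwards.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Deterministic substream seed derived from a master seed and a label,
# kept inside 32-bit integer range.
substream_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * (seq_along(utf8ToInt(label)) %% 31 + 1))
  as.integer((as.numeric(seed) * 2654435.0 + h) %% 2147483647)
}

# Fix the sign of each column so that its largest-magnitude entry is
# positive; removes the sign indeterminacy of SVD components so results
# do not depend on participant ordering.
fix_signs <- function(x) {
  if (!ncol(x)) return(x)
  s <- vapply(seq_len(ncol(x)), function(j) {
    i <- which.max(abs(x[, j]))
    if (x[i, j] < 0) -1 else 1
  }, 1)
  sweep(x, 2, s, "*")
}

# Pearson correlation between two numeric vectors without the overhead of
# stats::cor on matrices.
vcor <- function(a, b) {
  a <- a - mean(a); b <- b - mean(b)
  den <- sqrt(sum(a^2) * sum(b^2))
  if (den == 0) return(NA_real_)
  sum(a * b) / den
}

wrap_degrees <- function(x) ((x %% 360) + 360) %% 360
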