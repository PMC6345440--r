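# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
# Every stochastic function in the package routes its randomness through this,
# so no stage ever reads system entropy.
with_seed <- function(seed, code) {
  seed <- as.integer(seed %% .Machine$integer.max)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# Running mean over a k-neighbourhood along rows (edge-truncated windows).
.run_mean_rows <- function(m, k) {
  n <- nrow(m); p <- ncol(m)
  hw <- k %/% 2L
  # per-column cumulative sums without the apply() loop: cumsum the flat
  # vector, then subtract each column's starting offset
  v <- cumsum(as.vector(m))
  cs <- matrix(v, n, p)
  if (p > 1L) cs <- sweep(cs, 2L, c(0, v[n * seq_len(p - 1L)]))
  idx <- seq_len(n)
  hi <- pmin(n, idx + hw)
  lo <- idx - hw - 1L
  res <- cs[hi, , drop = FALSE]
  pos <- lo >= 1L
  res[pos, ] <- res[pos, ] - cs[lo[pos], , drop = FALSE]
  res / (hi - pmax(lo, 0L))
}

# Separable box blur with edge truncation; preserves the overall mean level.
box_blur <- function(m, k) {
  t(.run_mean_rows(t(.run_mean_rows(m, k)), k))
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

`%||%` <- function(a, b) if (is.null(a)) b else a

# Rank-based AUC (exactly the trapezoidal ROC area with tie interpolation).
auc_rank <- function(scores, positive) {
  positive <- as.logical(positive)
  n1 <- sum(positive)
  n0 <- sum(!positive)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
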