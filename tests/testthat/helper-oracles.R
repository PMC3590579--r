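# Independent oracles, kept deliberately separate from the package internals.

# Brute-force sample entropy by explicit template matrices and stats::dist
# (Chebyshev metric). Counts every unordered template pair i < j with
# start points <= N - m; self-matches excluded.
sampen_bruteforce <- function(x, m, r) {
  n <- length(x)
  tm <- stats::embed(x, m)[, m:1, drop = FALSE]      # N - m + 1 templates
  tm <- tm[seq_len(n - m), , drop = FALSE]           # restrict start points
  tm1 <- stats::embed(x, m + 1)[, (m + 1):1, drop = FALSE]
  B <- sum(as.vector(stats::dist(tm, method = "maximum")) <= r)
  A <- sum(as.vector(stats::dist(tm1, method = "maximum")) <= r)
  if (B == 0) return(NaN)
  if (A == 0) return(Inf)
  -log(A / B)
}

# Loop-based coarse-graining, independent of the matrix implementation.
coarse_grain_loop <- function(x, tau) {
  k <- length(x) %/% tau
  vapply(seq_len(k), function(j) mean(x[((j - 1) * tau + 1):(j * tau)]),
         numeric(1))
}
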