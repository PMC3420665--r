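# Small builders used across test files.

# genotype_matrix from carrier counts: one column per variant, `ones[j]`
# heterozygotes placed at distinct rows (staggered so columns differ).
toy_counts <- function(n, ones, stagger = TRUE) {
  p <- length(ones)
  v <- matrix(0, n, p)
  start <- 1L
  for (j in seq_len(p)) {
    idx <- ((start - 1L + seq_len(ones[j]) - 1L) %% n) + 1L
    v[idx, j] <- 1
    if (stagger) start <- start + ones[j]
  }
  genotype_matrix(v)
}

# random full-rank Gaussian design plus response
rand_problem <- function(n, p, seed, signal = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  y <- signal * X[, 1] + rnorm(n)
  list(X = X, y = y)
}

# design with exactly orthonormal centered columns
orthonormal_design <- function(n, p, seed) {
  set.seed(seed)
  M <- matrix(rnorm(n * p), n, p)
  M <- sweep(M, 2, colMeans(M))
  qr.Q(qr(M))
}

ols_fitted <- function(X, y) unname(fitted(stats::lm(y ~ X)))
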