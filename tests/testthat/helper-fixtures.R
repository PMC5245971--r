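# shared fixtures and independent oracles used across test files

# brute-force Pearson from explicit sums, independent of stats::cor
pearson_oracle <- function(a, b) {
  n <- length(a)
  ma <- sum(a) / n
  mb <- sum(b) / n
  num <- sum((a - ma) * (b - mb))
  num / sqrt(sum((a - ma)^2) * sum((b - mb)^2))
}

# brute-force Gini from the sorted mean-absolute-difference form
gini_oracle <- function(v) {
  a <- sort(abs(v))
  n <- length(a)
  num <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) num <- num + abs(a[i] - a[j])
  num / (2 * n * sum(a))
}

# small default config for pipeline tests (protocol-sized runs live in
# test-acceptance.R)
small_config <- function(seed = 42, ...) {
  experiment_config(n_networks = 5, seed = seed, ...)
}

# orthogonal matrix that fixes the all-ones direction, so it commutes with
# mean-centering and preserves Pearson correlation exactly
centering_preserving_orthogonal <- function(n, seed) {
  set.seed(seed)
  M <- cbind(rep(1, n) / sqrt(n), matrix(rnorm(n * (n - 1)), n))
  B <- qr.Q(qr(M))
  R <- qr.Q(qr(matrix(rnorm((n - 1)^2), n - 1)))
  B %*% rbind(c(1, rep(0, n - 1)), cbind(0, R)) %*% t(B)
}
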