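# Independent brute-force oracles, deliberately written as naive loops so
# they share no code path with the package internals.

# causal zero-padded linear convolution, truncated to length(x)
brute_conv <- function(x, k) {
  n <- length(x)
  out <- numeric(n)
  for (i in seq_len(n)) {
    acc <- 0
    for (j in seq_len(i)) {
      lag <- i - j + 1
      if (lag <= length(k)) acc <- acc + x[j] * k[lag]
    }
    out[i] <- acc
  }
  out
}

# dense convolution evaluated at TR onsets
brute_tr_sample <- function(neural, hrf, spb) {
  n_tr <- length(neural) %/% spb
  out <- numeric(n_tr)
  for (j in seq_len(n_tr)) {
    p <- (j - 1) * spb + 1
    acc <- 0
    for (i in seq_len(p)) {
      lag <- p - i + 1
      if (lag <= length(hrf)) acc <- acc + neural[i] * hrf[lag]
    }
    out[j] <- acc
  }
  out
}

# normal-equations least squares
normal_eq <- function(X, y) drop(solve(t(X) %*% X, t(X) %*% y))

# one short run per experiment, cheap enough for repeated fitting in tests
small_designs <- function(n_per_exp = 2) {
  designs <- list()
  for (e in 1:3) for (r in seq_len(n_per_exp))
    designs[[length(designs) + 1]] <- experiment_run(e)
  designs
}
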