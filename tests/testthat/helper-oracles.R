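# Monte-Carlo oracles for Gaussian averages, independent of the quadrature
# code paths they check. Sampling is chunked to bound memory.

mc_avg <- function(f, nsamp = 1e7, seed = 99, chunk = 1e6) {
  set.seed(seed)
  tot <- 0; n <- 0
  while (n < nsamp) {
    m <- min(chunk, nsamp - n)
    tot <- tot + sum(f(stats::rnorm(m)))
    n <- n + m
  }
  tot / n
}

mc_pair <- function(f, cov = 0.5, nsamp = 1e7, seed = 99, chunk = 1e6) {
  set.seed(seed)
  tot <- 0; n <- 0
  while (n < nsamp) {
    m <- min(chunk, nsamp - n)
    u <- stats::rnorm(m); v1 <- stats::rnorm(m); v2 <- stats::rnorm(m)
    a <- sqrt(cov) * u + sqrt(1 - cov) * v1
    b <- sqrt(cov) * u + sqrt(1 - cov) * v2
    tot <- tot + sum(f(a) * f(b))
    n <- n + m
  }
  tot / n
}

# E[prod_t f((a_{S[t]} + b_{C[t]})/sqrt(2))] with variables shared by index
mc_pattern <- function(f, S, C, nsamp = 1e7, seed = 99, chunk = 1e6) {
  set.seed(seed)
  uS <- unique(S); uC <- unique(C)
  tot <- 0; n <- 0
  while (n < nsamp) {
    m <- min(chunk, nsamp - n)
    a <- matrix(stats::rnorm(m * length(uS)), m)
    b <- matrix(stats::rnorm(m * length(uC)), m)
    prod <- rep(1, m)
    for (t in seq_along(S))
      prod <- prod * f((a[, match(S[t], uS)] + b[, match(C[t], uC)]) / sqrt(2))
    tot <- tot + sum(prod)
    n <- n + m
  }
  tot / n
}
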