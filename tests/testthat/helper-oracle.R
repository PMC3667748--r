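# Independent brute-force oracle for the expected sample SFS: textbook
# Wright density (naive algebraic form; exp(gamma) underflows harmlessly
# for large negative gamma) integrated by dense trapezoid quadrature with
# analytic endpoint limits.  Deliberately shares no code with the package
# quadrature.
trap_sfs_oracle <- function(n, gammas, N = 1e6) {
  q <- seq_len(N - 1L) / N
  lq <- log(q)
  l1q <- log1p(-q)
  H <- vapply(gammas, function(g) {
    if (g == 0) 1 / q else (exp(g * q) - exp(g)) / ((1 - exp(g)) * q * (1 - q))
  }, numeric(N - 1L))
  out <- matrix(0, n - 1L, length(gammas))
  for (i in seq_len(n - 1L)) {
    b <- exp(lchoose(n, i) + i * lq + (n - i) * l1q)
    out[i, ] <- colSums(b * H) / N
  }
  # endpoint limits: the integrand vanishes at both ends except for i = 1,
  # where q * h(q) -> 1 as q -> 0 for every gamma, so f_1(0) = n
  out[1L, ] <- out[1L, ] + n / (2 * N)
  out
}
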