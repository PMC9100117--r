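# Independent oracles kept deliberately naive: a literal transcription of the
# Benjamini-Hochberg step-up definition, and exhaustive enumeration of the
# Mann-Whitney permutation null. They must never call into the package.

bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# Exact two-sided Mann-Whitney p by enumerating every assignment of the
# pooled (tie-free) values into groups of the observed sizes; two-sided via
# the symmetry of U around n1*n2/2 under the null.
mw_enum_p <- function(a, b) {
  pooled <- c(a, b)
  n1 <- length(a)
  mu <- n1 * length(b) / 2
  obs <- sum(outer(a, b, ">"))
  sets <- utils::combn(length(pooled), n1)
  us <- apply(sets, 2L, function(idx) {
    sum(outer(pooled[idx], pooled[-idx], ">"))
  })
  mean(abs(us - mu) >= abs(obs - mu) - 1e-12)
}
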