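# small phantom for fast module tests; the acceptance tests use the full
# 64 x 64 x 16 grid
small_phantom <- function(...) {
  build_phantom(phantom_spec(shape = c(32L, 32L, 8L), ...))
}

# relative error helper over a logical mask
rel_err <- function(est, truth, mask) {
  sel <- mask & is.finite(truth) & truth != 0
  max(abs(est[sel] - truth[sel]) / abs(truth[sel]))
}

# independent brute-force BH step-up (quadratic loops, no shortcuts) used
# as the oracle for bh_adjust()
bh_brute <- function(p, q = 0.05) {
  m <- length(p)
  adj <- numeric(m)
  for (i in seq_len(m)) {
    rank_i <- sum(p <= p[i])  # maximal rank among ties
    cand <- Inf
    for (j in seq_len(m)) {
      rank_j <- sum(p <= p[j])
      if (p[j] >= p[i]) cand <- min(cand, m * p[j] / rank_j)
    }
    adj[i] <- min(1, cand)
  }
  kmax <- 0L
  ps <- sort(p)
  for (i in seq_len(m)) if (ps[i] <= i * q / m) kmax <- i
  disc <- if (kmax == 0L) rep(FALSE, m) else p <= ps[kmax]
  list(p_adjusted = adj, discovery = disc)
}
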