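# Independent oracle for the analytic evidential-reasoning formula: the
# recursive two-source combination rule. Each rule is turned into a
# discounted mass assignment (m_j = w_k * beta_jk, with the unassigned
# remainder split into weight-induced mass mbar = 1 - w_k and
# incompleteness-induced mass mtil = w_k * (1 - sum_j beta_jk)), sources
# are combined pairwise in sequence with conflict renormalisation, and the
# final beliefs are read off by removing the weight-induced remainder.
er_combine_oracle <- function(w, B) {
  stopifnot(nrow(B) == length(w), abs(sum(w) - 1) < 1e-9)
  m <- w[1L] * B[1L, ]
  mbar <- 1 - w[1L]
  mtil <- w[1L] * (1 - sum(B[1L, ]))
  for (k in seq_len(nrow(B))[-1L]) {
    mk <- w[k] * B[k, ]
    mbark <- 1 - w[k]
    mtilk <- w[k] * (1 - sum(B[k, ]))
    mH <- mbar + mtil
    mHk <- mbark + mtilk
    conflict <- sum(m) * sum(mk) - sum(m * mk)
    K <- 1 / (1 - conflict)
    m_new <- K * (m * mk + m * mHk + mH * mk)
    mbar_new <- K * mbar * mbark
    mtil_new <- K * (mtil * mtilk + mtil * mbark + mbar * mtilk)
    m <- m_new; mbar <- mbar_new; mtil <- mtil_new
  }
  m / (1 - mbar)
}

# random small ER instance: L weighted sources over N grades, a mix of
# complete and incomplete belief rows
random_er_instance <- function(L = sample(2:5, 1), N = sample(2:5, 1),
                               incomplete = TRUE) {
  B <- matrix(stats::runif(L * N), L, N)
  B <- B / rowSums(B)
  if (incomplete) {
    shrink <- stats::runif(L, 0.5, 1)
    keep <- stats::runif(L) < 0.5
    shrink[keep] <- 1
    B <- B * shrink
  }
  w <- stats::runif(L, 0.05, 1)
  w <- w / sum(w)
  list(w = w, B = B)
}
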