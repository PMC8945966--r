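# Periodised multilevel discrete wavelet transform (Daubechies-4, 8 taps).
# Implemented here because baseline-wander removal needs only this one
# orthogonal filter bank; coefficients are the standard db4 values.

DB4_DEC_LO <- c(-0.010597401785069032, 0.0328830116668852,
                0.030841381835560764, -0.18703481171909309,
                -0.027983769416859854, 0.6308807679298589,
                0.7148465705529157, 0.2303778133088965)
DB4_DEC_HI <- rev(DB4_DEC_LO) * rep(c(-1, 1), 4)

# one analysis step, periodic boundary; x must have even length
dwt_step <- function(x) {
  n <- length(x)
  k <- length(DB4_DEC_LO)
  half <- n / 2
  # a[j] = sum_m lo[m] * x[(2j + m - 2) mod n + 1], j = 1..n/2
  idx <- outer(2 * seq_len(half) - 2L, seq_len(k) - 1L, "+") %% n + 1L
  xm <- matrix(x[idx], nrow = half)
  list(a = drop(xm %*% DB4_DEC_LO), d = drop(xm %*% DB4_DEC_HI))
}

# inverse of dwt_step (periodic synthesis with time-reversed filters)
idwt_step <- function(a, d) {
  half <- length(a)
  n <- 2L * half
  k <- length(DB4_DEC_LO)
  x <- numeric(n)
  pos <- outer(2 * seq_len(half) - 2L, seq_len(k) - 1L, "+") %% n + 1L
  for (m in seq_len(k)) {
    p <- pos[, m]
    x[p] <- x[p] + DB4_DEC_LO[m] * a + DB4_DEC_HI[m] * d
  }
  x
}

# full decomposition to `levels`; returns list(a = coarsest, d = list of
# details, finest first)
dwt_multilevel <- function(x, levels) {
  d <- vector("list", levels)
  a <- x
  for (l in seq_len(levels)) {
    s <- dwt_step(a)
    a <- s$a
    d[[l]] <- s$d
  }
  list(a = a, d = d)
}

idwt_multilevel <- function(dec) {
  a <- dec$a
  for (l in rev(seq_along(dec$d))) a <- idwt_step(a, dec$d[[l]])
  a
}
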