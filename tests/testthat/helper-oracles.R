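# Independent brute-force oracles, kept deliberately naive: explicit loops
# and textbook formulas, sharing no code with the package implementations.

# V_ST from first principles: population variances via explicit sums,
# V_T over the pooled values, V_S size-weighted, (V_T - V_S) / V_T.
vst_oracle <- function(a, b) {
  popvar <- function(x) {
    m <- 0
    for (v in x) m <- m + v
    m <- m / length(x)
    s <- 0
    for (v in x) s <- s + (v - m)^2
    s / length(x)
  }
  pooled <- c(a, b)
  v_t <- popvar(pooled)
  v_s <- (length(a) * popvar(a) + length(b) * popvar(b)) / length(pooled)
  if (v_t == 0) 0 else (v_t - v_s) / v_t
}

# silhouette by enumerating every pair of points
silhouette_oracle <- function(values, labels) {
  n <- length(values)
  s <- numeric(n)
  for (i in seq_len(n)) {
    same <- d_same <- 0
    other_means <- c()
    for (lab in unique(labels[labels != labels[i]])) {
      tot <- cnt <- 0
      for (j in seq_len(n)) {
        if (labels[j] == lab) { tot <- tot + abs(values[i] - values[j]); cnt <- cnt + 1 }
      }
      other_means <- c(other_means, tot / cnt)
    }
    for (j in seq_len(n)) {
      if (j != i && labels[j] == labels[i]) {
        d_same <- d_same + abs(values[i] - values[j]); same <- same + 1
      }
    }
    if (same == 0) { s[i] <- 0; next }
    a <- d_same / same
    b <- min(other_means)
    s[i] <- if (max(a, b) > 0) (b - a) / max(a, b) else 0
  }
  mean(s)
}
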