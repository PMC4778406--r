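# Independent brute-force dominance oracle: a strategy is off the frontier
# iff some single strategy, or some convex combination of two strategies,
# attains at least its effect at strictly lower cost (or more effect at no
# greater cost). Checked by exhaustive enumeration; O(n^3), for small tables.
oracle_frontier_labels <- function(df, tol = 1e-9) {
  n <- nrow(df)
  keep <- rep(TRUE, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j == i) next
      if (df$cost[j] <= df$cost[i] && df$effect[j] >= df$effect[i] &&
          (df$cost[j] < df$cost[i] - tol || df$effect[j] > df$effect[i] + tol)) {
        keep[i] <- FALSE
      }
    }
    if (!keep[i]) next
    for (j in seq_len(n - 1)) {
      for (k in (j + 1):n) {
        if (j == i || k == i) next
        e1 <- df$effect[j]; e2 <- df$effect[k]
        if (e1 == e2) next
        lam <- (e2 - df$effect[i]) / (e2 - e1)
        if (lam < 0 || lam > 1) next   # effect_i outside the chord's span
        cc <- lam * df$cost[j] + (1 - lam) * df$cost[k]
        if (cc < df$cost[i] - tol) keep[i] <- FALSE
      }
    }
  }
  sort(df$label[keep])
}
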