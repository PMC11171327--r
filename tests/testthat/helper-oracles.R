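# Independent oracles used across the suite.  These deliberately avoid the
# package's own code paths.

# Brute-force product-limit estimator: explicit product over risk sets.
brute_km <- function(times, event) {
  ut <- sort(unique(times[event]))
  surv <- numeric(length(ut))
  for (j in seq_along(ut)) {
    s <- 1
    for (t in ut[seq_len(j)]) {
      n <- sum(times >= t)
      d <- sum(times == t & event)
      s <- s * (1 - d / n)
    }
    surv[j] <- s
  }
  list(time = ut, survival = surv)
}

# Brute-force Benjamini-Hochberg step-up from the definition:
# adj_i = min over j >= rank(i) of p_(j) * m / j, capped at 1.
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m)) {
    adj[i] <- min(pmin(1, ps[i:m] * m / (i:m)))
  }
  out <- numeric(m)
  out[o] <- adj
  out
}

# Piecewise-exponential model volume, written independently of the package.
oracle_volume <- function(v0, k_regress, effect_days, k_regrow, k_control, t) {
  if (effect_days <= 0) return(v0 * exp(k_control * t))
  ifelse(t <= effect_days,
         v0 * exp(k_regress * t),
         v0 * exp(k_regress * effect_days + k_regrow * (t - effect_days)))
}
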