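# Independent oracles kept deliberately separate from the package code
# paths they check.

# Exact Wilcoxon signed-rank two-sided p by literal enumeration of all 2^n
# sign assignments (n <= ~15). Same zero-drop / average-rank conventions.
wilcoxon_enumeration_oracle <- function(deltas) {
  d <- deltas[deltas != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- drop(signs %*% r)
  p_le <- mean(w_all <= w_obs + 1e-9)
  p_ge <- mean(w_all >= w_obs - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

# Event-level stochastic shuttle simulator. Each CETP encounter picks an
# unordered fraction pair with probability proportional to S_i * S_j and
# swaps one neutral lipid drawn from each core (TG with probability r).
# The net TG flux estimate for 20 batches of `batch` events is
#   J_hat_i = Lambda * mean_e(dTG_i per event),
# with Lambda = k * sum_{i<j} S_i S_j / S_tot the total encounter rate.
# Returns the batch-mean estimate and its standard error.
shuttle_simulate <- function(geoms, k = 1, n_batches = 20, batch = 5e4) {
  S <- vapply(geoms, `[[`, numeric(1), "surface")
  r <- vapply(geoms, `[[`, numeric(1), "core_tg_ratio")
  n <- length(S)
  pairs <- t(combn(n, 2))
  w <- S[pairs[, 1]] * S[pairs[, 2]]
  lambda <- k * sum(w) / sum(S)
  est <- matrix(0, n_batches, n)
  for (b in seq_len(n_batches)) {
    counts <- drop(rmultinom(1, batch, w))
    d_tg <- numeric(n)
    for (p in seq_len(nrow(pairs))) {
      if (counts[p] == 0) next
      i <- pairs[p, 1]
      j <- pairs[p, 2]
      # TG carried i -> j minus TG carried j -> i over counts[p] encounters
      from_i <- rbinom(1, counts[p], r[i])
      from_j <- rbinom(1, counts[p], r[j])
      d_tg[j] <- d_tg[j] + from_i - from_j
      d_tg[i] <- d_tg[i] - from_i + from_j
    }
    est[b, ] <- lambda * d_tg / batch
  }
  list(mean = colMeans(est),
       se = apply(est, 2, sd) / sqrt(n_batches))
}

# Closed-form two-pool relaxation: TG_1(t) for the linear system
# dTG1/dt = c (TG2/T2 - TG1/T1), c = k S1 S2 / S_tot (umol/l/h scale).
two_pool_closed_form <- function(tg0, totals, S, k, t) {
  c_rate <- k * S[1] * S[2] / sum(S) * 1e-3   # mmol/l per h per unit ratio
  rate <- c_rate * (1 / totals[1] + 1 / totals[2])
  r_eq <- sum(tg0) / sum(totals)
  tg1_eq <- totals[1] * r_eq
  tg1_eq + (tg0[1] - tg1_eq) * exp(-rate * t)
}
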