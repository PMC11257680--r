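# Independent oracles used by the unit tests.

# Stationary distribution of the full 2k-state cascade chain under random
# +/-1 events, by explicit transition-matrix power iteration. States are
# ordered (sign = +1, level 1..k) then (sign = -1, level 1..k).
oracle_cascade_stationary <- function(k, alpha) {
  P <- matrix(0, 2 * k, 2 * k)
  idx <- function(sign, lvl) if (sign > 0) lvl else k + lvl
  adv <- function(lvl) alpha^lvl
  sw <- function(lvl) if (lvl < k) alpha^(lvl - 1) else min(1, alpha^(k - 1) / (1 - alpha))
  for (s in c(1, -1)) {
    for (l in seq_len(k)) {
      i <- idx(s, l)
      # same-sign event (prob 1/2): advance with prob alpha^l if l < k
      if (l < k) {
        P[i, idx(s, l + 1)] <- P[i, idx(s, l + 1)] + 0.5 * adv(l)
        P[i, i] <- P[i, i] + 0.5 * (1 - adv(l))
      } else {
        P[i, i] <- P[i, i] + 0.5
      }
      # opposite-sign event (prob 1/2): reset to other sign, level 1
      P[i, idx(-s, 1)] <- P[i, idx(-s, 1)] + 0.5 * sw(l)
      P[i, i] <- P[i, i] + 0.5 * (1 - sw(l))
    }
  }
  v <- rep(1 / (2 * k), 2 * k)
  for (it in 1:4000) v <- as.vector(v %*% P)
  v
}

# Exact trajectory of one multivariable synapse chain driven by a given
# input sequence, from the linear difference equations (no saturation).
# inputs: numeric vector, one impulse to u_1 per timestep (0 = silent).
oracle_mv_trajectory <- function(inputs, m = 10L, n = 2, alpha = 0.5) {
  cin <- alpha * n^(-2 * seq_len(m) + 2)
  cout <- alpha * n^(-2 * seq_len(m) + 1)
  u <- numeric(m)
  out <- matrix(NA_real_, length(inputs), m)
  for (t in seq_along(inputs)) {
    u[1] <- u[1] + inputs[t]
    old <- u
    for (i in seq_len(m)) {
      up <- if (i > 1) cin[i] * (old[i - 1] - old[i]) else 0
      dn <- cout[i] * (old[i] - if (i < m) old[i + 1] else 0)
      u[i] <- old[i] + up - dn
    }
    out[t, ] <- u
  }
  out
}

# Steady-state recall SNR of a reliable memory for the dense binary switch
# with p = 1: the weights equal the most recent event, so the expected SNR
# is lambda * sqrt(N).
oracle_dense_p1_steady_snr <- function(N, lambda) lambda * sqrt(N)
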