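# Independent oracles used across the suite. Each re-derives its quantity
# by a different route than the implementation (enumeration, closed form,
# direct recomputation), so agreement is evidence rather than tautology.

# Closed-form spike count of a noiseless leaky integrate-and-fire neuron,
# iterated spike by spike (no vectorized shortcuts): first latency from
# rest, later intervals from the reset potential plus refractory time.
oracle_lif_count <- function(neuron, i_pa, step_dur_s = 0.5) {
  g_extra <- neuron$trpv4_conductance
  k <- 1 + neuron$input_resistance * g_extra / 1000
  tau <- neuron$membrane_tau / 1000 / k
  v_inf <- (neuron$v_rest + neuron$input_resistance *
              (i_pa + g_extra * neuron$trpv4_reversal) / 1000) / k
  if (v_inf <= neuron$v_threshold) return(0L)
  latency <- function(v0) {
    tau * log((v_inf - v0) / (v_inf - neuron$v_threshold))
  }
  t <- latency(neuron$v_rest)
  n <- 0L
  while (t < step_dur_s - 1e-12) {
    n <- n + 1L
    t <- t + neuron$refractory / 1000 + latency(neuron$v_reset)
  }
  n
}

# Exhaustive hypergeometric tail probability for the one-sided Fisher
# test on table [[a, b], [c, d]]: P(overlap >= a) with the margins fixed.
oracle_fisher_greater <- function(a, b, c, d) {
  n_sel <- a + b; n_set <- a + c; n_tot <- a + b + c + d
  ks <- max(0, n_sel + n_set - n_tot):min(n_sel, n_set)
  probs <- choose(n_set, ks) * choose(n_tot - n_set, n_sel - ks) /
    choose(n_tot, n_sel)
  sum(probs[ks >= a])
}

# Worst-case fold change by explicit double loop over replicate pairs.
oracle_wcfc <- function(a_vals, b_vals, eps = 0) {
  mags <- c(); sides <- c()
  for (x in a_vals) for (y in b_vals) {
    r <- (y + eps) / (x + eps)
    mags <- c(mags, max(r, 1 / r))
    sides <- c(sides, sign(log(r)))
  }
  list(
    wcfc = min(mags),
    direction = if (all(sides > 0)) "up" else if (all(sides < 0)) "down"
      else "discordant"
  )
}

# Spreadsheet-style ddCt recomputation, one sample at a time.
oracle_ddct <- function(ct_t, ct_r, group, control) {
  dct <- numeric(length(ct_t))
  for (i in seq_along(ct_t)) dct[i] <- ct_t[i] - ct_r[i]
  cal <- mean(dct[group == control])
  sapply(seq_along(dct), function(i) 2^(-(dct[i] - cal)))
}

# Biexponential EPSC with unit peak, for constructing synaptic sweeps.
epsc_wave <- function(t, onset, amp, rise = 0.0015, decay = 0.008) {
  u <- t - onset
  w <- ifelse(u >= 0, exp(-u / decay) - exp(-u / rise), 0)
  tp <- log(decay / rise) / (1 / rise - 1 / decay)
  amp * w / (exp(-tp / decay) - exp(-tp / rise))
}
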