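#' Leaky integrate-and-fire neuron parameters
#'
#' A minimal point-neuron model used to generate current-clamp sweeps with
#' known spike times. Defaults describe a medium spiny neuron-like cell:
#' hyperpolarized rest, no sag, moderate input resistance. An optional
#' ohmic TRP-like conductance (`trpv4_conductance`, reversal near 0 mV)
#' depolarizes the cell and lowers rheobase.
#'
#' @param membrane_tau Membrane time constant (ms).
#' @param input_resistance Input resistance (MOhm).
#' @param v_rest,v_threshold,v_reset Potentials (mV); `v_reset < v_threshold`.
#' @param refractory Absolute refractory period (ms).
#' @param trpv4_conductance Tonic cation conductance (nS).
#' @param trpv4_reversal Its reversal potential (mV).
#' @return An object of class `synthetic_neuron`.
#' @export
synthetic_neuron <- function(membrane_tau = 12, input_resistance = 150,
                             v_rest = -80, v_threshold = -40,
                             v_reset = -55, refractory = 4,
                             trpv4_conductance = 0, trpv4_reversal = 0) {
  if (v_reset >= v_threshold)
    stop_socphys("parameter_error", "v_reset must be below v_threshold")
  if (membrane_tau <= 0 || input_resistance <= 0)
    stop_socphys("parameter_error", "tau and input resistance must be > 0")
  if (trpv4_conductance < 0)
    stop_socphys("parameter_error", "conductances must be >= 0")
  structure(as.list(environment()), class = "synthetic_neuron")
}

# Effective linear dynamics of the LIF with a tonic ohmic conductance:
#   tau dV/dt = -(V - v_rest) + R/1000 * (I_inj - g (V - E))   [mV, pA, nS]
# reduces to dV/dt = -(V - v_inf)/tau_eff with
#   tau_eff = tau / (1 + R g / 1000)
#   v_inf   = (v_rest + R (I + g E)/1000) / (1 + R g / 1000)
lif_effective <- function(neuron, i_pa) {
  k <- 1 + neuron$input_resistance * neuron$trpv4_conductance / 1000
  list(
    tau_s = neuron$membrane_tau / 1000 / k,
    v_inf = (neuron$v_rest + neuron$input_resistance *
               (i_pa + neuron$trpv4_conductance * neuron$trpv4_reversal) /
               1000) / k
  )
}

#' Simulate a family of current-step sweeps from a LIF neuron
#'
#' Integrates the leaky integrate-and-fire dynamics over a depolarizing
#' step protocol (default 0-500 pA in 50 pA increments, 500 ms steps) using
#' the exact exponential update between grid points. In the noiseless case
#' threshold crossings are refined analytically within the grid interval,
#' so spike times are exact in continuous time and the spike count matches
#' the closed-form interspike-interval solution. Spike peaks are stamped
#' into the voltage trace (at `spike_peak` mV) so threshold-based detectors
#' see them.
#'
#' @param neuron A [synthetic_neuron()].
#' @param steps Injected currents (pA), ascending.
#' @param step_dur Step duration (ms).
#' @param rate Sampling rate (Hz).
#' @param pre_dur Pre-step baseline (ms).
#' @param noise_sd Per-sample membrane-noise SD (mV); 0 = deterministic.
#' @param spike_peak Stamped spike peak (mV).
#' @param seed Optional integer seed.
#' @return A list: `sweeps` (class `sweep_set`: `mode`, `t`, `traces`
#'   matrix time x steps, `sweep_labels` pA, `rate`, `stim_window` s) and
#'   `truth` (list of spike-time vectors per step, continuous time).
#' @export
simulate_fi_sweeps <- function(neuron, steps = seq(0, 500, by = 50),
                               step_dur = 500, rate = 50000,
                               pre_dur = 50, noise_sd = 0,
                               spike_peak = 30, seed = NULL) {
  if (rate <= 0) stop_socphys("parameter_error", "rate must be > 0")
  if (is.unsorted(steps)) stop_socphys("parameter_error", "steps must ascend")
  if (!is.null(seed)) set.seed(seed)
  dt <- 1 / rate
  t_on <- pre_dur / 1000
  t_off <- t_on + step_dur / 1000
  t <- seq(0, t_off + 0.05, by = dt)
  refr <- neuron$refractory / 1000

  traces <- matrix(NA_real_, length(t), length(steps))
  truth <- vector("list", length(steps))
  names(truth) <- paste0(steps, "pA")

  for (s in seq_along(steps)) {
    v <- numeric(length(t)); v[1] <- neuron$v_rest
    spikes <- numeric()
    lock_until <- -Inf
    for (i in 2:length(t)) {
      i_inj <- if (t[i - 1] >= t_on && t[i - 1] < t_off) steps[s] else 0
      eff <- lif_effective(neuron, i_inj)
      t0 <- max(t[i - 1], lock_until)
      v0 <- if (t[i - 1] < lock_until) neuron$v_reset else v[i - 1]
      if (t[i] <= lock_until) {
        v[i] <- neuron$v_reset
        next
      }
      v1 <- eff$v_inf + (v0 - eff$v_inf) * exp(-(t[i] - t0) / eff$tau_s)
      if (noise_sd > 0) v1 <- v1 + rnorm(1, 0, noise_sd)
      if (v1 >= neuron$v_threshold) {
        t_cross <- if (noise_sd == 0 && eff$v_inf > neuron$v_threshold) {
          t0 + eff$tau_s *
            log((eff$v_inf - v0) / (eff$v_inf - neuron$v_threshold))
        } else t[i]
        spikes <- c(spikes, t_cross)
        lock_until <- t_cross + refr
        v[i] <- spike_peak  # stamped peak for threshold detectors
      } else {
        v[i] <- v1
      }
    }
    traces[, s] <- v
    truth[[s]] <- spikes[spikes >= t_on & spikes < t_off]
  }

  sweeps <- structure(
    list(mode = "current-clamp", t = t, traces = traces,
         sweep_labels = steps, rate = rate,
         stim_window = c(t_on, t_off)),
    class = "sweep_set"
  )
  list(sweeps = sweeps, truth = truth)
}

#' Closed-form noiseless LIF spike count
#'
#' Continuous-time solution used as an oracle: first spike latency from
#' rest `tau_eff * log((v_inf - v_rest)/(v_inf - v_th))`, subsequent
#' interspike intervals from `v_reset` plus the refractory period; counts
#' spikes fitting in the step window.
#'
#' @param neuron A [synthetic_neuron()].
#' @param i_pa Injected current (pA).
#' @param step_dur Step duration (ms).
#' @return Integer spike count.
#' @export
lif_spike_count <- function(neuron, i_pa, step_dur = 500) {
  eff <- lif_effective(neuron, i_pa)
  win <- step_dur / 1000
  if (eff$v_inf <= neuron$v_threshold) return(0L)
  refr <- neuron$refractory / 1000
  t1 <- eff$tau_s *
    log((eff$v_inf - neuron$v_rest) / (eff$v_inf - neuron$v_threshold))
  isi <- refr + eff$tau_s *
    log((eff$v_inf - neuron$v_reset) / (eff$v_inf - neuron$v_threshold))
  if (t1 >= win) return(0L)
  length(seq(t1, win - 1e-12, by = isi))
}

#' Simulate a voltage-ramp drug-subtraction session
#'
#' Emulates repeated voltage-clamp ramps (default -100 to +100 mV over 400
#' ms, every 5 s): per-sweep current is leak plus a tonic ohmic TRP-like
#' conductance during the baseline phase; the TRP term disappears at the
#' drug-application timestamp, emulating a selective blocker.
#'
#' @param neuron A [synthetic_neuron()]; leak conductance is
#'   `1000/input_resistance` nS reversing at `v_rest`.
#' @param ramp_v Ramp voltage range (mV).
#' @param n_v Number of samples on the voltage grid.
#' @param period Sweep period (s).
#' @param baseline_dur Baseline phase (min).
#' @param drug_dur Drug phase (min).
#' @param noise_sd Per-sample current noise SD (pA).
#' @param seed Optional integer seed.
#' @return An object of class `ramp_recording`: `sweep_times` (s),
#'   `current` matrix sweeps x voltage grid (pA), `v_grid` (mV),
#'   `drug_onset` (s).
#' @export
simulate_ramp_session <- function(neuron, ramp_v = c(-100, 100), n_v = 201,
                                  period = 5, baseline_dur = 5,
                                  drug_dur = 20, noise_sd = 0,
                                  seed = NULL) {
  if (period <= 0 || baseline_dur <= 0 || drug_dur <= 0)
    stop_socphys("parameter_error", "durations must be > 0")
  if (!is.null(seed)) set.seed(seed)
  v_grid <- seq(ramp_v[1], ramp_v[2], length.out = n_v)
  drug_onset <- baseline_dur * 60
  total <- (baseline_dur + drug_dur) * 60
  sweep_times <- seq(0, total - period, by = period)
  g_leak <- 1000 / neuron$input_resistance  # nS
  cur <- matrix(NA_real_, length(sweep_times), n_v)
  for (k in seq_along(sweep_times)) {
    i_leak <- g_leak * (v_grid - neuron$v_rest)
    i_trp <- if (sweep_times[k] < drug_onset)
      neuron$trpv4_conductance * (v_grid - neuron$trpv4_reversal) else 0
    noise <- if (noise_sd > 0) rnorm(n_v, 0, noise_sd) else 0
    cur[k, ] <- i_leak + i_trp + noise
  }
  structure(
    list(sweep_times = sweep_times, current = cur, v_grid = v_grid,
         drug_onset = drug_onset),
    class = "ramp_recording"
  )
}
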