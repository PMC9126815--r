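#' Double-exponential fluorescence response kernel
#'
#' `exp(-t/decay) - exp(-t/rise)` for `t >= 0`, scaled to peak 1, zero for
#' `t < 0`. Models the rise and decay of a slow calcium indicator transient.
#'
#' @param t Time from response onset (s); may be a vector.
#' @param rise_tau,decay_tau Time constants (s), `rise_tau < decay_tau`.
#' @return Kernel values, peak-normalized to 1.
#' @export
dexp_kernel <- function(t, rise_tau = 0.2, decay_tau = 1.6) {
  if (rise_tau <= 0 || decay_tau <= rise_tau)
    stop_socphys("parameter_error", "need 0 < rise_tau < decay_tau")
  t_peak <- log(decay_tau / rise_tau) /
    (1 / rise_tau - 1 / decay_tau)
  peak <- exp(-t_peak / decay_tau) - exp(-t_peak / rise_tau)
  k <- ifelse(t >= 0, exp(-t / decay_tau) - exp(-t / rise_tau), 0)
  k / peak
}

#' Simulate a two-channel fiber photometry session
#'
#' Emulates an interleaved-LED recording: a calcium-dependent 465 nm channel
#' carrying event-locked transients at the ground-truth entry times, and a
#' calcium-independent 405 nm isosbestic channel. Both channels share slow
#' photobleaching, white noise, and (optionally) an identical additive
#' motion artifact; only the 465 channel carries the event term. An
#' `led_state` column alternates between the two LEDs in square pulses.
#'
#' The event term is `baseline * amplitude * kernel`, so the planted
#' amplitude is recovered on the dF/F scale after baseline normalization.
#'
#' @param truth A [session_truth()] with entry times and kinetics.
#' @param duration Recording length (s); must cover all entry times.
#' @param raw_rate Acquisition rate (Hz).
#' @param led_alt_rate LED alternation rate (Hz): pulses of `1/led_alt_rate`
#'   s alternate 465/405, i.e. each channel is illuminated at
#'   `led_alt_rate/2` Hz.
#' @param baseline_465,baseline_405 Baseline fluorescence (a.u.).
#' @param motion_times,motion_amplitude,motion_dur Optional shared artifact:
#'   square transients of the given amplitude (a.u.) and length (s).
#' @param habituation_dur Length of the habituation phase at the start of
#'   the recording (s); stored for downstream F0 selection.
#' @param seed Optional integer seed.
#'
#' @return An object of class `photometry_session`: data frame `t_s`,
#'   `f465`, `f405`, `led_state` with attributes `raw_rate`,
#'   `led_alt_rate`, `habituation_interval`, `test_interval`, `truth`.
#' @export
simulate_photometry <- function(truth, duration,
                                raw_rate = 12000, led_alt_rate = 40,
                                baseline_465 = 100, baseline_405 = 60,
                                motion_times = numeric(),
                                motion_amplitude = 0, motion_dur = 0.5,
                                habituation_dur = 0, seed = NULL) {
  ev <- c(truth$entry_times_social, truth$entry_times_object)
  if (length(ev) && max(ev) > duration)
    stop_socphys("parameter_error", "duration does not cover all entry times")
  if (truth$event_response_amplitude < 0 || truth$noise_sd < 0)
    stop_socphys("parameter_error", "amplitude and noise_sd must be >= 0")
  if (!is.null(seed)) set.seed(seed)

  t <- seq(0, duration, by = 1 / raw_rate)
  n <- length(t)
  bleach <- if (is.finite(truth$bleach_tau)) exp(-t / truth$bleach_tau) else 1

  event_term <- numeric(n)
  a <- truth$event_response_amplitude
  if (a > 0) {
    for (t0 in sort(c(truth$entry_times_social))) {
      on <- truth$response_latency + t0
      idx <- which(t >= on & t <= on + 8 * truth$decay_tau)
      event_term[idx] <- event_term[idx] +
        a * dexp_kernel(t[idx] - on, truth$rise_tau, truth$decay_tau)
    }
  }

  motion <- numeric(n)
  for (m0 in motion_times) {
    idx <- which(t >= m0 & t < m0 + motion_dur)
    motion[idx] <- motion[idx] + motion_amplitude
  }

  noise465 <- if (truth$noise_sd > 0)
    rnorm(n, 0, truth$noise_sd * baseline_465) else 0
  noise405 <- if (truth$noise_sd > 0)
    rnorm(n, 0, truth$noise_sd * baseline_405) else 0

  f465 <- baseline_465 * bleach + baseline_465 * event_term + motion + noise465
  f405 <- baseline_405 * bleach + motion + noise405

  # square-pulse alternation: pulse k covers [k, k+1)/led_alt_rate and is
  # 465 for even k, 405 for odd k
  pulse <- floor(t * led_alt_rate)
  led_state <- ifelse(pulse %% 2 == 0, "465", "405")

  session <- data.frame(t_s = t, f465 = f465, f405 = f405,
                        led_state = led_state)
  attr(session, "raw_rate") <- raw_rate
  attr(session, "led_alt_rate") <- led_alt_rate
  attr(session, "habituation_interval") <- c(0, habituation_dur)
  attr(session, "test_interval") <- c(habituation_dur, duration)
  attr(session, "truth") <- truth
  class(session) <- c("photometry_session", "data.frame")
  session
}
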