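#' Construct a sweep set
#'
#' Container for a family of electrophysiology sweeps sharing one time
#' base: current-clamp voltage traces labeled by injected current, or
#' voltage-clamp current traces labeled by holding potential.
#'
#' @param mode `"current-clamp"` or `"voltage-clamp"`.
#' @param t Time base (s).
#' @param traces Matrix time x sweeps (mV or pA).
#' @param sweep_labels Injected pA or holding mV, one per sweep; unique.
#' @param rate Sampling rate (Hz).
#' @param stim_window For step protocols, `c(on, off)` s.
#' @param stim_onsets For synaptic protocols, stimulation times (s).
#' @return An object of class `sweep_set`.
#' @export
sweep_set <- function(mode = c("current-clamp", "voltage-clamp"),
                      t, traces, sweep_labels, rate,
                      stim_window = NULL, stim_onsets = NULL) {
  mode <- match.arg(mode)
  traces <- as.matrix(traces)
  if (length(t) != nrow(traces))
    stop_socphys("parameter_error", "t and traces must share the time base")
  if (length(sweep_labels) != ncol(traces))
    stop_socphys("parameter_error", "one label per sweep required")
  if (anyDuplicated(sweep_labels))
    stop_socphys("parameter_error", "sweep labels must be unique")
  structure(
    list(mode = mode, t = t, traces = traces,
         sweep_labels = sweep_labels, rate = rate,
         stim_window = stim_window, stim_onsets = stim_onsets),
    class = "sweep_set"
  )
}

#' Detect action potentials by threshold crossing
#'
#' Upward crossings of the voltage threshold separated by at least
#' `min_isi`; optionally restricted to a time window (e.g. the current
#' step).
#'
#' @param t Time base (s).
#' @param v Membrane voltage (mV).
#' @param threshold Crossing threshold (mV).
#' @param min_isi Minimum interspike interval (s).
#' @param window Optional `c(start, stop)` s; spikes outside are ignored.
#' @return Spike times (s).
#' @export
detect_spikes <- function(t, v, threshold = 0, min_isi = 0.002,
                          window = NULL) {
  up <- which(v[-1] >= threshold & v[-length(v)] < threshold) + 1
  times <- t[up]
  if (length(times) > 1) {
    # greedy pass: keep a crossing only if min_isi past the last kept one
    last <- times[1]; sel <- TRUE
    for (k in seq_along(times)[-1]) {
      ok <- (times[k] - last) >= min_isi
      sel <- c(sel, ok)
      if (ok) last <- times[k]
    }
    times <- times[sel]
  }
  if (!is.null(window))
    times <- times[times >= window[1] & times < window[2]]
  times
}

#' F-I curve: spike counts across current steps
#'
#' Counts action potentials within the step window of every sweep of a
#' current-clamp step protocol.
#'
#' @param sweeps A current-clamp [sweep_set()] with `stim_window`.
#' @param threshold,min_isi Detector parameters, see [detect_spikes()].
#' @return An object of class `fi_curve`: data frame `step_pA`, `n_ap`.
#' @export
fi_curve <- function(sweeps, threshold = 0, min_isi = 0.002) {
  if (sweeps$mode != "current-clamp")
    stop_socphys("mode_error", "F-I curve requires current-clamp sweeps")
  counts <- vapply(seq_along(sweeps$sweep_labels), function(j) {
    length(detect_spikes(sweeps$t, sweeps$traces[, j], threshold, min_isi,
                         window = sweeps$stim_window))
  }, numeric(1))
  res <- data.frame(step_pA = sweeps$sweep_labels, n_ap = as.integer(counts))
  class(res) <- c("fi_curve", "data.frame")
  res
}

#' Access resistance from the -4 mV monitor step
#'
#' `Ra (MOhm) = dV / I_peak`, with the -4 mV step and the peak transient
#' current in pA: `Ra = 1000 * dV_mV / I_peak_pA`.
#'
#' @param i_peak_pa Peak transient current (pA), same sign as the step.
#' @param v_step_mv Monitor step (mV).
#' @return Access resistance (MOhm).
#' @export
access_resistance <- function(i_peak_pa, v_step_mv = -4) {
  1000 * v_step_mv / i_peak_pa
}

#' Cell quality control for MSN recordings
#'
#' Applies the inclusion rules: resting membrane potential below -60 mV,
#' absence of a sag (Ih-like) current in the -140 mV voltage-clamp step,
#' and stability of the access resistance (maximum relative change from
#' the first monitor value at most 20%; exactly 20% passes).
#'
#' The sag test compares the instantaneous current just after the step
#' (window `inst_window` s after onset) with the steady-state current at
#' the step end: a slow further inward growth beyond `sag_threshold`
#' (relative) flags Ih.
#'
#' @param rmp_mv Resting membrane potential samples (mV); averaged.
#' @param ih_sweep Optional list/data frame with `t` and `i_pa` for the
#'   -140 mV step, plus the step window `ih_window` `c(on, off)` s.
#' @param ih_window Step window for `ih_sweep` (s).
#' @param ra_series_mohm Access-resistance monitor series (MOhm).
#' @param sag_threshold Relative sag beyond which Ih is flagged.
#' @param ra_max_change Maximum allowed relative Ra change.
#' @param inst_window `c(start, stop)` s after step onset for the
#'   instantaneous current.
#' @param ss_fraction Trailing fraction of the step used as steady state.
#' @return An object of class `cell_qc`: list with `rmp`, `has_ih`,
#'   `ra_change`, `passes`, `reasons`, `qc_complete`.
#' @export
cell_qc <- function(rmp_mv, ih_sweep = NULL, ih_window = NULL,
                    ra_series_mohm = NULL,
                    sag_threshold = 0.1, ra_max_change = 0.2,
                    inst_window = c(0.005, 0.02), ss_fraction = 0.2) {
  rmp <- mean(rmp_mv)
  reasons <- character()
  qc_complete <- TRUE

  has_ih <- NA
  if (!is.null(ih_sweep)) {
    if (is.null(ih_window))
      stop_socphys("parameter_error", "ih_window required with ih_sweep")
    on <- ih_window[1]; off <- ih_window[2]
    inst <- mean(ih_sweep$i_pa[ih_sweep$t >= on + inst_window[1] &
                                 ih_sweep$t <= on + inst_window[2]])
    ss <- mean(ih_sweep$i_pa[ih_sweep$t >= off - ss_fraction * (off - on) &
                               ih_sweep$t <= off])
    sag <- (inst - ss) / max(abs(inst), 1)  # inward growth: ss < inst < 0
    has_ih <- is.finite(sag) && sag > sag_threshold
  } else {
    qc_complete <- FALSE
    reasons <- c(reasons, "Ih protocol absent")
  }

  ra_change <- NA_real_
  if (!is.null(ra_series_mohm) && length(ra_series_mohm) >= 1) {
    ra_change <- max(abs(ra_series_mohm - ra_series_mohm[1])) /
      ra_series_mohm[1]
  } else {
    qc_complete <- FALSE
    reasons <- c(reasons, "Ra monitor absent")
  }

  if (!(rmp < -60)) reasons <- c(reasons, sprintf("RMP %.1f mV >= -60", rmp))
  if (isTRUE(has_ih)) reasons <- c(reasons, "sag (Ih) current present")
  if (is.finite(ra_change) && ra_change > ra_max_change)
    reasons <- c(reasons,
                 sprintf("access resistance changed %.0f%% > %.0f%%",
                         100 * ra_change, 100 * ra_max_change))
  passes <- qc_complete && rmp < -60 && identical(has_ih, FALSE) &&
    is.finite(ra_change) && ra_change <= ra_max_change
  structure(
    list(rmp = rmp, has_ih = has_ih, ra_change = ra_change,
         passes = passes, reasons = reasons, qc_complete = qc_complete),
    class = "cell_qc"
  )
}

#' Drug-subtracted ramp current (I-V curve)
#'
#' Averages the ramp sweeps within the baseline and drug windows and
#' subtracts: `IV(V) = mean_baseline I(V) - mean_drug I(V)` on the common
#' voltage grid. This isolates the blocker-sensitive conductance.
#'
#' @param rec A `ramp_recording`.
#' @param baseline_window `c(start, stop)` s, entirely before `drug_onset`.
#' @param drug_window `c(start, stop)` s, entirely after
#'   `drug_onset + equilibration`.
#' @param equilibration Settling time after drug onset (s) excluded from
#'   the drug window.
#' @return Data frame `v_mV`, `i_pA` with attribute `n_sweeps`
#'   (baseline, drug).
#' @export
trpv4_current <- function(rec, baseline_window = NULL, drug_window = NULL,
                          equilibration = 0) {
  total <- max(rec$sweep_times)
  baseline_window <- baseline_window %||% c(0, rec$drug_onset)
  drug_window <- drug_window %||% c(max(rec$drug_onset + equilibration,
                                        total - 300), total)
  if (baseline_window[2] > rec$drug_onset ||
      drug_window[1] < rec$drug_onset + equilibration)
    stop_socphys("window_error",
                 "windows must not overlap the drug transition")
  bsel <- rec$sweep_times >= baseline_window[1] &
    rec$sweep_times <= baseline_window[2] &
    rec$sweep_times < rec$drug_onset  # the onset sweep is already drug
  dsel <- rec$sweep_times >= drug_window[1] &
    rec$sweep_times <= drug_window[2]
  if (sum(bsel) < 3 || sum(dsel) < 3)
    stop_socphys("window_error", "each window needs at least 3 sweeps")
  iv <- colMeans(rec$current[bsel, , drop = FALSE]) -
    colMeans(rec$current[dsel, , drop = FALSE])
  out <- data.frame(v_mV = rec$v_grid, i_pA = iv)
  attr(out, "n_sweeps") <- c(baseline = sum(bsel), drug = sum(dsel))
  out
}

#' Chord conductance
#'
#' `g = I / (V - E_rev)` in nS for I in pA and V in mV.
#'
#' @param i_pa Current (pA).
#' @param v_mv Holding potential (mV).
#' @param e_rev Reversal potential (mV).
#' @return Conductance (nS).
#' @export
chord_conductance <- function(i_pa, v_mv, e_rev = 0) {
  if (v_mv == e_rev)
    stop_socphys("parameter_error", "holding equals reversal potential")
  i_pa / (v_mv - e_rev)
}

epsc_amplitude <- function(t, i, stim_t, peak_window = c(0.001, 0.04),
                           baseline_window = c(-0.005, 0),
                           statistic = c("peak", "mean")) {
  statistic <- match.arg(statistic)
  base <- mean(i[t >= stim_t + baseline_window[1] &
                   t <= stim_t + baseline_window[2]])
  seg <- i[t >= stim_t + peak_window[1] & t <= stim_t + peak_window[2]] - base
  if (!length(seg)) stop_socphys("protocol_error", "empty response window")
  if (statistic == "peak") seg[which.max(abs(seg))] else mean(seg)
}

#' Synaptic transmission metrics
#'
#' Computes one of three standard evoked-EPSC metrics from voltage-clamp
#' sweeps labeled by holding potential, with per-pulse local baseline
#' subtraction:
#'
#' * `"ampa_nmda"`: ratio of the peak response at -70 mV (AMPA-dominated)
#'   to the late-window mean response at +35 mV (NMDA-dominated; default
#'   window 45-55 ms after the stimulus, when the fast AMPA component has
#'   decayed).
#' * `"rectification"`: chord conductance at the negative holding
#'   potential divided by the chord conductance at the positive one
#'   (peak amplitudes; reversal 0 mV by default). Holding labels -60/+40
#'   are expected; +35 is accepted for the positive arm.
#' * `"ppr"`: second over first EPSC peak for a paired-pulse protocol
#'   (two `stim_onsets`, conventionally 50 ms apart).
#'
#' @param sweeps A voltage-clamp [sweep_set()] with `stim_onsets` and
#'   holding potentials as `sweep_labels`.
#' @param protocol One of `"ampa_nmda"`, `"rectification"`, `"ppr"`.
#' @param peak_window Post-stimulus window for peak amplitudes (s).
#' @param nmda_window Post-stimulus late window for the NMDA component (s).
#' @param baseline_window Pre-stimulus baseline window (s, relative).
#' @param e_rev Reversal potential for chord conductances (mV).
#' @return A named list with the requested ratio and its components.
#' @export
synaptic_metrics <- function(sweeps,
                             protocol = c("ampa_nmda", "rectification",
                                          "ppr"),
                             peak_window = c(0.001, 0.04),
                             nmda_window = c(0.045, 0.055),
                             baseline_window = c(-0.005, 0),
                             e_rev = 0) {
  protocol <- match.arg(protocol)
  if (sweeps$mode != "voltage-clamp")
    stop_socphys("mode_error", "synaptic metrics require voltage-clamp")
  if (is.null(sweeps$stim_onsets) || !length(sweeps$stim_onsets))
    stop_socphys("protocol_error", "stim_onsets required")
  lab <- sweeps$sweep_labels
  pick <- function(v) {
    j <- which(lab == v)
    if (!length(j))
      stop_socphys("protocol_error",
                   sprintf("no sweep at holding %g mV", v))
    sweeps$traces[, j[1]]
  }
  s1 <- sweeps$stim_onsets[1]
  if (protocol == "ampa_nmda") {
    amp70 <- abs(epsc_amplitude(sweeps$t, pick(-70), s1, peak_window,
                                baseline_window, "peak"))
    nmda <- abs(epsc_amplitude(sweeps$t, pick(35), s1, nmda_window,
                               baseline_window, "mean"))
    list(ampa_nmda = amp70 / nmda, amp_minus70 = amp70, amp_plus35 = nmda)
  } else if (protocol == "rectification") {
    v_pos <- if (40 %in% lab) 40 else if (35 %in% lab) 35 else
      stop_socphys("protocol_error", "no positive holding sweep (+40/+35)")
    i_neg <- epsc_amplitude(sweeps$t, pick(-60), s1, peak_window,
                            baseline_window, "peak")
    i_pos <- epsc_amplitude(sweeps$t, pick(v_pos), s1, peak_window,
                            baseline_window, "peak")
    g_neg <- chord_conductance(i_neg, -60, e_rev)
    g_pos <- chord_conductance(i_pos, v_pos, e_rev)
    list(rectification = g_neg / g_pos, g_neg = g_neg, g_pos = g_pos)
  } else {
    if (length(sweeps$stim_onsets) < 2)
      stop_socphys("protocol_error", "ppr requires two stimulus onsets")
    s2 <- sweeps$stim_onsets[2]
    tr <- sweeps$traces[, 1]
    # second pulse's peak window must not reach into the first response:
    # local baselines immediately before each pulse
    a1 <- abs(epsc_amplitude(sweeps$t, tr, s1, peak_window,
                             baseline_window, "peak"))
    a2 <- abs(epsc_amplitude(sweeps$t, tr, s2, peak_window,
                             baseline_window, "peak"))
    list(ppr = a2 / a1, amp1 = a1, amp2 = a2)
  }
}
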