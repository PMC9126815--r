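#' Demultiplex an interleaved two-LED photometry recording
#'
#' Splits the raw recording into one trace per excitation channel using the
#' LED-state column: every contiguous on-pulse of a channel yields one
#' sample equal to the mean of its in-pulse raw samples after discarding
#' the leading settle fraction (LED rise time); the sample is timestamped
#' at the pulse center. Off-state samples are ignored.
#'
#' @param session A `photometry_session` (or data frame with `t_s`,
#'   `f465`, `f405`, `led_state` in `{"465","405","off"}`).
#' @param settle_discard Leading fraction of each pulse to discard; at
#'   least one sample per pulse is always retained.
#' @return List with `ch465` and `ch405`, each a data frame `t_s`, `f`.
#' @export
demultiplex <- function(session, settle_discard = 0.2) {
  if (is.null(session$led_state))
    stop_socphys("demux_error", "led_state column missing")
  if (settle_discard < 0 || settle_discard >= 1)
    stop_socphys("demux_error", "settle_discard must be in [0, 1)")
  runs <- rle(as.character(session$led_state))
  run_id <- rep(seq_along(runs$lengths), runs$lengths)
  run_len <- rep(runs$lengths, runs$lengths)
  pos <- sequence(runs$lengths)
  retained <- pos > floor(settle_discard * run_len)
  pulse_means <- function(state, column) {
    k <- which(runs$values == state)
    if (!length(k))
      stop_socphys("demux_error", paste("no pulses for channel", state))
    in_state <- run_id %in% k
    tt <- tapply(session$t_s[in_state], run_id[in_state], mean)
    sel <- in_state & retained
    if (!all(k %in% unique(run_id[sel])))
      stop_socphys("demux_error", "pulse with zero retained samples")
    ff <- tapply(session[[column]][sel], run_id[sel], mean)
    data.frame(t_s = as.numeric(tt), f = as.numeric(ff))
  }
  list(ch465 = pulse_means("465", "f465"),
       ch405 = pulse_means("405", "f405"))
}

#' Fractional fluorescence change (dF/F)
#'
#' `dff(t) = (F(t) - F0)/F0` with `F0` the baseline statistic (mean by
#' default) of the fluorescence over the baseline window, conventionally
#' the last minutes of the habituation phase before the stimuli are
#' presented.
#'
#' @param trace Data frame `t_s`, `f` (one demultiplexed channel).
#' @param f0_window `c(start, stop)` in s, inside the recording.
#' @param statistic Baseline statistic: `"mean"` (default) or `"median"`.
#' @return An object of class `dff_trace`: data frame `t_s`, `dff`, with
#'   attributes `f0`, `f0_window`, `correction_mode = "none"`.
#' @export
compute_dff <- function(trace, f0_window, statistic = c("mean", "median")) {
  statistic <- match.arg(statistic)
  sel <- trace$t_s >= f0_window[1] & trace$t_s <= f0_window[2]
  if (!any(sel))
    stop_socphys("baseline_error", "f0_window contains no samples")
  f0 <- if (statistic == "mean") mean(trace$f[sel]) else median(trace$f[sel])
  if (!is.finite(f0) || f0 <= 0)
    stop_socphys("baseline_error", "baseline F0 must be positive")
  out <- data.frame(t_s = trace$t_s, dff = (trace$f - f0) / f0)
  attr(out, "f0") <- f0
  attr(out, "f0_window") <- f0_window
  attr(out, "correction_mode") <- "none"
  class(out) <- c("dff_trace", "data.frame")
  out
}

#' Isosbestic motion correction (optional path)
#'
#' Least-squares fit of the isosbestic 405 nm channel onto the 465 nm
#' channel over `fit_window`; the corrected trace is
#' `(F465 - fitted405)/fitted405`. Off by default in the pipeline, which
#' uses the plain baseline-window dF/F; provided for robustness studies of
#' shared motion artifacts.
#'
#' @param trace465,trace405 Data frames `t_s`, `f`; the 405 channel is
#'   linearly interpolated onto the 465 timestamps (interleaved-LED demux
#'   samples the two channels at alternating pulse centers).
#' @param fit_window Optional `c(start, stop)` s; default the whole trace.
#' @return A `dff_trace` with `correction_mode = "isosbestic"` and the fit
#'   coefficients in attribute `fit`.
#' @export
isosbestic_correct <- function(trace465, trace405, fit_window = NULL) {
  f405 <- approx(trace405$t_s, trace405$f, xout = trace465$t_s,
                 rule = 2)$y
  sel <- if (is.null(fit_window)) rep(TRUE, nrow(trace465)) else
    trace465$t_s >= fit_window[1] & trace465$t_s <= fit_window[2]
  if (var(f405[sel]) == 0)
    stop_socphys("correction_error", "degenerate fit: 405 channel constant")
  fit <- lm(trace465$f[sel] ~ f405[sel])
  fitted <- coef(fit)[1] + coef(fit)[2] * f405
  if (any(fitted <= 0))
    stop_socphys("correction_error", "fitted 405 reference non-positive")
  out <- data.frame(t_s = trace465$t_s,
                    dff = (trace465$f - fitted) / fitted)
  attr(out, "correction_mode") <- "isosbestic"
  attr(out, "fit") <- coef(fit)
  class(out) <- c("dff_trace", "data.frame")
  out
}

#' Build a peri-event time histogram (PETH)
#'
#' Aligns the dF/F trace on event times: one row per included event,
#' linearly interpolated onto a relative time grid spanning
#' `[window[1], window[2]]` around the event (the grid always contains 0).
#' Events whose window exceeds the recording bounds are dropped and
#' reported in the `dropped` attribute.
#'
#' @param dff A `dff_trace`.
#' @param events An `entry_events` data frame (only rows with
#'   `included == TRUE` are used) or a data frame with `t_entry` and
#'   `stimulus`.
#' @param window `c(-T_pre, T_post)` s.
#' @param bin Grid spacing (s); default the median sampling interval of
#'   `dff`.
#' @return An object of class `peth`: list with `time` (relative grid),
#'   `mat` (events x bins), `events` (provenance: stimulus, t_entry),
#'   `mean` (per-bin mean over all rows).
#' @export
build_peth <- function(dff, events, window = c(-5, 10), bin = NULL) {
  if (!all(is.finite(window)) || window[1] >= window[2])
    stop_socphys("parameter_error", "window must be finite and increasing")
  ev <- as.data.frame(events)
  if (!is.null(ev$included)) ev <- ev[ev$included, , drop = FALSE]
  bin <- bin %||% median(diff(dff$t_s))
  grid <- sort(unique(c(seq(0, window[1], by = -bin),
                        seq(0, window[2], by = bin))))
  ok <- ev$t_entry + window[1] >= min(dff$t_s) &
    ev$t_entry + window[2] <= max(dff$t_s)
  dropped <- ev[!ok, , drop = FALSE]
  ev <- ev[ok, , drop = FALSE]
  if (nrow(ev) == 0)
    stop_socphys("empty_peth_error", "no usable events for PETH")
  mat <- t(vapply(ev$t_entry, function(t0) {
    approx(dff$t_s, dff$dff, xout = t0 + grid)$y
  }, numeric(length(grid))))
  res <- structure(
    list(time = grid, mat = mat,
         events = data.frame(event_id = seq_len(nrow(ev)),
                             stimulus = ev$stimulus,
                             t_entry = ev$t_entry),
         mean = colMeans(mat)),
    class = "peth"
  )
  attr(res, "dropped") <- dropped
  res
}

#' @export
print.peth <- function(x, ...) {
  cat(sprintf("<peth> %d events x %d bins, window [%g, %g] s\n",
              nrow(x$mat), length(x$time), min(x$time), max(x$time)))
  invisible(x)
}

#' Session z-score normalization and post-entry window summary
#'
#' Normalizes the PETH to session z-scores,
#' `z(bin) = (peth_mean(bin) - mu)/sigma`, where `mu` and `sigma` are the
#' mean and SD of the whole-session dF/F trace supplied (by convention the
#' test phase), then averages z over the summary window (default the 5 s
#' after the entry, `[0, 5]`, closed). Per-event z summaries are retained
#' for paired statistics.
#'
#' @param peth A [build_peth()] result.
#' @param session_dff The `dff_trace` defining the normalization constants.
#' @param summary_window `c(start, stop)` s relative to the event.
#' @return An object of class `window_stat`: list with `per_stimulus`
#'   (stimulus, mean_z, n_events), `per_event` (event_id, stimulus,
#'   mean_z), `z_mean` (per-bin z of the PETH mean), `mu`, `sigma`,
#'   `summary_window`.
#' @export
peth_zscore_summary <- function(peth, session_dff, summary_window = c(0, 5)) {
  mu <- mean(session_dff$dff)
  sigma <- sd(session_dff$dff)
  if (!is.finite(sigma) || sigma == 0)
    stop_socphys("normalization_error", "zero session variance")
  zmat <- (peth$mat - mu) / sigma
  inwin <- peth$time >= summary_window[1] & peth$time <= summary_window[2]
  per_event <- data.frame(
    event_id = peth$events$event_id,
    stimulus = peth$events$stimulus,
    mean_z = rowMeans(zmat[, inwin, drop = FALSE])
  )
  stimuli <- unique(peth$events$stimulus)
  per_stimulus <- do.call(rbind, lapply(stimuli, function(s) {
    rows <- peth$events$stimulus == s
    zbar <- colMeans(zmat[rows, , drop = FALSE])
    data.frame(stimulus = s, mean_z = mean(zbar[inwin]),
               n_events = sum(rows))
  }))
  structure(
    list(per_stimulus = per_stimulus, per_event = per_event,
         z_mean = (peth$mean - mu) / sigma,
         mu = mu, sigma = sigma, summary_window = summary_window),
    class = "window_stat"
  )
}

#' @export
print.window_stat <- function(x, ...) {
  cat(sprintf("<window_stat> mean z over [%g, %g] s (mu=%.4g, sigma=%.4g)\n",
              x$summary_window[1], x$summary_window[2], x$mu, x$sigma))
  print(x$per_stimulus, row.names = FALSE)
  invisible(x)
}
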