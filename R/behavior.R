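#' Zone and chamber occupancy from a tracking trace
#'
#' Dwell time in each proximity zone (closed disc: points on the boundary
#' circle count as inside), time in each of the three chambers, and total
#' distance moved. Each frame contributes the interval to the next frame;
#' the last frame contributes one median frame interval.
#'
#' @param trace Tracking data frame with columns `t_s`, `x_cm`, `y_cm`.
#' @param layout An [arena_layout()].
#' @return A list with `zone_times` (named, s), `chamber_times` (named, s),
#'   `distance_cm`, and `total_time`.
#' @export
compute_occupancy <- function(trace, layout) {
  if (is.null(trace) || nrow(trace) == 0)
    stop_socphys("empty_input_error", "empty tracking trace")
  t <- trace$t_s; x <- trace$x_cm; y <- trace$y_cm
  n <- length(t)
  dt <- diff(t)
  dt <- c(dt, if (n > 1) median(dt) else 0)

  zone_times <- vapply(names(layout$enclosure_centers), function(z) {
    sum(dt[in_zone(x, y, layout, z)])
  }, numeric(1))

  chamber_times <- vapply(names(layout$chamber_bounds), function(ch) {
    b <- layout$chamber_bounds[[ch]]
    # half-open [lo, hi) except the rightmost chamber, so chambers
    # partition the arena width exactly
    inside <- if (ch == "right") x >= b[1] & x <= b[2] else x >= b[1] & x < b[2]
    sum(dt[inside])
  }, numeric(1))

  dist <- if (n > 1) sum(sqrt(diff(x)^2 + diff(y)^2)) else 0
  list(zone_times = zone_times, chamber_times = chamber_times,
       distance_cm = dist, total_time = sum(dt))
}

#' Detect proximity-zone entry events
#'
#' An entry is an outside-to-inside transition of a zone circle preceded by
#' at least `debounce` seconds of continuous time outside; exits shorter
#' than `debounce` are merged into the surrounding visit (suppressing
#' boundary jitter). Events whose entry time falls inside an exclusion
#' window are flagged excluded but retained with a reason. The session
#' start counts as "outside since forever" for the first entry.
#'
#' @param trace Tracking data frame (`t_s`, `x_cm`, `y_cm`).
#' @param layout An [arena_layout()].
#' @param debounce Minimum continuous outside time before a new entry (s).
#' @param exclusion_windows List of `c(start, stop)` intervals (s); events
#'   starting inside any of them are flagged excluded.
#' @return Data frame of class `entry_events`: `stimulus`, `t_entry`,
#'   `t_exit`, `included`, `reason`. A visit still open at session end gets
#'   the last timestamp as `t_exit`.
#' @export
detect_entries <- function(trace, layout, debounce = 0.5,
                           exclusion_windows = NULL) {
  if (debounce < 0) stop_socphys("parameter_error", "debounce must be >= 0")
  if (is.null(trace) || nrow(trace) == 0)
    stop_socphys("empty_input_error", "empty tracking trace")
  t <- trace$t_s
  out <- list()
  for (z in names(layout$enclosure_centers)) {
    inside <- in_zone(trace$x_cm, trace$y_cm, layout, z)
    runs <- rle(inside)
    ends <- cumsum(runs$lengths)
    starts <- c(1, head(ends, -1) + 1)
    seg <- data.frame(inside = runs$values,
                      t_start = t[starts],
                      t_end = t[pmin(ends + 1, length(t))])
    # merge outside gaps shorter than debounce into the surrounding visit
    if (nrow(seg) > 2) {
      keep <- rep(TRUE, nrow(seg))
      for (k in 2:(nrow(seg) - 1)) {
        if (!seg$inside[k] && (seg$t_end[k] - seg$t_start[k]) < debounce)
          keep[k] <- FALSE
      }
      seg <- seg[keep, , drop = FALSE]
      # coalesce adjacent inside segments
      merged <- seg[1, , drop = FALSE]
      for (k in seq_len(nrow(seg))[-1]) {
        if (seg$inside[k] && merged$inside[nrow(merged)]) {
          merged$t_end[nrow(merged)] <- seg$t_end[k]
        } else {
          merged <- rbind(merged, seg[k, ])
        }
      }
      seg <- merged
    }
    vis <- seg[seg$inside, , drop = FALSE]
    if (nrow(vis)) {
      ev <- data.frame(stimulus = z, t_entry = vis$t_start,
                       t_exit = vis$t_end)
      ev$included <- TRUE
      ev$reason <- ""
      for (w in exclusion_windows %||% list()) {
        hit <- ev$t_entry >= w[1] & ev$t_entry <= w[2]
        ev$included[hit] <- FALSE
        ev$reason[hit] <- sprintf("exclusion_window[%g,%g]", w[1], w[2])
      }
      out[[z]] <- ev
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(stimulus = character(), t_entry = numeric(),
               t_exit = numeric(), included = logical(),
               reason = character())
  rownames(res) <- NULL
  res <- res[order(res$t_entry), , drop = FALSE]
  class(res) <- c("entry_events", "data.frame")
  res
}

#' Social preference index
#'
#' `time_social / (time_social + time_object)`; chance level 0.5.
#'
#' @param time_social,time_object Exploration times (s), both `>= 0` with a
#'   positive sum.
#' @return The preference index in `[0, 1]`.
#' @export
#' @examples
#' preference_index(90, 30)  # 0.75
preference_index <- function(time_social, time_object) {
  if (any(time_social < 0) || any(time_object < 0))
    stop_socphys("parameter_error", "times must be >= 0")
  tot <- time_social + time_object
  if (any(tot == 0))
    stop_socphys("undefined_index_error",
                 "preference index undefined for zero total exploration")
  time_social / tot
}

#' Minimum-exploration inclusion filter
#'
#' Animals whose total enclosure exploration is below the threshold are
#' flagged excluded (default: less than 10 s excluded, i.e. exactly 10 s is
#' kept).
#'
#' @param result A list/data frame with `time_social` and `time_object`.
#' @param min_total_exploration Threshold (s).
#' @return `result` with `included` and `exclusion_reason` set.
#' @export
inclusion_filter <- function(result, min_total_exploration = 10) {
  tot <- result$time_social + result$time_object
  inc <- tot >= min_total_exploration
  result$included <- inc
  result$exclusion_reason <- ifelse(
    inc, "",
    sprintf("total exploration %.3f s < %g s", tot, min_total_exploration))
  result
}

#' Score one three-chamber session
#'
#' Convenience wrapper: occupancy + preference index + inclusion filter.
#'
#' @inheritParams compute_occupancy
#' @inheritParams inclusion_filter
#' @return A one-row data frame (`time_social`, `time_object`, chamber
#'   times, `distance_cm`, `preference_index`, `included`,
#'   `exclusion_reason`).
#' @export
score_preference <- function(trace, layout, min_total_exploration = 10) {
  occ <- compute_occupancy(trace, layout)
  res <- data.frame(
    time_social = occ$zone_times[["social"]],
    time_object = occ$zone_times[["object"]],
    time_left = occ$chamber_times[["left"]],
    time_center = occ$chamber_times[["center"]],
    time_right = occ$chamber_times[["right"]],
    distance_cm = occ$distance_cm
  )
  res$preference_index <- if (res$time_social + res$time_object > 0)
    preference_index(res$time_social, res$time_object) else NA_real_
  inclusion_filter(res, min_total_exploration)
}
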