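#' Ground-truth container for a synthetic session
#'
#' Bundles everything the downstream tests need to know about a simulated
#' animal: the scheduled proximity-zone entry times and the photometry
#' response kinetics that [simulate_photometry()] will plant at those times.
#'
#' @param entry_times_social,entry_times_object Scheduled entry times (s).
#' @param event_response_amplitude Peak event-locked response in dF/F units.
#' @param response_latency Delay from zone entry to response onset (s).
#' @param rise_tau,decay_tau Double-exponential kernel time constants (s).
#' @param bleach_tau Photobleaching time constant (s); `Inf` disables.
#' @param noise_sd Additive white-noise SD in dF/F units.
#' @param seed Seed recorded for provenance.
#' @return An object of class `session_truth`.
#' @export
session_truth <- function(entry_times_social = numeric(),
                          entry_times_object = numeric(),
                          event_response_amplitude = 0.05,
                          response_latency = 0.2,
                          rise_tau = 0.2, decay_tau = 1.6,
                          bleach_tau = 1200, noise_sd = 0.01,
                          seed = NA_integer_) {
  if (event_response_amplitude < 0 || noise_sd < 0)
    stop_socphys("parameter_error", "amplitude and noise_sd must be >= 0")
  if (is.unsorted(entry_times_social) || is.unsorted(entry_times_object))
    stop_socphys("parameter_error", "entry times must be sorted")
  structure(
    list(entry_times_social = entry_times_social,
         entry_times_object = entry_times_object,
         event_response_amplitude = event_response_amplitude,
         response_latency = response_latency,
         rise_tau = rise_tau, decay_tau = decay_tau,
         bleach_tau = bleach_tau, noise_sd = noise_sd, seed = seed),
    class = "session_truth"
  )
}

reflect_interval <- function(x, lo, hi) {
  # fold a coordinate back into [lo, hi] by mirror reflection
  w <- hi - lo
  y <- (x - lo) %% (2 * w)
  lo + ifelse(y > w, 2 * w - y, y)
}

#' Simulate center-point tracking in a three-chamber arena
#'
#' Generates a reflected Gaussian random walk confined to the arena. Between
#' scheduled visits the walk is held in a central corridor that stays clear
#' of both proximity zones, so the only zone entries are the scheduled ones.
#' During each scheduled visit the point is placed (and walks) inside the
#' named zone. The scheduled visit starts are recorded as ground-truth entry
#' times.
#'
#' @param layout An [arena_layout()].
#' @param duration Session length (s).
#' @param visit_schedule Data frame with columns `zone` ("social"/"object"),
#'   `start`, `stop` (s); intervals must be non-overlapping and inside
#'   `[0, duration]`. May be empty.
#' @param step_sd Per-frame step SD (cm). `0` gives a stationary point.
#' @param rate Frame rate (Hz).
#' @param seed Optional integer seed.
#' @param start Starting position `c(x, y)`; default arena center.
#' @param truth_args Named list forwarded to [session_truth()] (photometry
#'   kinetics for the paired photometry simulation).
#'
#' @return A list with `trace` (data frame `t_s`, `x_cm`, `y_cm` with
#'   attributes `frame_rate` and `layout`) and `truth` (a `session_truth`).
#' @export
simulate_tracking <- function(layout, duration,
                              visit_schedule = NULL,
                              step_sd = 1.5, rate = 25,
                              seed = NULL, start = NULL,
                              truth_args = list()) {
  if (rate <= 0) stop_socphys("parameter_error", "rate must be > 0")
  if (duration <= 0) stop_socphys("parameter_error", "duration must be > 0")
  if (!is.null(seed)) set.seed(seed)
  sched <- normalize_schedule(visit_schedule, duration)
  if (nrow(sched) > 1) {
    s <- sched[order(sched$start), ]
    if (any(s$start[-1] < s$stop[-nrow(s)]))
      stop_socphys("schedule_error", "visit intervals overlap")
  }
  for (z in unique(sched$zone)) {
    ctr <- layout$enclosure_centers[[z]]
    if (is.null(ctr)) stop_socphys("layout_error", paste("unknown zone:", z))
    if (ctr[1] < 0 || ctr[1] > layout$arena_w ||
        ctr[2] < 0 || ctr[2] > layout$arena_h)
      stop_socphys("layout_error", "zone center outside arena")
  }

  t <- seq(0, duration, by = 1 / rate)
  n <- length(t)
  x <- numeric(n); y <- numeric(n)
  pos <- start %||% c(layout$arena_w / 2, layout$arena_h / 2)

  # corridor clear of both zones (1 cm margin); falls back to full arena
  # when the zones leave no room
  r <- zone_radius(layout)
  cx <- vapply(layout$enclosure_centers, `[`, numeric(1), 1)
  corr_lo <- min(cx) + r + 1
  corr_hi <- max(cx) - r - 1
  if (corr_lo >= corr_hi) { corr_lo <- 0; corr_hi <- layout$arena_w }
  margin <- 0.5

  zone_at <- function(ti) {
    k <- which(sched$start <= ti & ti < sched$stop)
    if (length(k)) sched$zone[k[1]] else NA_character_
  }

  cur_zone <- NA_character_
  for (i in seq_len(n)) {
    zi <- zone_at(t[i])
    if (!is.na(zi)) {
      ctr <- layout$enclosure_centers[[zi]]
      r_conf <- 0.6 * r
      if (!identical(zi, cur_zone)) {
        pos <- ctr  # enter the zone at its center
      } else if (step_sd > 0) {
        cand <- pos + rnorm(2, 0, step_sd)
        d <- sqrt(sum((cand - ctr)^2))
        if (d > r_conf) cand <- ctr + (cand - ctr) * (r_conf / d)
        pos <- cand
      }
    } else {
      if (!is.na(cur_zone)) {
        # leave the zone: re-enter the corridor at its nearest point
        pos <- c(mean(c(corr_lo, corr_hi)), layout$arena_h / 2)
      } else if (step_sd > 0) {
        cand <- pos + rnorm(2, 0, step_sd)
        cand[1] <- reflect_interval(cand[1], corr_lo + margin, corr_hi - margin)
        cand[2] <- reflect_interval(cand[2], margin, layout$arena_h - margin)
        pos <- cand
      }
    }
    # hard confinement to the arena
    pos[1] <- min(max(pos[1], 0), layout$arena_w)
    pos[2] <- min(max(pos[2], 0), layout$arena_h)
    x[i] <- pos[1]; y[i] <- pos[2]
    cur_zone <- zi
  }

  trace <- data.frame(t_s = t, x_cm = x, y_cm = y)
  attr(trace, "frame_rate") <- rate
  attr(trace, "layout") <- layout

  truth <- do.call(session_truth, c(
    list(entry_times_social = sort(sched$start[sched$zone == "social"]),
         entry_times_object = sort(sched$start[sched$zone == "object"]),
         seed = seed %||% NA_integer_),
    truth_args
  ))
  list(trace = trace, truth = truth)
}

normalize_schedule <- function(visit_schedule, duration) {
  if (is.null(visit_schedule) ||
      (is.data.frame(visit_schedule) && nrow(visit_schedule) == 0) ||
      (is.list(visit_schedule) && length(visit_schedule) == 0)) {
    return(data.frame(zone = character(), start = numeric(),
                      stop = numeric()))
  }
  sched <- as.data.frame(visit_schedule)
  stopifnot(all(c("zone", "start", "stop") %in% names(sched)))
  if (any(sched$start < 0) || any(sched$stop > duration) ||
      any(sched$start >= sched$stop))
    stop_socphys("schedule_error",
                 "visit intervals must satisfy 0 <= start < stop <= duration")
  sched
}

#' Build an alternating visit schedule
#'
#' Convenience generator of a regular alternating social/object visit
#' schedule used by the cohort pipeline and the tests.
#'
#' @param n_visits_per_zone Number of visits to each zone.
#' @param first_start Start of the first visit (s).
#' @param visit_dur Visit length (s).
#' @param gap Gap between consecutive visits (s).
#' @param first_zone Zone visited first.
#' @return Data frame `zone`, `start`, `stop`.
#' @export
alternating_schedule <- function(n_visits_per_zone, first_start = 30,
                                 visit_dur = 5, gap = 10,
                                 first_zone = "social") {
  zones <- rep(c(first_zone, setdiff(c("social", "object"), first_zone)),
               n_visits_per_zone)
  starts <- first_start + (seq_along(zones) - 1) * (visit_dur + gap)
  data.frame(zone = zones, start = starts, stop = starts + visit_dur)
}
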