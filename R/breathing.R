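# Simulated breathing patterns and AHI arithmetic.
#
# The alveolar-volume input is a sinusoid starting and ending each cycle at
# end-expiration,
#     V_A(t) = 1/2 V_vent sin(2 pi b_r t - pi/2) + 1/2 V_vent + V_End,
#     V_vent = V_T - V_D,
# with equal inspiration and expiration durations. Respiratory events modify
# the trace: apneas hold V_A at V_End (zero airflow), hypopneas scale the
# oscillation amplitude, hyperventilation epochs override V_T and/or b_r.
# Every event (and the breathing stretch that follows it) restarts the
# sinusoid at end-expiration phase, so the trace is continuous as long as
# event boundaries fall at end-expiration of the preceding segment; a
# misaligned boundary raises a warning.

#' Respiratory / annotation event
#'
#' @param kind one of "apnea", "hypopnea", "hyperventilation", "RERA",
#'   "wake", "sleep"
#' @param start event onset in seconds (relative to the start of the
#'   analyzed breathing period, i.e. after any stabilization run-in)
#' @param duration event duration in seconds (> 0)
#' @param airflow_fraction fraction of normal oscillation amplitude during
#'   the event: 0 for apnea, e.g. 0.5 for a 50 percent airflow reduction
#' @param V_T,b_r optional tidal volume (L) and breathing rate (per min)
#'   overrides for hyperventilation epochs
#' @return a one-row data.frame usable in \code{\link{breathing_spec}}
#' @export
resp_event <- function(kind, start, duration, airflow_fraction = NULL,
                       V_T = NA_real_, b_r = NA_real_) {
  kind <- match.arg(kind, c("apnea", "hypopnea", "hyperventilation",
                            "RERA", "wake", "sleep"))
  if (!is.finite(duration) || duration <= 0) {
    stop("event duration must be positive", call. = FALSE)
  }
  if (is.null(airflow_fraction)) {
    airflow_fraction <- switch(kind, apnea = 0, hypopnea = 0.5, 1)
  }
  if (airflow_fraction < 0 || airflow_fraction > 1) {
    stop("airflow_fraction must lie in [0, 1]", call. = FALSE)
  }
  data.frame(kind = kind, start = start, duration = duration,
             airflow_fraction = airflow_fraction,
             V_T = V_T, b_r = b_r, stringsAsFactors = FALSE)
}

#' Breathing pattern specification
#'
#' @param V_T tidal volume, L
#' @param V_D dead space volume, L (must satisfy 0 < V_D < V_T)
#' @param V_End end-expiration alveolar volume, L
#' @param b_r breathing rate, breaths per minute
#' @param events data.frame of \code{\link{resp_event}} rows (possibly
#'   empty); respiratory events must not overlap and must lie inside
#'   [0, total_duration]
#' @param total_duration analyzed breathing time, s
#' @param stabilization_time run-in of event-free normal breathing prepended
#'   before the analyzed period, s (default 360)
#' @return object of class \code{breathing_spec}
#' @export
breathing_spec <- function(V_T = 0.5, V_D = 0.15, V_End = 2.3, b_r = 12,
                           events = NULL, total_duration = 120,
                           stabilization_time = 360) {
  stop_if_not_scalar_pos(V_T, "V_T")
  stop_if_not_scalar_pos(V_D, "V_D")
  stop_if_not_scalar_pos(V_End, "V_End")
  stop_if_not_scalar_pos(b_r, "b_r")
  stop_if_not_scalar_pos(total_duration, "total_duration")
  if (V_T <= V_D) stop("tidal volume V_T must exceed dead space V_D",
                       call. = FALSE)
  if (stabilization_time < 0) stop("stabilization_time must be >= 0",
                                   call. = FALSE)
  if (is.null(events)) {
    events <- resp_event("apnea", 0, 1)[0, ]   # empty, right columns
  }
  resp <- events[events$kind %in% c("apnea", "hypopnea", "hyperventilation"), ,
                 drop = FALSE]
  if (nrow(resp)) {
    if (any(resp$start < 0) ||
        any(resp$start + resp$duration > total_duration + 1e-9)) {
      stop("events must lie inside [0, total_duration]", call. = FALSE)
    }
    o <- order(resp$start)
    resp <- resp[o, ]
    if (nrow(resp) > 1L) {
      gap <- resp$start[-1L] - (resp$start + resp$duration)[-nrow(resp)]
      if (any(gap < -1e-9)) stop("respiratory events must not overlap",
                                 call. = FALSE)
    }
  }
  structure(list(V_T = V_T, V_D = V_D, V_End = V_End, b_r = b_r,
                 V_vent = V_T - V_D, events = events,
                 total_duration = total_duration,
                 stabilization_time = stabilization_time),
            class = "breathing_spec")
}

# Sinusoidal segment starting at end-expiration phase at local time tau.
.breath_segment <- function(tau, V_vent, b_r, V_End) {
  w <- 2 * pi * b_r / 60
  list(V  = 0.5 * V_vent * sin(w * tau - pi / 2) + 0.5 * V_vent + V_End,
       dV = 0.5 * V_vent * w * cos(w * tau - pi / 2))
}

#' Generate an alveolar-volume breathing pattern
#'
#' Evaluates the sinusoidal pattern (with any events in the spec applied) on
#' a uniform grid covering the stabilization run-in plus the analyzed
#' period. Event onsets in the spec are relative to the analyzed period; the
#' returned trace is absolute (stabilization first).
#'
#' @param spec a \code{\link{breathing_spec}}
#' @param dt sample spacing, s
#' @return object of class \code{breathing_pattern}: list with \code{times},
#'   \code{V_A} (L), \code{dV_A_dt} (L/s), \code{events} (absolute times),
#'   \code{spec}
#' @export
breathing_pattern <- function(spec, dt = 0.005) {
  stopifnot(inherits(spec, "breathing_spec"))
  stop_if_not_scalar_pos(dt, "dt")
  t0 <- spec$stabilization_time
  total <- t0 + spec$total_duration
  times <- seq(0, total, by = dt)
  V <- numeric(length(times))
  dV <- numeric(length(times))

  resp <- spec$events[spec$events$kind %in%
                        c("apnea", "hypopnea", "hyperventilation"), ,
                      drop = FALSE]
  resp <- resp[order(resp$start), , drop = FALSE]
  # segment table: breathing stretches between events, and the events
  # themselves; each segment restarts at end-expiration phase.
  seg_start <- 0
  segs <- list()
  add_seg <- function(from, to, frac, V_T, b_r) {
    if (to - from > 1e-12) {
      segs[[length(segs) + 1L]] <<- list(from = from, to = to, frac = frac,
                                         V_T = V_T, b_r = b_r)
    }
  }
  if (nrow(resp)) {
    for (i in seq_len(nrow(resp))) {
      ev <- resp[i, ]
      abs_start <- t0 + ev$start
      add_seg(seg_start, abs_start, 1, spec$V_T, spec$b_r)
      add_seg(abs_start, abs_start + ev$duration,
              ev$airflow_fraction,
              if (is.finite(ev$V_T)) ev$V_T else spec$V_T,
              if (is.finite(ev$b_r)) ev$b_r else spec$b_r)
      seg_start <- abs_start + ev$duration
    }
  }
  add_seg(seg_start, total, 1, spec$V_T, spec$b_r)

  for (sg in segs) {
    idx <- which(times >= sg$from - 1e-9 & times <= sg$to + 1e-9)
    V_vent_seg <- sg$frac * (sg$V_T - spec$V_D)
    if (sg$frac == 0) {
      V[idx] <- spec$V_End
      dV[idx] <- 0
    } else {
      s <- .breath_segment(times[idx] - sg$from, V_vent_seg, sg$b_r,
                           spec$V_End)
      V[idx] <- s$V
      dV[idx] <- s$dV
    }
  }

  # continuity audit at segment boundaries
  jump <- max(abs(diff(V)))
  bound <- max(abs(dV)) * dt * 1.5 + 1e-12
  if (jump > bound) {
    warning(sprintf(paste0("breathing trace jumps by %.3g L at a segment ",
                           "boundary; align event times with end-expiration"),
                    jump), call. = FALSE)
  }

  ev_abs <- spec$events
  if (nrow(ev_abs)) ev_abs$start <- ev_abs$start + t0
  structure(list(times = times, V_A = V, dV_A_dt = dV,
                 events = ev_abs, spec = spec, dt = dt),
            class = "breathing_pattern")
}

#' @export
print.breathing_pattern <- function(x, ...) {
  cat(sprintf("<breathing_pattern> %d samples, dt = %g s, span %.1f s\n",
              length(x$times), x$dt, max(x$times)))
  cat(sprintf("  V_End %.2f L, V_T %.2f L, V_D %.2f L, b_r %g /min\n",
              x$spec$V_End, x$spec$V_T, x$spec$V_D, x$spec$b_r))
  nresp <- sum(x$events$kind %in% c("apnea", "hypopnea", "hyperventilation"))
  cat(sprintf("  %d respiratory event(s); stabilization %g s\n",
              nresp, x$spec$stabilization_time))
  invisible(x)
}

#' @export
plot.breathing_pattern <- function(x, ...) {
  graphics::plot(x$times, x$V_A, type = "l", xlab = "time (s)",
                 ylab = expression(V[A] ~ "(L)"), ...)
  resp <- x$events[x$events$kind %in% c("apnea", "hypopnea"), , drop = FALSE]
  if (nrow(resp)) {
    graphics::rect(resp$start, min(x$V_A), resp$start + resp$duration,
                   max(x$V_A), col = grDevices::adjustcolor("gray", 0.4),
                   border = NA)
  }
  invisible(x)
}

#' Apnea-hypopnea index
#'
#' AHI = number of scored apnea/hypopnea events divided by the analyzed
#' breathing time in hours. Clinical scoring requires events to last at
#' least 10 s; sub-threshold events are excluded when the duration filter is
#' on. Non-respiratory annotations (wake, RERA, ...) never count.
#'
#' @param events data.frame of \code{\link{resp_event}} rows
#' @param analyzed_time total breathing time analyzed, in seconds (> 0)
#' @param min_duration minimum scored event duration, s (default 10); set to
#'   0 to disable the filter
#' @return events per hour
#' @examples
#' ev <- do.call(rbind, lapply(c(0, 150, 300, 450),
#'                             function(s) resp_event("apnea", s, 20)))
#' compute_ahi(ev, 600)   # 24
#' @export
compute_ahi <- function(events, analyzed_time, min_duration = 10) {
  if (!is.finite(analyzed_time) || analyzed_time <= 0) {
    stop("analyzed_time must be positive", call. = FALSE)
  }
  scored <- events[events$kind %in% c("apnea", "hypopnea") &
                     events$duration >= min_duration, , drop = FALSE]
  nrow(scored) / (analyzed_time / 3600)
}
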