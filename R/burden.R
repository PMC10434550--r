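# Hypoxia burden scoring against a wakefulness baseline, and intra-patient
# interval statistics.
#
# The burden score for an analysis interval is the signed area between the
# wakefulness mean of the systemic arterial dissolved oxygen and the trace,
# normalized by the interval duration:
#     score = (1/T) * integral( mean_wake - C(t) ) dt      [uM]
# so scoring the wake baseline itself gives approximately zero, dips below
# the baseline raise the score and overshoots above it subtract (a clipped
# variant is available for sensitivity analysis). The hypoxia-period score
# restricts the integral to samples below threshold = mean - 1 sd of the
# wake baseline and normalizes by the time spent below it. Trapezoidal
# quadrature throughout.

#' Wakefulness baseline of the arterial dissolved oxygen
#'
#' Pooled mean and standard deviation over all samples inside the supplied
#' wake intervals.
#'
#' @param times sample times, s
#' @param C_sa_d arterial dissolved oxygen trace (any consistent unit;
#'   conventionally uM)
#' @param wake_intervals list of length-2 numeric intervals (s), each
#'   containing at least 2 samples
#' @return object of class \code{wake_baseline}: list with \code{mean},
#'   \code{sd}, \code{threshold} (mean - sd) and the intervals
#' @export
wake_baseline <- function(times, C_sa_d, wake_intervals) {
  if (!length(wake_intervals)) {
    stop("at least one wake interval is required", call. = FALSE)
  }
  if (is.numeric(wake_intervals)) wake_intervals <- list(wake_intervals)
  sel <- rep(FALSE, length(times))
  for (iv in wake_intervals) {
    idx <- times >= iv[1] & times <= iv[2]
    if (sum(idx) < 2L) {
      stop(sprintf("wake interval [%g, %g] contains fewer than 2 samples",
                   iv[1], iv[2]), call. = FALSE)
    }
    sel <- sel | idx
  }
  x <- C_sa_d[sel]
  m <- mean(x)
  s <- stats::sd(x)
  structure(list(mean = m, sd = s, threshold = m - s,
                 intervals = wake_intervals),
            class = "wake_baseline")
}

#' Hypoxia burden score of an interval
#'
#' Signed, time-normalized area between the wakefulness mean and the trace;
#' higher values indicate a more severe hypoxia burden.
#'
#' @param times sample times, s (restricted to the analysis interval)
#' @param C_sa_d arterial dissolved oxygen over those times
#' @param baseline a \code{\link{wake_baseline}}
#' @param clip_deficit if TRUE, overshoots above the baseline do not
#'   subtract (integrand floored at zero)
#' @return score in the units of the trace (uM per the convention here)
#' @export
burden_score <- function(times, C_sa_d, baseline, clip_deficit = FALSE) {
  stopifnot(inherits(baseline, "wake_baseline"))
  if (length(times) < 2L) stop("interval must contain at least 2 samples",
                               call. = FALSE)
  if (any(!is.finite(C_sa_d))) stop("non-finite trace samples", call. = FALSE)
  dev <- baseline$mean - C_sa_d
  if (clip_deficit) dev <- pmax(dev, 0)
  trapz(times, dev) / (max(times) - min(times))
}

#' Hypoxia-period score and time in hypoxia
#'
#' Hypoxia is defined per sample as the arterial dissolved oxygen lying
#' below one standard deviation under the wakefulness mean (no dwell-time
#' hysteresis). The score is the area between the threshold and the trace
#' over hypoxic samples, normalized by the total time spent in hypoxia.
#'
#' @inheritParams burden_score
#' @return list with \code{score} (0 with \code{flag = "no-hypoxia"} when
#'   the trace never crosses the threshold), \code{time_in_hypoxia} (s) and
#'   \code{threshold}
#' @export
hypoxia_period_score <- function(times, C_sa_d, baseline) {
  stopifnot(inherits(baseline, "wake_baseline"))
  if (baseline$sd <= 0) {
    stop("baseline sd must be positive for a meaningful threshold",
         call. = FALSE)
  }
  thr <- baseline$threshold
  below <- C_sa_d < thr
  if (!any(below)) {
    return(list(score = 0, time_in_hypoxia = 0, threshold = thr,
                flag = "no-hypoxia"))
  }
  dt_step <- diff(times)
  # per-sample rectangles on hypoxic samples (threshold-crossing
  # segmentation without hysteresis)
  w <- c(dt_step, 0) / 2 + c(0, dt_step) / 2
  area <- sum(w[below] * (thr - C_sa_d[below]))
  t_hyp <- sum(w[below])
  list(score = area / t_hyp, time_in_hypoxia = t_hyp, threshold = thr,
       flag = "ok")
}

#' Full burden report for an analysis window
#'
#' Mirrors the three-column clinical comparison: the event-sequence score,
#' the total-sequence score, and the hypoxia-period score with time in
#' hypoxia.
#'
#' @param times,C_sa_d full trace
#' @param baseline a \code{\link{wake_baseline}}
#' @param event_sequence length-2 interval (s) holding the event series of
#'   interest
#' @param total_sequence length-2 interval (s) for the whole analysis
#'   period (default: full trace)
#' @return list of class \code{burden_report}
#' @export
burden_report <- function(times, C_sa_d, baseline, event_sequence,
                          total_sequence = range(times)) {
  pick <- function(iv) times >= iv[1] & times <= iv[2]
  i1 <- pick(event_sequence)
  i2 <- pick(total_sequence)
  hp <- hypoxia_period_score(times[i2], C_sa_d[i2], baseline)
  structure(list(
    event_sequence_score = burden_score(times[i1], C_sa_d[i1], baseline),
    total_sequence_score = burden_score(times[i2], C_sa_d[i2], baseline),
    hypoxia_period_score = hp$score,
    time_in_hypoxia = hp$time_in_hypoxia,
    threshold = baseline$threshold,
    baseline = baseline), class = "burden_report")
}

#' @export
print.burden_report <- function(x, ...) {
  cat("<burden_report>\n")
  cat(sprintf("  wake baseline %.1f +/- %.1f (threshold %.1f)\n",
              x$baseline$mean, x$baseline$sd, x$threshold))
  cat(sprintf("  event sequence score  %.3g\n", x$event_sequence_score))
  cat(sprintf("  total sequence score  %.3g\n", x$total_sequence_score))
  cat(sprintf("  hypoxia period score  %.3g (%.0f s in hypoxia)\n",
              x$hypoxia_period_score, x$time_in_hypoxia))
  invisible(x)
}

#' Intra-patient interval statistics
#'
#' For each analyzed variable, computes the differences between interval
#' averages (one per selected window, conventionally 125 s each containing
#' two obstructive events) and the overall average over the whole study,
#' and tests the hypothesis that the differences come from a zero-mean
#' distribution with a two-sided one-sample t test (significance at
#' p < 0.05).
#'
#' @param times sample times, s
#' @param traces named list of numeric traces (same length as times), e.g.
#'   \code{list(S_sa = ..., S_sv = ..., dC_d = ...)}
#' @param intervals list of length-2 numeric windows, s (conventionally 4
#'   windows of 125 s)
#' @param overall_span length-2 interval for the overall average (default:
#'   full trace)
#' @return data.frame with one row per variable: \code{mean_difference},
#'   \code{sd_difference}, \code{t}, \code{df}, \code{p_value},
#'   \code{significant}
#' @export
interval_ttest <- function(times, traces, intervals,
                           overall_span = range(times)) {
  if (length(intervals) < 2L) {
    stop("need at least 2 intervals for a t test", call. = FALSE)
  }
  i_all <- times >= overall_span[1] & times <= overall_span[2]
  out <- lapply(names(traces), function(nm) {
    x <- traces[[nm]]
    overall <- mean(x[i_all])
    d <- vapply(intervals, function(iv) {
      mean(x[times >= iv[1] & times <= iv[2]]) - overall
    }, numeric(1))
    if (stats::sd(d) == 0) {
      stop(sprintf(paste0("zero variance across interval differences for ",
                          "'%s': t statistic undefined"), nm), call. = FALSE)
    }
    tt <- stats::t.test(d, mu = 0)
    data.frame(variable = nm, mean_difference = mean(d),
               sd_difference = stats::sd(d),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p_value = tt$p.value,
               significant = tt$p.value < 0.05)
  })
  do.call(rbind, out)
}
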