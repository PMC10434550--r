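# Severity metrics derived from a simulation.
#
# Percent decreases compare the average "normal" value (over a reference
# window of steady breathing, by default the last minute of the
# stabilization run-in) with the minimum reached during the analyzed
# period. The mass-transfer reduction compares the time-averaged systemic
# arteriovenous dissolved-oxygen difference (the driving force for tissue
# transfer) against its normal value. Reoxygenation time is measured per
# respiratory event from the post-event minimum until both the arterial
# saturation and the arterial dissolved concentration re-enter a relative
# band around their normal averages.

#' Summary severity metrics for a simulation
#'
#' @param sim an \code{\link{simulate_oxygen}} result
#' @param normal_window length-2 numeric: time interval (s) of steady
#'   normal breathing used as the reference; defaults to the last 60 s of
#'   the stabilization run-in
#' @param band relative half-width of the recovery band (default 0.01)
#' @return object of class \code{oxy_metrics}: list with
#'   \code{pct_decrease} (data.frame: variable, normal_avg, minimum,
#'   pct_decrease for S_sa, S_sv, C_sa_d, C_sv_d),
#'   \code{pct_reduction_mass_transfer}, and \code{per_event} (data.frame:
#'   one row per respiratory event with its post-event minimum arterial
#'   saturation, desaturation depth and reoxygenation time in s)
#' @export
oxygen_metrics <- function(sim, normal_window = NULL, band = 0.01) {
  stopifnot(inherits(sim, "oxy_sim"))
  stab <- sim$pattern$spec$stabilization_time
  if (is.null(normal_window)) normal_window <- c(max(0, stab - 60), stab)
  if (normal_window[2] <= normal_window[1]) {
    stop("normal_window must be a non-empty interval", call. = FALSE)
  }
  s <- sim$series
  nw <- s$time >= normal_window[1] & s$time < normal_window[2]
  if (!any(nw)) stop("normal_window lies outside the simulated span",
                     call. = FALSE)
  an <- s$time >= stab   # analyzed period

  vars <- c("S_sa", "S_sv", "C_sa_d", "C_sv_d")
  normal_avg <- vapply(vars, function(v) mean(s[[v]][nw]), numeric(1))
  minimum <- vapply(vars, function(v) min(s[[v]][an]), numeric(1))
  pct <- data.frame(variable = vars, normal_avg = normal_avg,
                    minimum = minimum,
                    pct_decrease = (normal_avg - minimum) / normal_avg * 100,
                    row.names = NULL)

  dd_norm <- mean(s$C_sa_d[nw] - s$C_sv_d[nw])
  dd_run <- mean(s$C_sa_d[an] - s$C_sv_d[an])
  pct_mt <- 100 * (1 - dd_run / dd_norm)

  per_event <- .per_event_metrics(sim, normal_avg, band)

  structure(list(pct_decrease = pct,
                 pct_reduction_mass_transfer = pct_mt,
                 per_event = per_event,
                 normal_window = normal_window, band = band),
            class = "oxy_metrics")
}

# Per-event minima and reoxygenation times. The search window for event k
# runs from its onset to the onset of the next respiratory event (or the
# end of the run); recovery is timed from the minimum of the arterial
# dissolved trace inside that window.
.per_event_metrics <- function(sim, normal_avg, band) {
  s <- sim$series
  ev <- sim$events
  resp <- ev[ev$kind %in% c("apnea", "hypopnea"), , drop = FALSE]
  if (!nrow(resp)) {
    return(data.frame(kind = character(0), start = numeric(0),
                      duration = numeric(0), min_S_sa = numeric(0),
                      desat = numeric(0), reox_time_s = numeric(0)))
  }
  resp <- resp[order(resp$start), ]
  t_end <- max(s$time)
  next_onset <- c(resp$start[-1L], t_end + 1)
  Sbar <- normal_avg[["S_sa"]]
  Cbar <- normal_avg[["C_sa_d"]]
  out <- resp[, c("kind", "start", "duration")]
  out$min_S_sa <- NA_real_
  out$desat <- NA_real_
  out$reox_time_s <- NA_real_
  for (k in seq_len(nrow(resp))) {
    win <- which(s$time >= resp$start[k] & s$time < next_onset[k])
    if (!length(win)) next
    imin <- win[which.min(s$C_sa_d[win])]
    out$min_S_sa[k] <- min(s$S_sa[win])
    out$desat[k] <- Sbar - out$min_S_sa[k]
    # recovery may complete after the next event starts; search to run end
    tail_idx <- which(s$time >= s$time[imin])
    ok <- abs(s$S_sa[tail_idx] - Sbar) / Sbar <= band &
      abs(s$C_sa_d[tail_idx] - Cbar) / Cbar <= band
    hit <- which(ok)[1L]
    if (!is.na(hit)) out$reox_time_s[k] <- s$time[tail_idx[hit]] - s$time[imin]
  }
  out
}

#' @export
print.oxy_metrics <- function(x, ...) {
  cat("<oxy_metrics>\n")
  cat(sprintf("  normal window [%g, %g] s, recovery band +/-%g%%\n",
              x$normal_window[1], x$normal_window[2], x$band * 100))
  pd <- x$pct_decrease
  for (i in seq_len(nrow(pd))) {
    cat(sprintf("  %-6s normal %.4g  min %.4g  decrease %5.2f%%\n",
                pd$variable[i], pd$normal_avg[i], pd$minimum[i],
                pd$pct_decrease[i]))
  }
  cat(sprintf("  mass-transfer reduction %5.2f%%\n",
              x$pct_reduction_mass_transfer))
  if (nrow(x$per_event)) {
    cat(sprintf("  %d respiratory event(s); mean reox time %.1f s\n",
                nrow(x$per_event), mean(x$per_event$reox_time_s, na.rm = TRUE)))
  }
  invisible(x)
}

#' Score respiratory events against clinical AHI criteria
#'
#' Applies the clinical scoring rules to the candidate events of a
#' simulation: apneas count when they last at least \code{min_duration}
#' seconds; hypopneas additionally require the arterial saturation to drop
#' by at least \code{desat_threshold} (default 4 percent of saturation,
#' absolute) below the normal average.
#'
#' @param sim an \code{oxy_sim}
#' @param min_duration minimum event duration, s
#' @param desat_threshold required arterial desaturation for hypopneas,
#'   absolute saturation fraction (0.04 = 4 percent)
#' @param normal_window,band passed to \code{\link{oxygen_metrics}}
#' @return data.frame of respiratory events with a logical \code{scored}
#'   column and the per-event minima
#' @export
score_events <- function(sim, min_duration = 10, desat_threshold = 0.04,
                         normal_window = NULL, band = 0.01) {
  m <- oxygen_metrics(sim, normal_window = normal_window, band = band)
  ev <- m$per_event
  if (!nrow(ev)) return(cbind(ev, scored = logical(0)))
  ev$scored <- ev$duration >= min_duration &
    (ev$kind != "hypopnea" | ev$desat >= desat_threshold)
  ev
}

#' AHI of a simulation after clinical scoring
#'
#' Convenience wrapper: scores the simulation's events with
#' \code{\link{score_events}} and divides by the analyzed breathing time.
#'
#' @param sim an \code{oxy_sim}
#' @param ... passed to \code{\link{score_events}}
#' @return events per hour
#' @export
ahi <- function(sim, ...) {
  ev <- score_events(sim, ...)
  analyzed <- sim$pattern$spec$total_duration
  sum(ev$scored) / (analyzed / 3600)
}
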