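# Coupled alveolar / pulmonary-capillary / systemic simulation.
#
# Explicit time stepping with fixed dt:
#   (1) membrane uptake and advection of the pulmonary capillary parcels,
#       driven by the current alveolar dissolved concentration and fed at
#       the inlet by the pulmonary arterial (= systemic venous) blood;
#   (2) alveolar partial-pressure update from the breathing input and the
#       moles actually transferred in (1), so lung gas and capillary blood
#       conserve oxygen exactly;
#   (3) systemic transit of the capillary outlet (after the optional
#       arteriolar leak fraction), returning the venous concentration that
#       feeds the pulmonary arteries.
# The breathing pattern carries its own stabilization run-in of normal
# breathing; compartments start from the steady state implied by an
# alveolar partial pressure of 99 mmHg and settle during the run-in.

#' Simulate oxygen transport for a breathing pattern
#'
#' Core model entry point. Runs the coupled compartment model over the full
#' span of the supplied breathing pattern and returns all compartment time
#' series plus optional capillary snapshots.
#'
#' @param pattern a \code{\link{breathing_pattern}} (its grid defines the
#'   solver step)
#' @param params an \code{\link{oxy_params}} object
#' @param heart_rate constant heart rate in bpm, or a data.frame/list with
#'   \code{times} (s) and \code{bpm} to be interpolated onto the simulation
#'   grid; defaults to \code{params$heart_rate}
#' @param dt optional solver step, s: if supplied and different from the
#'   pattern's own grid, the volume trace is linearly resampled onto the
#'   solver grid (needed e.g. for patient recordings sampled more coarsely
#'   than the capillary advection constraint allows)
#' @param n_slices number of pulmonary capillary parcels (default 40)
#' @param P_A0 initial alveolar O2 partial pressure, mmHg (default 99); any
#'   initialization reaching the cyclic steady state during the run-in is
#'   equivalent
#' @param snapshot_times times (s) at which to record the axial capillary
#'   profile
#' @return object of class \code{oxy_sim}: list with \code{times}, a
#'   \code{series} data.frame (columns \code{P_A}, \code{V_A}, and per
#'   systemic compartment \code{C_sa_T}, \code{C_sa_d}, \code{S_sa},
#'   \code{P_sa}, \code{C_sv_T}, \code{C_sv_d}, \code{S_sv}, \code{P_sv},
#'   plus \code{C_pa_T}, \code{C_pv_T}, \code{C_c_bar}), \code{snapshots},
#'   \code{events}, \code{pattern}, \code{params}
#' @examples
#' \donttest{
#' spec <- breathing_spec(total_duration = 30, stabilization_time = 30)
#' sim <- simulate_oxygen(breathing_pattern(spec, dt = 0.005), oxy_params())
#' summary(sim)
#' }
#' @export
simulate_oxygen <- function(pattern, params = oxy_params(),
                            heart_rate = NULL, dt = NULL, n_slices = 40,
                            P_A0 = 99, snapshot_times = numeric(0)) {
  stopifnot(inherits(pattern, "breathing_pattern"),
            inherits(params, "oxy_params"))
  if (!is.null(dt) && abs(dt - pattern$dt) > 1e-12) {
    tt <- seq(min(pattern$times), max(pattern$times), by = dt)
    VV <- stats::approx(pattern$times, pattern$V_A, xout = tt)$y
    pattern$times <- tt
    pattern$V_A <- VV
    pattern$dV_A_dt <- c(diff(VV) / dt, 0)
    pattern$dt <- dt
  }
  times <- pattern$times
  n <- length(times)
  dt <- pattern$dt
  V_A <- pattern$V_A
  dV <- pattern$dV_A_dt
  if (any(V_A <= 0)) stop("alveolar volume must stay positive", call. = FALSE)

  # heart rate -> flow series on the grid
  if (is.null(heart_rate)) heart_rate <- params$heart_rate
  if (is.list(heart_rate)) {
    hr <- stats::approx(heart_rate$times, heart_rate$bpm, xout = times,
                        rule = 2)$y
  } else {
    hr <- rep_len(heart_rate, n)
  }
  Q <- cardiac_output(hr, params)

  # advection constraint: at most one parcel per step
  dV_parcel <- params$V_pc / n_slices
  if (max(Q) * dt > dV_parcel) {
    stop(sprintf(paste0("step size dt = %g s violates the capillary ",
                        "advection constraint for n_slices = %d; ",
                        "use dt <= %.4g s or fewer slices"),
                 dt, n_slices, dV_parcel / max(Q)), call. = FALSE)
  }

  beta <- params$beta_p
  C_Hb <- params$C_Hb
  RT <- params$R * params$T
  P_I <- params$P_I
  leak <- params$arteriole_leak_fraction

  # steady initial state implied by P_A0
  P_A <- P_A0
  art0 <- blood_from_dissolved(beta * P_A0, params)
  ven0 <- max(art0$C_T - params$MR_O2 / Q[1L], 0)
  cap <- capillary_init(params, n_slices, C_T_init = art0$C_T)
  sys <- systemic_init(params, art0$C_T * leak, Q[1L], t0 = 0, dt = dt,
                       capacity = n)
  C_pa_T <- ven0
  C_pa_d <- .dissolved_newton(ven0, C_Hb, beta)

  out_P_A <- numeric(n)
  out_sa_T <- numeric(n); out_sa_d <- numeric(n)
  out_sv_T <- numeric(n); out_sv_d <- numeric(n)
  out_cbar <- numeric(n)
  snapshots <- vector("list", length(snapshot_times))
  names(snapshots) <- as.character(snapshot_times)
  snap_idx <- if (length(snapshot_times)) {
    pmin(pmax(round(snapshot_times / dt) + 1L, 1L), n)
  } else integer(0)

  C_sa_T <- art0$C_T * leak
  C_sa_d <- .dissolved_newton(C_sa_T, C_Hb, beta)
  C_sv_T <- ven0
  C_sv_d <- C_pa_d

  # -- hot loop over inlined local state ---------------------------------
  # The exported step functions advance_capillary()/systemic_step() are the
  # reference implementation of the identical update; a regression test
  # pins this loop against them.
  cap_C_T <- cap$C_T; cap_C_d <- cap$C_d
  cap_vol_in <- 0; cap_out_T <- cap$outlet_C_T
  k_pc <- params$k_l / n_slices
  alpha <- k_pc / dV_parcel
  fourHb <- 4 * C_Hb
  # systemic FIFO (local mirrors of systemic_init's prefill)
  f_vol <- sys$vol; f_C <- sys$C; f_te <- sys$te
  f_head <- sys$head; f_tail <- sys$tail
  V_sys <- params$V_sys_cap; MR <- params$MR_O2
  clamped <- 0L

  sat_slope <- function(P) {
    g <- P^3 + 150 * P
    23400 * (3 * P^2 + 150) / (g + 23400)^2
  }
  # scalar/vector warm-started Newton (no bracket bookkeeping; the map is
  # monotone and the guesses are one step away, fall back to the
  # safeguarded solver if an update misbehaves)
  newt <- function(C_T, x0) {
    x <- x0
    for (it in 1:30) {
      g <- (x / beta)^3 + 150 * (x / beta)
      S <- g / (g + 23400)
      f <- x + fourHb * S - C_T
      if (max(abs(f)) < 1e-13) return(x)
      fp <- 1 + fourHb * sat_slope(x / beta) / beta
      x <- x - f / fp
      if (any(!is.finite(x)) || any(x < 0)) {
        return(.dissolved_newton(C_T, C_Hb, beta))
      }
    }
    .dissolved_newton(C_T, C_Hb, beta, x0 = x)
  }

  take_snaps <- length(snap_idx) > 0L
  for (i in seq_len(n)) {
    t <- times[i]
    Qi <- Q[i]
    # (1) capillary membrane uptake (exponential update) + advection
    C_A <- beta * P_A
    m <- 1 / (1 + fourHb * sat_slope(cap_C_d / beta) / beta)
    dC_T <- (C_A - cap_C_d) / m * (1 - exp(-alpha * m * dt))
    cap_C_T <- cap_C_T + dC_T
    cap_C_d <- newt(cap_C_T, cap_C_d + m * dC_T)
    uptake <- dV_parcel * sum(dC_T)
    cap_vol_in <- cap_vol_in + Qi * dt
    if (cap_vol_in >= dV_parcel * (1 - 1e-12)) {
      cap_out_T <- cap_C_T[n_slices]
      cap_C_T <- c(C_pa_T, cap_C_T[-n_slices])
      cap_C_d <- c(C_pa_d, cap_C_d[-n_slices])
      cap_vol_in <- cap_vol_in - dV_parcel
    }
    # (2) alveolar update with the moles actually transferred
    conv <- if (dV[i] > 0) dV[i] * (P_I - P_A) * dt else 0
    P_A <- P_A + (conv - uptake * RT) / V_A[i]
    if (!is.finite(P_A) || P_A <= 0) {
      stop(sprintf(paste0("alveolar pressure became non-physical at ",
                          "t = %.3f s (step %d); reduce dt"), t, i),
           call. = FALSE)
    }
    # (3) systemic transit: push arterial, withdraw venous
    C_sa_T <- leak * cap_out_T
    C_sa_d <- newt(C_sa_T, C_sa_d)
    v_step <- Qi * dt
    f_vol[f_tail] <- v_step; f_C[f_tail] <- C_sa_T; f_te[f_tail] <- t
    f_tail <- f_tail + 1L
    need <- v_step; acc <- 0
    while (need > 0 && f_head < f_tail) {
      avail <- f_vol[f_head]
      take <- if (avail < need) avail else need
      c_out <- f_C[f_head] - MR * (t - f_te[f_head]) / V_sys
      if (c_out < 0) { clamped <- clamped + 1L; c_out <- 0 }
      acc <- acc + take * c_out
      f_vol[f_head] <- avail - take
      need <- need - take
      if (f_vol[f_head] <= 0) f_head <- f_head + 1L
    }
    C_sv_T <- acc / v_step
    C_sv_d <- newt(C_sv_T, C_sv_d)
    C_pa_T <- C_sv_T
    C_pa_d <- C_sv_d

    out_P_A[i] <- P_A
    out_sa_T[i] <- C_sa_T; out_sa_d[i] <- C_sa_d
    out_sv_T[i] <- C_sv_T; out_sv_d[i] <- C_sv_d
    out_cbar[i] <- sum(cap_C_d) / n_slices

    if (take_snaps && any(snap_idx == i)) {
      cap$C_T <- cap_C_T; cap$C_d <- cap_C_d; cap$vol_in <- cap_vol_in
      for (k in which(snap_idx == i)) {
        snapshots[[k]] <- capillary_snapshot(cap, params)
      }
    }
  }
  sys$clamped <- clamped

  if (sys$clamped > 0L) {
    warning(sprintf(paste0("systemic venous concentration clamped at zero ",
                           "in %d step(s): oxygen delivery could not meet ",
                           "the configured metabolic rate"), sys$clamped),
            call. = FALSE)
  }

  series <- data.frame(
    time = times, V_A = V_A, P_A = out_P_A,
    C_sa_T = out_sa_T, C_sa_d = out_sa_d,
    S_sa = hb_saturation(out_sa_d / beta), P_sa = out_sa_d / beta,
    C_sv_T = out_sv_T, C_sv_d = out_sv_d,
    S_sv = hb_saturation(out_sv_d / beta), P_sv = out_sv_d / beta,
    C_pa_T = out_sv_T, C_pv_T = out_sa_T / leak,
    C_c_bar = out_cbar)
  stopifnot(all(is.finite(as.matrix(series))))

  structure(list(times = times, series = series, snapshots = snapshots,
                 events = pattern$events, pattern = pattern,
                 params = params, dt = dt, n_slices = n_slices,
                 Q = Q, clamped = sys$clamped),
            class = "oxy_sim")
}

#' @export
print.oxy_sim <- function(x, ...) {
  cat(sprintf("<oxy_sim> %d steps of %g s (%.1f s simulated)\n",
              length(x$times), x$dt, max(x$times)))
  stab <- x$pattern$spec$stabilization_time
  idx <- x$times >= stab
  s <- x$series[idx, ]
  cat(sprintf("  after stabilization (t >= %g s):\n", stab))
  cat(sprintf("    P_A    mean %6.1f mmHg   range [%.1f, %.1f]\n",
              mean(s$P_A), min(s$P_A), max(s$P_A)))
  cat(sprintf("    S_sa   mean %6.3f        min %.3f\n",
              mean(s$S_sa), min(s$S_sa)))
  cat(sprintf("    S_sv   mean %6.3f        min %.3f\n",
              mean(s$S_sv), min(s$S_sv)))
  cat(sprintf("    C_sa_d mean %6.1f uM     C_sv_d mean %5.1f uM\n",
              mean(s$C_sa_d) * 1e6, mean(s$C_sv_d) * 1e6))
  invisible(x)
}

#' @export
summary.oxy_sim <- function(object, ...) {
  stab <- object$pattern$spec$stabilization_time
  idx <- object$times >= stab
  s <- object$series[idx, ]
  out <- list(
    analyzed_time = max(object$times) - stab,
    P_A_mean = mean(s$P_A),
    S_sa_mean = mean(s$S_sa), S_sv_mean = mean(s$S_sv),
    C_sa_d_mean_uM = mean(s$C_sa_d) * 1e6,
    C_sv_d_mean_uM = mean(s$C_sv_d) * 1e6,
    P_sv_mean = mean(s$P_sv),
    S_sa_min = min(s$S_sa), S_sv_min = min(s$S_sv),
    fick_residual = {
      Qbar <- mean(object$Q[idx])
      Qbar * (mean(s$C_sa_T) - mean(s$C_sv_T)) / object$params$MR_O2 - 1
    })
  class(out) <- "summary.oxy_sim"
  out
}

#' @export
print.summary.oxy_sim <- function(x, ...) {
  cat(sprintf("analyzed %.1f s after stabilization\n", x$analyzed_time))
  cat(sprintf("  P_A  %6.2f mmHg | S_sa %.3f (min %.3f) | S_sv %.3f (min %.3f)\n",
              x$P_A_mean, x$S_sa_mean, x$S_sa_min, x$S_sv_mean, x$S_sv_min))
  cat(sprintf("  C_sa_d %6.1f uM | C_sv_d %5.1f uM | P_sv %5.1f mmHg\n",
              x$C_sa_d_mean_uM, x$C_sv_d_mean_uM, x$P_sv_mean))
  cat(sprintf("  Fick residual Q*(Ca-Cv)/MR - 1 = %+.2e\n", x$fick_residual))
  invisible(x)
}

#' @export
plot.oxy_sim <- function(x, which = c("saturation", "dissolved", "alveolar"),
                         ...) {
  which <- match.arg(which)
  s <- x$series
  if (which == "saturation") {
    graphics::plot(s$time, s$S_sa, type = "l", ylim = range(s$S_sa, s$S_sv),
                   xlab = "time (s)", ylab = "hemoglobin saturation", ...)
    graphics::lines(s$time, s$S_sv, lty = 2)
    graphics::legend("bottomleft", legend = c("systemic arteries",
                                              "systemic veins"),
                     lty = 1:2, bty = "n")
  } else if (which == "dissolved") {
    graphics::plot(s$time, s$C_sa_d * 1e6, type = "l",
                   ylim = range(s$C_sa_d, s$C_sv_d) * 1e6,
                   xlab = "time (s)", ylab = "dissolved O2 (uM)", ...)
    graphics::lines(s$time, s$C_sv_d * 1e6, lty = 2)
  } else {
    graphics::plot(s$time, s$P_A, type = "l", xlab = "time (s)",
                   ylab = expression(P[A] ~ "(mmHg)"), ...)
  }
  invisible(x)
}
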