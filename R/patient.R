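# Nasal-pressure to lung-volume conversion for polysomnography recordings,
# plus a synthetic nasal-pressure generator used for testing and
# demonstration (clinical recordings are not redistributable).
#
# Pipeline: (1) the raw pressure signal is normalized to zero mean by
# subtracting a centered moving average; (2) a per-patient nasal
# conductance (flow per unit recorder pressure, laminar relation) is fitted
# on a clinician-identified normal-breathing segment by equating the mean
# per-breath peak pressure with the peak inspiratory flow of an ideal
# sinusoidal pattern built from the patient's ideal-body-weight tidal
# volume and BMI-class functional residual capacity; (3) flow = conductance
# x normalized pressure is integrated to volume, and slow integrator drift
# is removed by re-anchoring a rolling end-expiration baseline (a rolling
# minimum over the normalization window) to the end-expiration volume.

#' Nasal pressure record
#'
#' @param times sample times, s (uniform spacing)
#' @param pressure recorded nasal pressure, recorder units
#' @param annotations data.frame of \code{\link{resp_event}} rows (times
#'   absolute within the record), or NULL
#' @return object of class \code{nasal_record}
#' @export
nasal_record <- function(times, pressure, annotations = NULL) {
  if (length(times) != length(pressure)) {
    stop("times and pressure must have equal length", call. = FALSE)
  }
  if (any(!is.finite(pressure))) {
    stop("pressure samples must be finite", call. = FALSE)
  }
  dts <- diff(times)
  if (length(dts) && (max(dts) - min(dts)) > 1e-6 * stats::median(dts)) {
    stop("record must be uniformly sampled", call. = FALSE)
  }
  if (is.null(annotations)) annotations <- resp_event("apnea", 0, 1)[0, ]
  structure(list(times = times, pressure = pressure,
                 fs = 1 / stats::median(dts),
                 annotations = annotations),
            class = "nasal_record")
}

#' Patient profile
#'
#' Derives the anthropometric quantities the pressure pipeline needs:
#' body-mass index, ideal body weight (Devine height-based formula), the
#' ideal tidal volume (7 mL per kg of ideal body weight), and the
#' functional residual capacity by BMI class (used as the end-expiration
#' volume). The FRC class values are configuration, not constants: they
#' default to published averages for overweight and obese subjects
#' evaluated for sleep-disordered breathing.
#'
#' @param height m
#' @param weight kg
#' @param sex "M" or "F" (Devine formula intercept)
#' @param V_D dead space volume, L
#' @param frc_by_class named list of FRC values (L) for BMI classes
#'   \code{normal} (BMI < 25), \code{overweight} (25 <= BMI < 30),
#'   \code{obese} (BMI >= 30)
#' @param ml_per_kg_ibw ideal tidal volume rule, mL per kg IBW
#' @return object of class \code{patient_profile} with fields \code{BMI},
#'   \code{bmi_class}, \code{IBW}, \code{V_T}, \code{V_End}, \code{V_D} and
#'   (after fitting) \code{conductance} and \code{b_r}
#' @examples
#' patient_profile(1.78, 84.1)$bmi_class   # overweight
#' patient_profile(1.85, 105.7)$bmi_class  # obese
#' @export
patient_profile <- function(height, weight, sex = "M", V_D = 0.15,
                            frc_by_class = list(normal = 3.0,
                                                overweight = 2.6,
                                                obese = 2.1),
                            ml_per_kg_ibw = 7) {
  stop_if_not_scalar_pos(height, "height")
  stop_if_not_scalar_pos(weight, "weight")
  bmi <- weight / height^2
  bmi_class <- if (bmi < 25) "normal" else if (bmi < 30) "overweight" else "obese"
  h_in <- height / 0.0254
  ibw <- (if (identical(sex, "F")) 45.5 else 50) + 2.3 * (h_in - 60)
  structure(list(height = height, weight = weight, sex = sex,
                 BMI = bmi, bmi_class = bmi_class, IBW = ibw,
                 V_T = ml_per_kg_ibw * ibw / 1000,
                 V_End = frc_by_class[[bmi_class]],
                 V_D = V_D,
                 conductance = NA_real_, b_r = NA_real_),
            class = "patient_profile")
}

#' @export
print.patient_profile <- function(x, ...) {
  cat(sprintf("<patient_profile> BMI %.1f (%s)\n", x$BMI, x$bmi_class))
  cat(sprintf("  IBW %.1f kg -> V_T %.2f L; FRC/V_End %.1f L; V_D %.2f L\n",
              x$IBW, x$V_T, x$V_End, x$V_D))
  if (is.finite(x$conductance)) {
    cat(sprintf("  fitted conductance %.4g L/s per unit; b_r %.1f /min\n",
                x$conductance, x$b_r))
  }
  invisible(x)
}

#' Normalize a nasal pressure signal to zero mean
#'
#' Subtracts a centered moving average (window shrinking at the record
#' edges) from the raw signal, removing baseline drift while leaving the
#' respiratory oscillation essentially unchanged when its period is much
#' shorter than the window.
#'
#' @param record a \code{\link{nasal_record}}
#' @param window moving-average window, s
#' @return numeric vector of normalized pressure, same length as the record
#' @export
normalize_pressure <- function(record, window = 70) {
  stopifnot(inherits(record, "nasal_record"))
  span <- max(record$times) - min(record$times)
  if (window <= 0 || window > span) {
    stop("window must be positive and no longer than the record",
         call. = FALSE)
  }
  k <- round(window * record$fs)
  if (k %% 2 == 0) k <- k + 1
  record$pressure - moving_average(record$pressure, k)
}

# upward zero crossings of a (normalized) signal
.upward_crossings <- function(x) {
  which(x[-length(x)] <= 0 & x[-1L] > 0)
}

#' Fit the nasal conductance on a normal-breathing segment
#'
#' Estimates the breathing rate from cycle detection (upward zero
#' crossings) on the normalized pressure within the segment, builds the
#' ideal sinusoidal pattern from the profile's ideal tidal volume and FRC,
#' and sets conductance = peak ideal inspiratory flow / mean per-breath
#' maximum pressure (laminar, linear flow-pressure relation).
#'
#' @param record a \code{\link{nasal_record}}
#' @param profile a \code{\link{patient_profile}}
#' @param normal_segment length-2 numeric: clinician-identified interval of
#'   normal breathing, s; must contain at least 3 full breaths
#' @param window normalization window, s
#' @return the profile with \code{conductance} (L/s per recorder unit) and
#'   \code{b_r} (breaths/min) filled in
#' @export
fit_nasal_conductance <- function(record, profile, normal_segment,
                                  window = 70) {
  stopifnot(inherits(record, "nasal_record"),
            inherits(profile, "patient_profile"))
  p_norm <- normalize_pressure(record, window)
  idx <- record$times >= normal_segment[1] & record$times <= normal_segment[2]
  seg <- p_norm[idx]
  tseg <- record$times[idx]
  cross <- .upward_crossings(seg)
  if (length(cross) < 4L) {
    stop("normal segment must contain at least 3 full breaths", call. = FALSE)
  }
  # full cycles between first and last upward crossing
  n_breaths <- length(cross) - 1L
  b_r <- 60 * n_breaths / (tseg[cross[length(cross)]] - tseg[cross[1L]])
  # per-breath maximum pressure over complete cycles
  peaks <- vapply(seq_len(n_breaths), function(i) {
    max(seg[cross[i]:cross[i + 1L]])
  }, numeric(1))
  mean_peak <- mean(peaks)
  if (!is.finite(mean_peak) || mean_peak <= 0) {
    stop("mean per-breath peak pressure must be positive", call. = FALSE)
  }
  # ideal pattern: V_A = V_vent/2 sin(2 pi b_r t - pi/2) + ..., so the peak
  # inspiratory flow is V_vent/2 * 2 pi b_r/60 = pi V_vent b_r / 60
  V_vent <- profile$V_T - profile$V_D
  if (V_vent <= 0) stop("profile tidal volume must exceed dead space",
                        call. = FALSE)
  max_flow <- pi * V_vent * b_r / 60
  profile$conductance <- max_flow / mean_peak
  profile$b_r <- b_r
  profile
}

#' Convert a nasal pressure record to an alveolar-volume breathing pattern
#'
#' flow = conductance x normalized pressure; volume = cumulative trapezoid
#' integral of the flow; integrator drift is removed by re-anchoring a
#' rolling end-expiration baseline (rolling minimum over the normalization
#' window) to the profile's end-expiration volume. A stabilization run-in
#' of ideal normal breathing (at the fitted rate) is prepended so the
#' result can be fed directly to \code{\link{simulate_oxygen}}.
#'
#' @param record a \code{\link{nasal_record}}
#' @param profile a fitted \code{\link{patient_profile}}
#' @param window normalization / baseline window, s
#' @param stabilization_time run-in length, s (0 disables)
#' @return a \code{\link{breathing_pattern}}; annotations are carried over
#'   with onsets shifted by the run-in
#' @export
pressure_to_lung_volume <- function(record, profile, window = 70,
                                    stabilization_time = 360) {
  stopifnot(inherits(record, "nasal_record"),
            inherits(profile, "patient_profile"))
  if (!is.finite(profile$conductance) || profile$conductance <= 0) {
    stop("profile conductance must be fitted first", call. = FALSE)
  }
  p_norm <- normalize_pressure(record, window)
  flow <- profile$conductance * p_norm
  dt <- 1 / record$fs
  V_raw <- c(0, cumsum((flow[-1L] + flow[-length(flow)]) / 2 * dt))
  k <- round(window * record$fs)
  if (k %% 2 == 0) k <- k + 1
  baseline <- rolling_min(V_raw, k)
  V <- profile$V_End + (V_raw - baseline)
  if (any(V < 0)) {
    stop("negative lung volume after integration; review drift correction",
         call. = FALSE)
  }

  spec <- breathing_spec(V_T = profile$V_T, V_D = profile$V_D,
                         V_End = profile$V_End,
                         b_r = if (is.finite(profile$b_r)) profile$b_r else 12,
                         events = record$annotations,
                         total_duration = max(record$times) - min(record$times),
                         stabilization_time = stabilization_time)
  t_rel <- record$times - min(record$times)
  if (stabilization_time > 0) {
    lead <- breathing_pattern(
      breathing_spec(V_T = spec$V_T, V_D = spec$V_D, V_End = spec$V_End,
                     b_r = spec$b_r, total_duration = stabilization_time,
                     stabilization_time = 0), dt = dt)
    keep <- lead$times < stabilization_time
    times <- c(lead$times[keep], stabilization_time + t_rel)
    V_all <- c(lead$V_A[keep], V)
  } else {
    times <- t_rel
    V_all <- V
  }
  dV <- c(diff(V_all) / dt, 0)
  ev_abs <- record$annotations
  if (nrow(ev_abs)) {
    ev_abs$start <- ev_abs$start - min(record$times) + stabilization_time
  }
  structure(list(times = times, V_A = V_all, dV_A_dt = dV,
                 events = ev_abs, spec = spec, dt = dt),
            class = "breathing_pattern")
}

#' Generate a synthetic nasal pressure record
#'
#' Builds the alveolar-volume trace of the supplied breathing
#' specification, differentiates it to flow, divides by the conductance to
#' obtain pressure, and adds a slow sinusoidal baseline drift plus Gaussian
#' noise. Annotations match the inserted events. With zero noise and drift
#' the pressure is exactly proportional to dV_A/dt. Reproducible given a
#' seed.
#'
#' @param spec a \code{\link{breathing_spec}} (its stabilization_time is
#'   ignored: records start at the analyzed period)
#' @param conductance nasal conductance, L/s per recorder unit
#' @param fs sampling rate, Hz
#' @param noise_sd additive Gaussian noise, recorder units
#' @param drift_amplitude baseline drift amplitude, recorder units
#' @param drift_period drift period, s; baseline wander in recordings is
#'   slow (minutes scale), and the normalization window presumes drift much
#'   slower than a breath
#' @param seed RNG seed
#' @return a \code{\link{nasal_record}}
#' @export
synthetic_nasal_record <- function(spec, conductance = 0.05, fs = 25,
                                   noise_sd = 0.05, drift_amplitude = 0.3,
                                   drift_period = 600, seed = 1) {
  stopifnot(inherits(spec, "breathing_spec"))
  stop_if_not_scalar_pos(conductance, "conductance")
  spec$stabilization_time <- 0
  pat <- breathing_pattern(spec, dt = 1 / fs)
  flow <- pat$dV_A_dt
  pressure <- flow / conductance
  set.seed(seed)
  drift <- drift_amplitude * sin(2 * pi * pat$times / drift_period)
  noise <- stats::rnorm(length(pressure), sd = noise_sd)
  nasal_record(pat$times, pressure + drift + noise,
               annotations = spec$events)
}
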