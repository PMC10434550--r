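# Systemic circulation: capillary consumption and compartment linkage.
#
# All systemic oxygen transfer to tissue happens in the capillary
# compartment at the overall basal metabolic rate: a blood parcel moving
# with the flow obeys dC_T/dt = -MR_O2 / V_sys_cap, so a parcel that enters
# with concentration C and spends transit time tau inside (defined by
# integral of Q dt over tau equalling V_sys_cap) exits with
# C - MR_O2 tau / V_sys_cap. With constant flow this is the Fick principle:
# tau = V_sys_cap / Q and the arteriovenous difference is MR_O2 / Q.
#
# Large-vessel transit is not modelled: total concentrations are equated
# across the conducting arteries and veins (C_sa ~ C_pv up to the optional
# arteriolar leak fraction, C_pa ~ C_sv), so the only systemic delay is the
# capillary transit itself.
#
# The compartment state is a FIFO of parcels kept in an environment so the
# simulator can update it in place without copying.

#' Cardiac output from heart rate
#'
#' Q(t) = HR(t) * stroke_volume / 60.
#'
#' @param hr heart rate, beats per minute (scalar or vector); every sample
#'   must be positive
#' @param params an \code{\link{oxy_params}} object
#' @return flow in L/s, same length as \code{hr}
#' @export
cardiac_output <- function(hr, params) {
  bad <- which(!is.finite(hr) | hr <= 0)
  if (length(bad)) {
    stop(sprintf("non-positive heart rate at sample index %d", bad[1L]),
         call. = FALSE)
  }
  hr * params$stroke_volume / 60
}

#' Initialize the systemic capillary transit compartment
#'
#' The compartment is pre-filled with parcels of entry concentration
#' \code{C_T_init} and staggered entry times consistent with steady flow
#' \code{Q0}, so that the venous outlet immediately reflects a full transit.
#'
#' @param params an \code{\link{oxy_params}} object
#' @param C_T_init arterial total concentration used for the pre-fill, mol/L
#' @param Q0 initial flow, L/s
#' @param t0 simulation time at initialization, s
#' @param dt step size used for the pre-fill granularity, s
#' @param capacity hint for the number of steps the buffer should hold
#' @return an environment of class \code{systemic_state}
#' @export
systemic_init <- function(params, C_T_init, Q0, t0 = 0, dt = 0.005,
                          capacity = 100000L) {
  stopifnot(inherits(params, "oxy_params"))
  if (Q0 <= 0) stop("flow must be positive", call. = FALSE)
  V <- params$V_sys_cap
  m <- ceiling(V / (Q0 * dt))
  n_max <- as.integer(m + capacity + 16L)
  e <- new.env(parent = emptyenv())
  e$vol <- numeric(n_max)
  e$C   <- numeric(n_max)
  e$te  <- numeric(n_max)
  # oldest parcel first; entry times stretch one transit into the past
  e$vol[seq_len(m)] <- V / m
  e$C[seq_len(m)]   <- C_T_init
  e$te[seq_len(m)]  <- t0 - (V / Q0) * ((m:1) / m)
  e$head <- 1L          # oldest resident parcel
  e$tail <- m + 1L      # next write position
  e$total_vol <- V
  e$V <- V
  e$MR <- params$MR_O2
  e$clamped <- 0L
  class(e) <- "systemic_state"
  e
}

#' Step the systemic compartment: push arterial blood, emit venous blood
#'
#' Admits a parcel of volume Q dt at the arterial end and withdraws the same
#' volume from the oldest parcels at the venous end, applying the transit
#' consumption MR_O2 (t - t_entry) / V_sys_cap to each withdrawn parcel.
#' Withdrawal can split a parcel. Concentrations driven below zero by the
#' consumption are clamped at zero and counted in \code{state$clamped}
#' (reported by the simulator as a warning: it signals unphysiological
#' parameters).
#'
#' @param state a \code{\link{systemic_init}} environment (modified in
#'   place)
#' @param inlet_C_T systemic arterial total concentration, mol/L
#' @param Q current cardiac output, L/s
#' @param dt step size, s
#' @param t current simulation time, s
#' @return venous (outlet) total concentration over this step, mol/L
#' @export
systemic_step <- function(state, inlet_C_T, Q, dt, t) {
  if (Q <= 0) stop("flow must be positive", call. = FALSE)
  v_step <- Q * dt
  # push
  i <- state$tail
  if (i > length(state$vol)) .systemic_grow(state)
  state$vol[i] <- v_step
  state$C[i]   <- inlet_C_T
  state$te[i]  <- t
  state$tail <- i + 1L
  state$total_vol <- state$total_vol + v_step
  # pop the same volume from the venous end
  need <- v_step
  acc <- 0
  h <- state$head
  while (need > 0 && h < state$tail) {
    avail <- state$vol[h]
    take <- min(avail, need)
    c_out <- state$C[h] - state$MR * (t - state$te[h]) / state$V
    if (c_out < 0) {
      state$clamped <- state$clamped + 1L
      c_out <- 0
    }
    acc <- acc + take * c_out
    state$vol[h] <- avail - take
    need <- need - take
    if (state$vol[h] <= 0) h <- h + 1L
  }
  state$head <- h
  state$total_vol <- state$total_vol - (v_step - need)
  acc / (v_step - need)
}

# double the buffer, dropping the dead prefix before head
.systemic_grow <- function(state) {
  keep <- state$head:(state$tail - 1L)
  n_new <- max(2L * length(state$vol), length(keep) + 1024L)
  vol <- numeric(n_new); C <- numeric(n_new); te <- numeric(n_new)
  k <- length(keep)
  vol[seq_len(k)] <- state$vol[keep]
  C[seq_len(k)]   <- state$C[keep]
  te[seq_len(k)]  <- state$te[keep]
  state$vol <- vol; state$C <- C; state$te <- te
  state$head <- 1L; state$tail <- k + 1L
  invisible(state)
}

#' Run a whole inlet series through the systemic compartment
#'
#' Convenience wrapper used for testing and for stand-alone analysis of the
#' transit/consumption stage: feeds an arterial concentration series sample
#' by sample and returns the venous series.
#'
#' @param inlet_C_T arterial total concentration series, mol/L
#' @param Q flow, L/s: scalar or series of the same length
#' @param dt sample spacing, s
#' @param params an \code{\link{oxy_params}} object
#' @return venous total concentration series, mol/L
#' @export
systemic_transit <- function(inlet_C_T, Q, dt, params) {
  n <- length(inlet_C_T)
  Q <- rep_len(Q, n)
  st <- systemic_init(params, inlet_C_T[1L], Q[1L], t0 = 0, dt = dt,
                      capacity = n)
  out <- numeric(n)
  for (i in seq_len(n)) {
    out[i] <- systemic_step(st, inlet_C_T[i], Q[i], dt, i * dt)
  }
  if (st$clamped > 0L) {
    warning(sprintf(paste0("venous concentration clamped at zero in %d ",
                           "step(s): consumption exceeds delivery"),
                    st$clamped), call. = FALSE)
  }
  out
}
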