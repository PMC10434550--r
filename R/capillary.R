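# Pulmonary capillary compartment: Lagrangian parcel transport.
#
# Blood moves through the capillary compartment of length L_c = V_pc / A_eff
# as a FIFO queue of control volumes ("parcels") of fixed blood volume
# dV = V_pc / N. Each parcel takes up oxygen across the membrane,
#     dV dC_T/dt = k_pc (C_A - C_d),    k_pc = (D_L_O2 / beta_p) (dz / L_c),
# with dz = L_c / N the parcel length, so k_pc = k_l / N and the summed
# parcel uptake equals the alveolar-side loss k_l (C_A - Cbar_c) exactly.
# Parcels advect with the pulmonary blood velocity v = Q / A_eff; a parcel
# leaving z = L_c carries the pulmonary end-capillary (= pulmonary venous)
# total concentration, and a fresh parcel enters at z = 0 with the pulmonary
# arterial total concentration.
#
# The per-step uptake uses an exponential (locally linearized) update: with
# m = dC_d/dC_T evaluated at the parcel state, the linear relaxation
#     C_T <- C_T + (C_A - C_d)/m * (1 - exp(-alpha m dt)),  alpha = k_pc/dV,
# is exact whenever C_d depends linearly on C_T (in particular with
# hemoglobin disabled, C_Hb = 0) and reduces to forward Euler as dt -> 0.
# It remains stable for step sizes where plain Euler would already be
# marginal.

#' Initialize a pulmonary capillary profile
#'
#' @param params an \code{\link{oxy_params}} object
#' @param n_slices number of parcels resident in the compartment
#' @param C_T_init initial total O2 concentration, mol/L: either a scalar or
#'   a vector of length \code{n_slices} ordered inlet to outlet
#' @return object of class \code{capillary_profile}
#' @export
capillary_init <- function(params, n_slices = 40, C_T_init) {
  stopifnot(inherits(params, "oxy_params"))
  n_slices <- as.integer(n_slices)
  if (n_slices < 1L) stop("n_slices must be at least 1", call. = FALSE)
  C_T <- rep_len(C_T_init, n_slices)
  C_d <- .dissolved_newton(C_T, params$C_Hb, params$beta_p)
  structure(list(
    n = n_slices,
    dV = params$V_pc / n_slices,          # L per parcel
    dz = params$L_c / n_slices,           # m per parcel
    k_pc = params$k_l / n_slices,         # L/s per parcel
    C_T = C_T,                            # ordered inlet -> outlet
    C_d = C_d,
    vol_in = 0,                           # advected volume since last shift, L
    outlet_C_T = C_T[n_slices]
  ), class = "capillary_profile")
}

#' Advance the capillary profile over one time step
#'
#' Applies membrane uptake to every parcel, then advects the queue by the
#' blood volume Q dt, emitting parcels at the outlet and admitting fresh
#' parcels at the inlet.
#'
#' @param profile a \code{\link{capillary_init}} object
#' @param C_A dissolved O2 concentration in the alveolar membrane, mol/L
#'   (= beta_p P_A)
#' @param inlet_C_T pulmonary arterial total O2 concentration entering at
#'   z = 0, mol/L
#' @param Q pulmonary blood flow, L/s (> 0)
#' @param dt step size, s; must satisfy the advection constraint
#'   Q dt <= dV (at most one parcel per step)
#' @param params an \code{\link{oxy_params}} object
#' @return list with the updated \code{profile}, \code{outlet_C_T} (total
#'   concentration of the most recently emitted parcel, mol/L) and
#'   \code{uptake_mol}, the oxygen taken up from the alveoli during the step
#'   (mol)
#' @export
advance_capillary <- function(profile, C_A, inlet_C_T, Q, dt, params) {
  if (Q <= 0) stop("pulmonary blood flow must be positive", call. = FALSE)
  if (dt <= 0) stop("dt must be positive", call. = FALSE)
  if (Q * dt > profile$dV * (1 + 1e-9)) {
    stop(sprintf(paste0("advection constraint violated: Q*dt = %.3g L exceeds ",
                        "the parcel volume %.3g L; reduce dt below %.3g s"),
                 Q * dt, profile$dV, profile$dV / Q), call. = FALSE)
  }
  up <- .capillary_uptake(profile, C_A, dt, params)
  profile <- up$profile
  # advection: admit Q dt of blood at the inlet, emit the same at the outlet
  profile$vol_in <- profile$vol_in + Q * dt
  while (profile$vol_in >= profile$dV * (1 - 1e-12)) {
    n <- profile$n
    profile$outlet_C_T <- profile$C_T[n]
    inlet_C_d <- .dissolved_newton(inlet_C_T, params$C_Hb, params$beta_p,
                                   x0 = profile$C_d[1L])
    profile$C_T <- c(inlet_C_T, profile$C_T[-n])
    profile$C_d <- c(inlet_C_d, profile$C_d[-n])
    profile$vol_in <- profile$vol_in - profile$dV
  }
  if (any(profile$C_T < 0)) {
    stop("negative capillary concentration: numerical failure", call. = FALSE)
  }
  list(profile = profile, outlet_C_T = profile$outlet_C_T,
       uptake_mol = up$uptake_mol)
}

# membrane uptake for all parcels over dt (exponential update); returns the
# updated profile and the moles moved across the membrane
.capillary_uptake <- function(profile, C_A, dt, params) {
  beta <- params$beta_p
  C_Hb <- params$C_Hb
  P <- profile$C_d / beta
  m <- 1 / (1 + 4 * C_Hb * hb_saturation_slope(P) / beta)  # dC_d/dC_T
  alpha <- profile$k_pc / profile$dV                       # 1/s
  dC_T <- (C_A - profile$C_d) / m * (1 - exp(-alpha * m * dt))
  C_T_new <- profile$C_T + dC_T
  C_d_new <- .dissolved_newton(C_T_new, C_Hb, beta,
                               x0 = pmax(profile$C_d + m * dC_T, 0))
  profile$C_T <- C_T_new
  profile$C_d <- C_d_new
  list(profile = profile, uptake_mol = profile$dV * sum(dC_T))
}

#' Spatially averaged dissolved oxygen along the capillary
#'
#' Volume-weighted mean of the parcel dissolved concentrations,
#' approximating (1/L_c) times the integral of C_d over [0, L_c]. All
#' parcels share the same volume, so this is the plain mean.
#'
#' @param profile a \code{capillary_profile}
#' @return mol/L
#' @export
capillary_average <- function(profile) {
  if (!length(profile$C_d)) stop("empty capillary compartment", call. = FALSE)
  mean(profile$C_d)
}

#' Positions and partial pressures of the resident parcels
#'
#' Snapshot of the axial oxygen profile, e.g. to compare the alveolar and
#' end-capillary partial pressures.
#'
#' @param profile a \code{capillary_profile}
#' @param params an \code{\link{oxy_params}} object
#' @return data.frame with \code{z_m} (position of parcel center, m, inlet
#'   at 0) and \code{P_mmHg}
#' @export
capillary_snapshot <- function(profile, params) {
  n <- profile$n
  frac <- profile$vol_in / profile$dV
  z <- ((seq_len(n) - 0.5) + frac) * profile$dz
  data.frame(z_m = z, P_mmHg = profile$C_d / params$beta_p)
}
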