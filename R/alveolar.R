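# Alveolar compartment oxygen mass balance.
#
# The alveoli are a single well-mixed compartment. During inspiration
# (dV_A/dt > 0) fresh humidified air enters at the inspired partial pressure
# P_I and oxygen leaves across the alveolar-capillary membrane:
#     V_A dP_A/dt = dV_A/dt (P_I - P_A) - k_l (C_A - Cbar_c) R T,
# during expiration (dV_A/dt <= 0) only the membrane term remains:
#     V_A dP_A/dt = - k_l (C_A - Cbar_c) R T,
# with C_A = beta_p P_A the dissolved oxygen in the membrane, Cbar_c the
# spatially averaged dissolved oxygen along the pulmonary capillary
# compartment, and k_l = D_L_O2 / beta_p. The two regimes coincide at
# dV_A/dt = 0, so the expiration form is used there.

#' Inspired oxygen partial pressure
#'
#' P_I = y_O2 (P_B - P_H2O): inspired air saturated with water vapor at body
#' temperature.
#'
#' @param params an \code{oxy_params} object (or any list carrying
#'   \code{y_O2}, \code{P_B}, \code{P_H2O})
#' @return partial pressure, mmHg
#' @export
inspired_po2 <- function(params) {
  if (params$P_H2O >= params$P_B) {
    stop("water vapor pressure must be below barometric pressure",
         call. = FALSE)
  }
  params$y_O2 * (params$P_B - params$P_H2O)
}

#' Alveolar pressure right-hand side
#'
#' Instantaneous rate of change of the alveolar oxygen partial pressure for
#' the current breathing regime.
#'
#' @param P_A alveolar O2 partial pressure, mmHg
#' @param V_A current alveolar volume, L (> 0)
#' @param dV_A_dt rate of change of alveolar volume, L/s
#' @param C_c_bar spatially averaged dissolved O2 in the pulmonary
#'   capillaries, mol/L
#' @param params an \code{\link{oxy_params}} object
#' @return dP_A/dt in mmHg/s
#' @export
alveolar_rhs <- function(P_A, V_A, dV_A_dt, C_c_bar, params) {
  if (!is.finite(V_A) || V_A <= 0) {
    stop("alveolar volume must be positive", call. = FALSE)
  }
  C_A <- params$beta_p * P_A
  membrane <- params$k_l * (C_A - C_c_bar) * params$R * params$T
  if (dV_A_dt > 0) {
    (dV_A_dt * (params$P_I - P_A) - membrane) / V_A
  } else {
    -membrane / V_A
  }
}
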