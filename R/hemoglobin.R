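# Oxygen-hemoglobin chemistry.
#
# The saturation curve is a rational-function fit to the standard adult
# oxygen-hemoglobin dissociation curve,
#     S(P) = [1 + 23400 / (P^3 + 150 P)]^-1      (P in mmHg),
# whose two constants define the published fit and are therefore not
# configurable. Total blood oxygen splits into a dissolved part C_d and a
# hemoglobin-bound part 4 * C_Hb * S, with P = C_d / beta_p linking the
# dissolved concentration to partial pressure.

#' Hemoglobin O2 saturation from partial pressure
#'
#' @param P oxygen partial pressure in mmHg (vectorized, must be >= 0)
#' @return saturation fraction in [0, 1); S(0) = 0 and S is strictly
#'   increasing in P
#' @examples
#' hb_saturation(c(0, 41, 99))
#' @export
hb_saturation <- function(P) {
  if (any(!is.finite(P)) || any(P < 0)) {
    stop("partial pressure must be finite and non-negative", call. = FALSE)
  }
  g <- P^3 + 150 * P
  g / (g + 23400)
}

#' Slope dS/dP of the dissociation curve
#' @param P partial pressure, mmHg
#' @return derivative of \code{\link{hb_saturation}} at P, per mmHg
#' @export
hb_saturation_slope <- function(P) {
  g <- P^3 + 150 * P
  23400 * (3 * P^2 + 150) / (g + 23400)^2
}

#' Blood oxygen state from the dissolved concentration
#'
#' Completes the (C_d, P, S, C_T) quadruple from a dissolved concentration:
#' P = C_d / beta_p, S = S(P), C_T = C_d + 4 C_Hb S.
#'
#' @param C_d dissolved O2 concentration, mol per L of blood (vectorized)
#' @param params an \code{\link{oxy_params}} object
#' @param compartment optional compartment tag ("pa", "pc", "pv", "sa", "sv")
#' @return data.frame of class \code{blood_state} with columns
#'   \code{C_d}, \code{C_T}, \code{S}, \code{P} (and \code{compartment})
#' @export
blood_from_dissolved <- function(C_d, params, compartment = NA_character_) {
  stopifnot(inherits(params, "oxy_params"))
  if (any(!is.finite(C_d)) || any(C_d < 0)) {
    stop("dissolved concentration must be finite and non-negative",
         call. = FALSE)
  }
  P <- C_d / params$beta_p
  S <- hb_saturation(P)
  out <- data.frame(C_d = C_d, C_T = C_d + 4 * params$C_Hb * S, S = S, P = P,
                    compartment = compartment)
  class(out) <- c("blood_state", class(out))
  out
}

# Vectorized safeguarded Newton for the inverse map C_T -> C_d.
# f(x) = x + 4 C_Hb S(x / beta) - C_T is strictly increasing, so the root in
# [0, C_T] is unique; Newton steps leaving the bracket fall back to bisection.
.dissolved_newton <- function(C_T, C_Hb, beta_p, x0 = NULL,
                              tol = 1e-12, maxit = 100L) {
  lo <- rep(0, length(C_T))
  hi <- C_T
  x <- if (is.null(x0)) pmin(C_T, 0.5 * C_T) else pmin(pmax(x0, lo), hi)
  for (it in seq_len(maxit)) {
    P <- x / beta_p
    S <- hb_saturation(P)
    f <- x + 4 * C_Hb * S - C_T
    if (all(abs(f) < tol)) return(x)
    lo[f < 0] <- x[f < 0]
    hi[f > 0] <- x[f > 0]
    fp <- 1 + 4 * C_Hb * hb_saturation_slope(P) / beta_p
    xn <- x - f / fp
    bad <- !is.finite(xn) | xn <= lo | xn >= hi
    xn[bad] <- (lo[bad] + hi[bad]) / 2
    x <- xn
  }
  P <- x / beta_p
  resid <- x + 4 * C_Hb * hb_saturation(P) - C_T
  if (any(abs(resid) >= 1e-9)) {
    stop(sprintf(paste0("dissolved-oxygen inversion did not converge: ",
                        "max residual %.3g mol/L, bracket [%.3g, %.3g]"),
                 max(abs(resid)), min(lo), max(hi)), call. = FALSE)
  }
  x
}

#' Blood oxygen state from the total concentration
#'
#' Inverts C_T = C_d + 4 C_Hb S(C_d / beta_p) for the unique dissolved
#' concentration (the map is strictly increasing in C_d, so any finite
#' non-negative total is admissible), then completes the state.
#'
#' @param C_T total O2 concentration, mol per L of blood (vectorized)
#' @param params an \code{\link{oxy_params}} object
#' @param compartment optional compartment tag
#' @param tol absolute residual tolerance in mol/L
#' @return \code{blood_state} data.frame as in
#'   \code{\link{blood_from_dissolved}}
#' @export
blood_from_total <- function(C_T, params, compartment = NA_character_,
                             tol = 1e-12) {
  stopifnot(inherits(params, "oxy_params"))
  if (any(!is.finite(C_T)) || any(C_T < 0)) {
    stop("total concentration must be finite and non-negative", call. = FALSE)
  }
  C_d <- .dissolved_newton(C_T, params$C_Hb, params$beta_p, tol = tol)
  out <- blood_from_dissolved(C_d, params, compartment)
  out$C_T <- C_T   # report the requested total, residual < tol
  out
}
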