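# Physiological parameter registry.
#
# Canonical internal units: mol, L, s, mmHg, K. The one deliberately
# "clinical" entry point is the lung diffusing capacity, which is configured
# in mL O2 min^-1 mmHg^-1 (how pulmonary function labs report it) and
# converted to mol s^-1 mmHg^-1 at STPD.

# Gas-volume <-> mole conversion at STPD, declared once: 22,400 mL O2 per mol.
STPD_ML_PER_MOL <- 22400

.oxy_param_defaults <- function() {
  list(
    D_L_O2_clinical = 21,      # mL O2 min^-1 mmHg^-1, normal resting adult
    beta_p   = 1.4e-6,         # mol L^-1 mmHg^-1, O2 solubility (plasma/membrane)
    C_Hb     = 2.3e-3,         # mol L^-1 hemoglobin (about 15 g/dL)
    MR_O2    = 1.83e-4,        # mol s^-1 basal O2 consumption (about 246 mL/min)
    V_pc     = 0.07,           # L, pulmonary capillary blood volume
    V_sys_cap = 5.0,           # L, systemic transit blood volume (see vignette)
    A_eff    = 0.07,           # m^2, effective pulmonary capillary cross-section
    P_B      = 760,            # mmHg barometric pressure
    P_H2O    = 47,             # mmHg water vapor pressure at 37 C
    y_O2     = 0.21,           # inspired O2 mole fraction
    R        = 62.36367,       # L mmHg K^-1 mol^-1
    T        = 310,            # K body temperature
    stroke_volume = 0.07,      # L per beat
    heart_rate    = 75,        # beats min^-1, default constant heart rate
    arteriole_leak_fraction = 1 # dimensionless (0,1], 1 = no arteriolar loss
  )
}

#' Physiological parameter set
#'
#' Builds and validates the full parameter registry used by every model
#' component. All fields have defaults calibrated to resting adult
#' physiology; any subset can be overridden. Internally all values are kept
#' in mol/L/s/mmHg/K units; the lung diffusing capacity is accepted in the
#' conventional clinical unit (mL O2 per minute per mmHg) and converted at
#' STPD (22,400 mL O2 per mol).
#'
#' @param ... named overrides of the defaults. Recognised names:
#'   \code{D_L_O2_clinical} (mL O2 min^-1 mmHg^-1), \code{beta_p}
#'   (mol L^-1 mmHg^-1), \code{C_Hb} (mol L^-1), \code{MR_O2} (mol s^-1),
#'   \code{V_pc}, \code{V_sys_cap} (L), \code{A_eff} (m^2), \code{P_B},
#'   \code{P_H2O} (mmHg), \code{y_O2} (fraction), \code{R}
#'   (L mmHg K^-1 mol^-1), \code{T} (K), \code{stroke_volume} (L),
#'   \code{heart_rate} (min^-1), \code{arteriole_leak_fraction} (fraction).
#' @param strict if TRUE (default) unknown names are an error, otherwise a
#'   warning.
#' @return an object of class \code{oxy_params}: a named list with derived
#'   quantities \code{D_L_O2} (mol s^-1 mmHg^-1), \code{k_l} (L s^-1),
#'   \code{L_c} (m) and \code{P_I} (mmHg, inspired O2 partial pressure)
#'   attached, and a \code{provenance} attribute recording which fields were
#'   user-supplied.
#' @examples
#' p <- oxy_params()
#' p$k_l              # lung mass-transfer coefficient, L/s
#' oxy_params(C_Hb = 2.0e-3)$C_Hb
#' @export
oxy_params <- function(..., strict = TRUE) {
  user <- list(...)
  if (length(user) == 1L && is.null(names(user)) && is.list(user[[1L]])) {
    user <- user[[1L]]
  }
  defaults <- .oxy_param_defaults()
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown)) {
    msg <- sprintf("unknown parameter(s): %s", paste(unknown, collapse = ", "))
    if (strict) stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
    user <- user[setdiff(names(user), unknown)]
  }
  p <- utils::modifyList(defaults, user)

  for (nm in c("D_L_O2_clinical", "beta_p", "C_Hb", "MR_O2", "V_pc",
               "V_sys_cap", "A_eff", "P_B", "P_H2O", "R", "T",
               "stroke_volume", "heart_rate")) {
    stop_if_not_scalar_pos(p[[nm]], nm)
  }
  if (p$y_O2 <= 0 || p$y_O2 >= 1) {
    stop("'y_O2' must be a mole fraction strictly inside (0, 1)", call. = FALSE)
  }
  if (p$arteriole_leak_fraction <= 0 || p$arteriole_leak_fraction > 1) {
    stop("'arteriole_leak_fraction' must lie in (0, 1]", call. = FALSE)
  }
  if (p$P_H2O >= p$P_B) {
    stop("'P_H2O' must be smaller than barometric pressure 'P_B'", call. = FALSE)
  }

  # Derived quantities. k_l = D_L_O2 / beta_p carries L s^-1 (a volumetric
  # conductance); L_c = V_pc / A_eff is the capillary compartment length.
  p$D_L_O2 <- p$D_L_O2_clinical / STPD_ML_PER_MOL / 60   # mol s^-1 mmHg^-1
  p$k_l <- p$D_L_O2 / p$beta_p                           # L s^-1
  p$L_c <- (p$V_pc / 1000) / p$A_eff                     # m (L -> m^3)
  p$P_I <- inspired_po2(p)                               # mmHg
  stopifnot(p$k_l > 0, p$L_c > 0)

  structure(p,
            class = "oxy_params",
            provenance = names(user))
}

#' Load a parameter set from a YAML/JSON file or list
#'
#' @param config path to a YAML (or JSON) key-value document, or a named list.
#'   Every field is optional; missing fields take the documented defaults.
#' @param strict reject unknown keys (TRUE) or warn about them (FALSE).
#' @return validated \code{oxy_params} object
#' @export
load_params <- function(config = list(), strict = TRUE) {
  if (is.character(config)) {
    if (!file.exists(config)) {
      stop(sprintf("parameter file not found: '%s'", config), call. = FALSE)
    }
    config <- yaml::read_yaml(config)
    if (is.null(config)) config <- list()
  }
  if (!is.list(config)) {
    stop("'config' must be a file path or a named list", call. = FALSE)
  }
  oxy_params(config, strict = strict)
}

#' Serialize a parameter set to the overridable configuration fields
#'
#' Writes the configurable (non-derived) fields so that reloading with
#' \code{\link{load_params}} reproduces the object exactly.
#'
#' @param params an \code{oxy_params} object
#' @param path file to write (YAML); if NULL, the list is returned invisibly
#' @export
write_params <- function(params, path = NULL) {
  stopifnot(inherits(params, "oxy_params"))
  cfg <- params[names(.oxy_param_defaults())]
  if (!is.null(path)) yaml::write_yaml(cfg, path)
  invisible(cfg)
}

#' @export
print.oxy_params <- function(x, ...) {
  cat("<oxy_params> physiological parameter set\n")
  cat(sprintf("  D_L_O2  %.3g mL O2/min/mmHg (%.3g mol/s/mmHg)\n",
              x$D_L_O2_clinical, x$D_L_O2))
  cat(sprintf("  beta_p  %.3g mol/L/mmHg   C_Hb %.3g mol/L\n", x$beta_p, x$C_Hb))
  cat(sprintf("  MR_O2   %.3g mol/s (%.0f mL O2/min STPD)\n",
              x$MR_O2, x$MR_O2 * STPD_ML_PER_MOL * 60))
  cat(sprintf("  V_pc %.3g L   V_sys_cap %.3g L   A_eff %.3g m^2 (L_c %.3g mm)\n",
              x$V_pc, x$V_sys_cap, x$A_eff, x$L_c * 1000))
  cat(sprintf("  P_B %g  P_H2O %g  y_O2 %g  ->  P_I %.2f mmHg\n",
              x$P_B, x$P_H2O, x$y_O2, x$P_I))
  cat(sprintf("  heart rate %g bpm x stroke volume %g L -> Q %.3f L/s\n",
              x$heart_rate, x$stroke_volume,
              x$heart_rate * x$stroke_volume / 60))
  ov <- attr(x, "provenance")
  if (length(ov)) cat("  user-set:", paste(ov, collapse = ", "), "\n")
  invisible(x)
}
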