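# Biophysical primitives: Boltzmann gating, Nernst potentials, LJP correction,
# surface area, flux-direction prediction.

.FARADAY <- 96485.33212   # C mol^-1
.GAS_CONST <- 8.314462618 # J mol^-1 K^-1

#' Thermal voltage RT/F in millivolts
#'
#' @param temperature Absolute temperature in kelvin.
#' @return Thermal voltage in mV (about 25.4 mV at 22 degC).
#' @export
thermal_voltage <- function(temperature = 295.15) {
  stopifnot(is.numeric(temperature), temperature > 0)
  1000 * .GAS_CONST * temperature / .FARADAY
}

.vt_mV <- function(temperature, thermal_voltage_mV = NULL) {
  if (!is.null(thermal_voltage_mV)) {
    stopifnot(is.numeric(thermal_voltage_mV), thermal_voltage_mV > 0)
    return(thermal_voltage_mV)
  }
  thermal_voltage(temperature)
}

#' Correct nominal command voltages for the liquid junction potential
#'
#' Whole-cell command voltages are nominal amplifier values; the true membrane
#' potential is offset by the liquid junction potential (LJP) of the
#' pipette/bath interface. The correction is additive: a nominal holding
#' potential of 0 mV with an LJP of -23 mV corresponds to a true membrane
#' potential of -23 mV.
#'
#' @param nominal_mV Numeric vector of nominal command voltages (mV).
#' @param ljp_mV Scalar LJP for the bath solution in use (mV). Must be
#'   supplied explicitly; there is no default because the LJP depends on the
#'   bath composition.
#' @return Corrected membrane potentials (mV).
#' @export
correct_ljp <- function(nominal_mV, ljp_mV) {
  if (missing(ljp_mV) || is.null(ljp_mV) || length(ljp_mV) != 1L ||
      !is.finite(ljp_mV)) {
    stop("a finite scalar `ljp_mV` must be provided for the recording's bath")
  }
  stopifnot(is.numeric(nominal_mV))
  nominal_mV + ljp_mV
}

#' Protoplast surface area from diameter
#'
#' Protoplasts are treated as spheres, so the membrane area is pi * d^2.
#'
#' @param diameter_um Diameter in micrometres.
#' @return Surface area in cm^2.
#' @export
surface_area <- function(diameter_um) {
  stopifnot(is.numeric(diameter_um))
  if (any(diameter_um <= 0)) stop("diameter must be positive")
  pi * (diameter_um * 1e-4)^2
}

#' Boltzmann conductance-voltage relation
#'
#' Specific conductance of a membrane carrying a single voltage-gated channel
#' population with a basal (voltage-invariant) component:
#' \deqn{G'(E) = G'_b + (G'_{max} - G'_b) / (1 + exp(z (E - E_{1/2}) / V_T))}
#' with thermal voltage \eqn{V_T = RT/F}. With z > 0 the conductance falls
#' with depolarization, i.e. the channels are inward rectifiers that open on
#' hyperpolarization.
#'
#' @param e_m Membrane potential(s), mV (LJP-corrected).
#' @param g_b Basal specific conductance, mS cm^-2.
#' @param g_max Maximal specific conductance, mS cm^-2.
#' @param e_half Half-activation voltage, mV.
#' @param z Effective gating charge (dimensionless, > 0).
#' @param temperature Kelvin; used when `thermal_voltage_mV` is NULL.
#' @param thermal_voltage_mV Optional explicit RT/F in mV (overrides
#'   `temperature`).
#' @return Specific conductance(s), mS cm^-2.
#' @export
boltzmann_conductance <- function(e_m, g_b, g_max, e_half, z,
                                  temperature = 295.15,
                                  thermal_voltage_mV = NULL) {
  vt <- .vt_mV(temperature, thermal_voltage_mV)
  g_b + (g_max - g_b) / (1 + exp(z * (e_m - e_half) / vt))
}

#' Steady-state open fraction of a voltage-gated channel
#'
#' \deqn{P_O(E) = 1 / (1 + exp(z (E - E_{1/2}) / V_T))}
#' which equals \eqn{(G'(E) - G'_b) / G'_{max,net}} under the Boltzmann
#' conductance model. P_O(E_1/2) = 0.5 exactly, and P_O is strictly
#' decreasing in E for z > 0.
#'
#' @param e_m Membrane potential(s), mV (LJP-corrected).
#' @param fit Optional `boltzmann_fit` object; if given, `e_half` and `z`
#'   are taken from it.
#' @param e_half,z Gating parameters, used when `fit` is NULL.
#' @inheritParams boltzmann_conductance
#' @return Open fraction(s) in [0, 1].
#' @export
open_fraction <- function(e_m, fit = NULL, e_half = NULL, z = NULL,
                          temperature = 295.15, thermal_voltage_mV = NULL) {
  if (!is.null(fit)) {
    stopifnot(inherits(fit, "boltzmann_fit"))
    e_half <- fit$e_half
    z <- fit$z
  }
  stopifnot(is.numeric(e_half), is.numeric(z), z > 0)
  vt <- .vt_mV(temperature, thermal_voltage_mV)
  1 / (1 + exp(z * (e_m - e_half) / vt))
}

#' Nernst equilibrium potential for one ion
#'
#' \deqn{E_X = (RT / zF) ln(c_{out} / c_{in})}
#'
#' @param c_out,c_in Extracellular and intracellular concentrations (mM, > 0).
#' @param valence Ion valence (nonzero integer; +1 for K+).
#' @param temperature Kelvin.
#' @return Equilibrium potential in mV.
#' @export
nernst <- function(c_out, c_in, valence = 1, temperature = 295.15) {
  stopifnot(is.numeric(c_out), is.numeric(c_in))
  if (any(c_out <= 0) || any(c_in <= 0)) {
    stop("concentrations must be positive")
  }
  if (valence == 0) stop("valence must be nonzero")
  (thermal_voltage(temperature) / valence) * log(c_out / c_in)
}

#' Ionic solution composition
#'
#' Holds per-ion total concentrations (mM) for a bath or pipette solution,
#' plus the LJP measured against the standard pipette filling where relevant.
#'
#' @param concentrations_mM Named numeric vector of ion concentrations, e.g.
#'   `c(K = 5, Cl = 11, Ca = 1, Mg = 4)`.
#' @param ljp_mV LJP of this bath against the standard pipette (mV), or NA.
#' @param label Free-text label.
#' @return An object of class `ion_solution`.
#' @export
ion_solution <- function(concentrations_mM, ljp_mV = NA_real_, label = "") {
  stopifnot(is.numeric(concentrations_mM), !is.null(names(concentrations_mM)))
  if (any(concentrations_mM < 0)) stop("concentrations must be non-negative")
  structure(list(conc = concentrations_mM, ljp_mV = ljp_mV, label = label),
            class = "ion_solution")
}

#' Standard experimental solutions
#'
#' Total ion contents of the standard bath and pipette solutions used in the
#' whole-cell experiments the package models. The low-K bath holds 5 mM K+
#' (LJP -23 mV), the 30-K bath 30 mM K+ (LJP -14 mV); the pipette filling
#' contains 140 mM K+ from K-gluconate/KCl plus 12 mM from the K2-ATP and
#' K4-BAPTA additions (152 mM total).
#'
#' @name standard_solutions
#' @return An `ion_solution`.
NULL

#' @rdname standard_solutions
#' @export
bath_low_k <- function() {
  ion_solution(c(K = 5, Cl = 11, Ca = 1, Mg = 4), ljp_mV = -23,
               label = "low-K bath (5 mM K+)")
}

#' @rdname standard_solutions
#' @export
bath_30_k <- function() {
  ion_solution(c(K = 30, Cl = 11, Ca = 1, Mg = 4), ljp_mV = -14,
               label = "30-K bath (30 mM K+)")
}

#' @rdname standard_solutions
#' @param include_additions Count the K+ contributed by the K2-ATP and
#'   K4-BAPTA additions (default TRUE, 152 mM total; FALSE gives 140 mM).
#' @export
pipette_standard <- function(include_additions = TRUE) {
  k <- if (include_additions) 152 else 140
  ion_solution(c(K = k, Cl = 36, Mg = 4), label = "standard pipette filling")
}

#' Nernst potential between two solutions
#'
#' @param bath,pipette `ion_solution` objects (bath = extracellular).
#' @param ion Ion name present in both solutions.
#' @param valence Ion valence.
#' @param temperature Kelvin.
#' @return Equilibrium potential, mV.
#' @export
nernst_potential <- function(bath, pipette, ion = "K", valence = 1,
                             temperature = 295.15) {
  stopifnot(inherits(bath, "ion_solution"), inherits(pipette, "ion_solution"))
  if (!ion %in% names(bath$conc) || !ion %in% names(pipette$conc)) {
    stop("ion '", ion, "' missing from a solution")
  }
  nernst(bath$conc[[ion]], pipette$conc[[ion]], valence, temperature)
}

#' Predict the direction of channel-mediated K+ flux
#'
#' Relative net K+ flux through the modelled channel population at a given
#' membrane potential, taking the K+ equilibrium potential as the zero-flux
#' point: flux is proportional to
#' \eqn{-(G'_b + G'_{max,net} P_O(E_M)) (E_M - E_K)}.
#' A positive value denotes influx (E_M more negative than E_K), a negative
#' value efflux.
#'
#' @param e_m Membrane potential, mV (corrected).
#' @param e_k K+ equilibrium potential, mV.
#' @param fit `boltzmann_fit` (or any list with `g_b`, `g_max_net`, `e_half`,
#'   `z` components).
#' @inheritParams boltzmann_conductance
#' @return A data.frame with columns `e_m`, `e_k`, `open_fraction`,
#'   `flux` (relative, mS cm^-2 mV) and `direction`
#'   ("influx", "efflux" or "zero").
#' @export
predict_flux_direction <- function(e_m, e_k, fit, temperature = 295.15,
                                   thermal_voltage_mV = NULL) {
  po <- open_fraction(e_m, e_half = fit$e_half, z = fit$z,
                      temperature = temperature,
                      thermal_voltage_mV = thermal_voltage_mV)
  g <- fit$g_b + fit$g_max_net * po
  flux <- -g * (e_m - e_k)
  direction <- ifelse(flux > 0, "influx", ifelse(flux < 0, "efflux", "zero"))
  data.frame(e_m = e_m, e_k = e_k, open_fraction = po,
             flux = flux, direction = direction)
}
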