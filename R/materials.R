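# Material properties, boundary conditions, permeability conversions and the
# lumped finite-reservoir pressure protocol.

#' Forchheimer friction factor from porosity
#'
#' `Cf = 1.75 / sqrt(150 * eps_p^3)`, the Ergun-type dimensionless friction
#' factor of a porous medium of porosity `eps_p`; strictly decreasing in
#' porosity.
#'
#' @param eps_p porosity in (0, 1].
#' @export
friction_factor <- function(eps_p) {
  if (any(!is.finite(eps_p)) || any(eps_p <= 0) || any(eps_p > 1))
    stop("porosity must lie in (0, 1]")
  1.75 / sqrt(150 * eps_p^3)
}

#' Hydraulic permeability from diffusive permeability
#'
#' `kappa = P_D * mu * L / eps_p` (the documented reading of the conversion
#' between the endothelial diffusive permeability and its Darcy
#' permeability; units are recorded in the result's attributes).
#'
#' @param Pd diffusive permeability, m/s.
#' @param mu dynamic viscosity of the layer, Pa s (default 3e-3, a
#'   whole-blood-like value for the endothelial monolayer).
#' @param L characteristic length in meters (default 1e-3, the tissue
#'   chamber thickness between parent channels).
#' @param eps_p porosity (default 0.265).
#' @return kappa in m^2, with a `units` attribute recording the reading.
#' @export
hydraulic_from_diffusive <- function(Pd, mu = 3e-3, L = 1e-3, eps_p = 0.265) {
  if (any(c(Pd, mu, L, eps_p) <= 0)) stop("all inputs must be positive")
  kappa <- Pd * mu * L / eps_p
  attr(kappa, "units") <- "kappa[m^2] = Pd[m/s] * mu[Pa s] * L[m] / eps_p[-]"
  kappa
}

#' Material properties of the flow domain
#'
#' Per-region porosity, Darcy permeability and effective viscosity for the
#' lumen (free flow), endothelial shell and interstitium. `kappa = 0` marks
#' a region as impermeable solid (treated as no-slip). The Forchheimer
#' friction factor is derived from porosity via [friction_factor()].
#'
#' @param rho fluid density, kg/m^3 (default 1000, culture medium).
#' @param mu fluid dynamic viscosity, Pa s (default 1.002e-3).
#' @param eps_endo,eps_inter porosities (default 0.265 for both the
#'   endothelial monolayer and the fibrin interstitium).
#' @param kappa_endo endothelial Darcy permeability, m^2 (default: converted
#'   from the control diffusive permeability 5e-8 m/s).
#' @param kappa_inter interstitial (fibrin) permeability, m^2
#'   (default 1.2e-7; configurable).
#' @param mu_endo effective viscosity inside the endothelial layer, Pa s
#'   (default 3e-3).
#' @return a `material_props` list with a per-region table.
#' @export
material_props <- function(rho = 1000, mu = 1.002e-3,
                           eps_endo = 0.265, eps_inter = 0.265,
                           kappa_endo = as.numeric(
                             hydraulic_from_diffusive(5e-8)),
                           kappa_inter = 1.2e-7,
                           mu_endo = 3e-3) {
  stopifnot(rho > 0, mu > 0, eps_endo > 0, eps_endo <= 1,
            eps_inter > 0, eps_inter <= 1,
            kappa_endo >= 0, kappa_inter >= 0)
  regions <- data.frame(
    label = c(LUMEN, ENDOTHELIUM, INTERSTITIUM),
    name = c("lumen", "endothelium", "interstitium"),
    eps = c(1, eps_endo, eps_inter),
    kappa = c(NA, kappa_endo, kappa_inter),
    mu = c(mu, mu_endo, mu),
    stringsAsFactors = FALSE)
  regions$Cf <- friction_factor(regions$eps)
  structure(list(rho = rho, mu = mu, regions = regions),
            class = "material_props")
}

#' Pressure boundary conditions on tagged block faces
#'
#' @param pressures named numeric vector mapping boundary tags (as used in
#'   `face_tags` of [build_label_field()]) to pressures in Pa. All untagged
#'   boundaries are no-slip walls.
#' @export
boundary_conditions <- function(pressures) {
  pressures <- unlist(pressures)
  if (!length(pressures)) stop("at least one pressure boundary is required")
  if (any(!is.finite(pressures))) stop("pressures must be finite")
  if (is.null(names(pressures)) || any(!nzchar(names(pressures))))
    stop("pressures must be a named vector of tag = Pa")
  structure(list(pressures = pressures), class = "boundary_conditions")
}

#' Study scenario parameter sets
#'
#' Returns the material properties and boundary pressures of the two device
#' conditions: `"control"` (vessel inlet 3.15 Pa, interstitial inlet
#' 1.75 Pa, endothelial diffusive permeability 5e-8 m/s) and `"il1b"`
#' (cytokine-treated: vessel inlet 0.35 Pa, interstitial inlet 0.075 Pa,
#' diffusive permeability 50e-8 m/s, i.e. a tenfold increase). Outlets are
#' 0 Pa in both.
#'
#' @param scenario `"control"` or `"il1b"`.
#' @export
scenario_parameters <- function(scenario = c("control", "il1b")) {
  scenario <- match.arg(scenario)
  Pd <- if (scenario == "control") 5e-8 else 50e-8
  props <- material_props(kappa_endo = as.numeric(hydraulic_from_diffusive(Pd)))
  p <- if (scenario == "control")
    c(vessel_inlet = 3.15, interstitial_inlet = 1.75,
      vessel_outlet = 0, interstitial_outlet = 0)
  else
    c(vessel_inlet = 0.35, interstitial_inlet = 0.075,
      vessel_outlet = 0, interstitial_outlet = 0)
  list(scenario = scenario, Pd = Pd, props = props,
       bcs = boundary_conditions(p))
}

#' Lumped finite-reservoir pressure decay
#'
#' The two media reservoirs of the device are modeled as communicating
#' columns of well area `A`; the head difference decays exponentially with
#' the device hydraulic conductance `G` (volumetric flow per unit pressure,
#' m^3 s^-1 Pa^-1): `dp(t) = dp0 * exp(-2 G rho g t / A)`. Used to compare
#' scenarios a fixed time after applying a media-height differential, when
#' flow is observed: a leakier (higher-conductance) device has equilibrated
#' further and so is driven by a smaller residual pressure.
#'
#' @param G device conductance, m^3 s^-1 Pa^-1.
#' @param t time after applying the differential, s.
#' @param dp0 initial pressure differential, Pa (default: 4 mm of medium,
#'   `1000 * 9.81 * 0.004`).
#' @param well_area reservoir cross-section, m^2.
#' @param rho,gravity fluid density and gravitational acceleration.
#' @return the residual pressure differential at time `t`, Pa.
#' @export
reservoir_pressure <- function(G, t, dp0 = 1000 * 9.81 * 0.004,
                               well_area = 2e-5, rho = 1000, gravity = 9.81) {
  stopifnot(G >= 0, t >= 0, well_area > 0)
  dp0 * exp(-2 * G * rho * gravity * t / well_area)
}
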