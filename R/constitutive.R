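# Constitutive flux laws.
#
# Unit system used throughout the package (fixed, see vignette):
#   volume µL, flow µL/min, pressure mmHg, concentration mmol/L (== µmol/mL
#   /1000; note 1 mmol/L = 1e-3 µmol/µL), time min, temperature K.
# A concentration C [mmol/L] times a flow Q [µL/min] gives a molar flux of
# C * Q / 1000 µmol/min; the helper `.molar_flux()` keeps that conversion in
# one place.

#' Physical constants of the model
#'
#' Bundles the gas constant, absolute temperature, and the carbonic-acid
#' dissociation constants used by the bicarbonate relation.
#'
#' @param gas_constant Gas constant in L·mmHg·mmol^-1·K^-1 (i.e. the molar
#'   gas constant 62.3637 L·mmHg·mol^-1·K^-1 divided by 1000 so that it
#'   multiplies mmol/L concentrations directly into mmHg).
#' @param temperature Absolute temperature in K; default body temperature.
#' @param pKa_carbonic Log acidity constant of carbonic acid.
#' @param Kh_co2 Henry's-law solubility of CO2 in blood, mmol·L^-1·mmHg^-1.
#' @return An object of class `csf_constants`.
#' @export
csf_constants <- function(gas_constant = 62.3637e-3,
                          temperature = 310.15,
                          pKa_carbonic = 6.1,
                          Kh_co2 = 0.03) {
  stopifnot(gas_constant > 0, temperature > 0)
  structure(
    list(gas_constant = gas_constant, temperature = temperature,
         pKa_carbonic = pKa_carbonic, Kh_co2 = Kh_co2),
    class = "csf_constants"
  )
}

#' Hagen-Poiseuille hydraulic resistance of a cylindrical vessel
#'
#' Computes the equivalent hydrodynamic resistance alpha such that
#' `Q = dP / alpha`, from `alpha = 8 mu L / (pi R^4)` converted into model
#' units (mmHg·min·µL^-1).
#'
#' @param radius_R Lumen radius, µm.
#' @param length_L Vessel length, mm.
#' @param viscosity_mu Dynamic viscosity, mPa·s (1 mPa·s = 1 cP).
#' @return Resistance in mmHg·min·µL^-1.
#' @examples
#' poiseuille_resistance(radius_R = 100, length_L = 10, viscosity_mu = 0.7)
#' @export
poiseuille_resistance <- function(radius_R, length_L, viscosity_mu) {
  if (any(radius_R <= 0) || any(length_L <= 0) || any(viscosity_mu <= 0)) {
    stop("poiseuille_resistance(): radius, length and viscosity must be positive")
  }
  # SI: alpha_SI = 8 mu L / (pi R^4)  [Pa s m^-3]
  # mu [mPa s] = 1e-3 Pa s; L [mm] = 1e-3 m; R [um] = 1e-6 m
  alpha_si <- 8 * (viscosity_mu * 1e-3) * (length_L * 1e-3) /
    (pi * (radius_R * 1e-6)^4)
  # convert Pa s / m^3 -> mmHg min / uL:
  #   1 Pa = 1/133.322 mmHg; 1 s = 1/60 min; 1 m^-3 = 1e-9 uL^-1
  alpha_si / 133.322 / 60 * 1e-9
}

#' Luminal (pressure-driven) flow through a resistance
#'
#' @param dP Hydrostatic pressure drop along the arc, mmHg (signed).
#' @param resistance_alpha Hydraulic resistance, mmHg·min·µL^-1.
#' @return Flow in µL/min, positive in the direction of positive `dP`.
#' @export
luminal_flow <- function(dP, resistance_alpha) {
  if (any(resistance_alpha <= 0)) {
    stop("luminal_flow(): resistance must be positive")
  }
  dP / resistance_alpha
}

#' Osmolarity of a solution
#'
#' Sums per-species contributions `phi * n * C`, where `phi` is the osmotic
#' coefficient and `n` the number of particles the molecule dissociates into.
#'
#' @param concentrations Named numeric vector, mmol/L per species.
#' @param species Species table as returned by [csf_species()]; only the
#'   `dissociation_n` and `osmotic_coeff_phi` columns are used.  Species
#'   missing from the table default to `n = 1`, `phi = 1`.
#' @return Osmolarity in mOsm (mosmol/L).
#' @export
osmolarity <- function(concentrations, species = NULL) {
  if (any(concentrations < 0)) stop("osmolarity(): negative concentration")
  if (length(concentrations) == 0) return(0)
  n <- rep(1, length(concentrations))
  phi <- rep(1, length(concentrations))
  if (!is.null(species)) {
    idx <- match(names(concentrations), species$name)
    ok <- !is.na(idx)
    n[ok] <- species$dissociation_n[idx[ok]]
    phi[ok] <- species$osmotic_coeff_phi[idx[ok]]
  }
  sum(phi * n * concentrations)
}

#' van't Hoff osmotic pressure
#'
#' @param osm Osmolarity, mOsm.
#' @param constants A [csf_constants()] object.
#' @return Osmotic pressure in mmHg (about 19.34 mmHg per mOsm at 310.15 K).
#' @export
osmotic_pressure <- function(osm, constants = csf_constants()) {
  constants$gas_constant * constants$temperature * osm
}

#' Transmembrane water flux by the amended Starling law
#'
#' `J = LpA * (dP - sum_i sigma_i * dPi_i)`, where the osmotic sum runs over
#' every species (proteins, ions, glucose, impermeant osmolytes), not only
#' colloids.  One-way arcs (the arachnoid granulations) are clamped at zero
#' for reversed gradients.
#'
#' @param LpA Hydraulic conductivity times membrane area, µL·min^-1·mmHg^-1.
#' @param dP Hydrostatic pressure difference (from-side minus to-side), mmHg.
#' @param dPi_by_species Named numeric vector of per-species osmotic pressure
#'   differences (from-side minus to-side), mmHg.
#' @param sigma_by_species Named numeric vector of reflection coefficients in
#'   `[0, 1]`; names must cover `names(dPi_by_species)`.
#' @param one_way If `TRUE` the flux is clamped at `max(J, 0)`.
#' @return Water flux in µL/min, positive from -> to.
#' @export
starling_flux <- function(LpA, dP, dPi_by_species = numeric(),
                          sigma_by_species = numeric(), one_way = FALSE) {
  if (LpA < 0) stop("starling_flux(): LpA must be >= 0")
  sig <- .match_sigma(sigma_by_species, names(dPi_by_species))
  if (any(sig < 0 | sig > 1)) {
    stop("starling_flux(): reflection coefficients must lie in [0, 1]")
  }
  J <- LpA * (dP - sum(sig * dPi_by_species))
  if (one_way) J <- max(J, 0)
  J
}

.match_sigma <- function(sigma_by_species, species_names) {
  if (length(species_names) == 0) return(numeric())
  sig <- rep(1, length(species_names))
  if (length(sigma_by_species)) {
    idx <- match(species_names, names(sigma_by_species))
    ok <- !is.na(idx)
    sig[ok] <- sigma_by_species[idx[ok]]
  }
  sig
}

#' Darcy flow through a porous interface
#'
#' `Q = k * A * dP / (mu * L)` in model units.  `permeability_k` is taken in
#' darcy (1 darcy = 9.869233e-13 m^2).
#'
#' @param permeability_k Permeability of the medium, darcy.
#' @param area_A Cross-sectional area of the interface, cm^2.
#' @param dP Pressure difference across the medium, mmHg (signed).
#' @param viscosity_mu Fluid viscosity, mPa·s.
#' @param path_length_L Hydraulic path length, mm.
#' @return Flow in µL/min, positive along positive `dP`.
#' @export
darcy_flow <- function(permeability_k, area_A, dP, viscosity_mu, path_length_L) {
  if (any(permeability_k <= 0) || any(area_A <= 0) ||
      any(viscosity_mu <= 0) || any(path_length_L <= 0)) {
    stop("darcy_flow(): permeability, area, viscosity and length must be positive")
  }
  dP / darcy_resistance(permeability_k, area_A, viscosity_mu, path_length_L)
}

#' Equivalent hydraulic resistance of a Darcy interface
#'
#' `alpha = mu * L / (k * A)` converted to mmHg·min·µL^-1, so that
#' `darcy_flow()` equals `luminal_flow(dP, darcy_resistance(...))`.
#'
#' @inheritParams darcy_flow
#' @return Resistance in mmHg·min·µL^-1.
#' @export
darcy_resistance <- function(permeability_k, area_A, viscosity_mu, path_length_L) {
  # SI: alpha = mu L / (k A) [Pa s m^-3]
  k_si <- permeability_k * 9.869233e-13          # m^2
  alpha_si <- (viscosity_mu * 1e-3) * (path_length_L * 1e-3) /
    (k_si * (area_A * 1e-4))
  alpha_si / 133.322 / 60 * 1e-9
}

#' Bicarbonate concentration from blood gas measurements
#'
#' Inverts the Henderson-Hasselbalch relation:
#' `C_HCO3 = Kh * pCO2 * 10^(pH - pKa)`.
#'
#' @param pH Blood pH.
#' @param pCO2 CO2 partial pressure, mmHg.
#' @param constants A [csf_constants()] object supplying `pKa_carbonic` and
#'   `Kh_co2`.
#' @return Bicarbonate concentration in mmol/L.
#' @examples
#' bicarbonate_from_gas(7.4, 40)  # about 24 mmol/L
#' @export
bicarbonate_from_gas <- function(pH, pCO2, constants = csf_constants()) {
  if (any(pCO2 <= 0)) stop("bicarbonate_from_gas(): pCO2 must be positive")
  constants$Kh_co2 * pCO2 * 10^(pH - constants$pKa_carbonic)
}

#' Metabolic water production rate
#'
#' Either stoichiometric (oxidation of glucose in the parenchyma, first-order
#' destruction with rate `k_gluc`, producing `nu` µL of water per µmol of
#' glucose consumed) or a direct constant override.
#'
#' @param C_gluc_ECS Glucose concentration at the extracellular-space node,
#'   mmol/L.
#' @param V_ECS Extracellular-space volume, µL.
#' @param params List with fields `k_gluc` (1/min), `nu_water_per_glucose`
#'   (µL/µmol) and optionally `direct_G_override` (µL/min); see
#'   [metabolic_params()].
#' @return Water production rate G in µL/min.
#' @export
metabolic_water_rate <- function(C_gluc_ECS, V_ECS, params) {
  if (!is.null(params$direct_G_override) && !is.na(params$direct_G_override)) {
    if (params$k_gluc > 0) {
      stop("metabolic_water_rate(): configure either the stoichiometric mode ",
           "(k_gluc > 0) or direct_G_override, not both")
    }
    return(params$direct_G_override)
  }
  if (C_gluc_ECS < 0 || V_ECS < 0) stop("metabolic_water_rate(): negative input")
  # destruction rate k*C*V is in (1/min)*(mmol/L)*(uL) = nmol/min -> umol/min
  params$nu_water_per_glucose * params$k_gluc * C_gluc_ECS * V_ECS / 1000
}

#' Metabolic parameters
#'
#' @param k_gluc First-order glucose destruction constant in the parenchyma,
#'   1/min.
#' @param nu_water_per_glucose Water yield, µL per µmol glucose; the default
#'   is the oxidation stoichiometry 6 H2O per glucose at 18.015 µL/mmol,
#'   i.e. 6 * 18.015 / 1000 µL/µmol.
#' @param direct_G_override If not `NA`, a constant water production rate in
#'   µL/min that bypasses the stoichiometric mode.
#' @return A list of class `csf_metabolic`.
#' @export
metabolic_params <- function(k_gluc = 0, nu_water_per_glucose = 0.108090,
                             direct_G_override = NA_real_) {
  stopifnot(k_gluc >= 0, nu_water_per_glucose >= 0)
  structure(list(k_gluc = k_gluc,
                 nu_water_per_glucose = nu_water_per_glucose,
                 direct_G_override = direct_G_override),
            class = "csf_metabolic")
}

#' Convective (solvent-drag) molar flux of a solute across a membrane
#'
#' `flux = (1 - sigma) * J * C_donor / 1000`, with the donor compartment
#' chosen by the sign of the water flux (upwind rule).  The division by 1000
#' converts mmol/L * µL/min into µmol/min.
#'
#' @param J Water flux along the arc, µL/min (signed, positive from -> to).
#' @param sigma Reflection coefficient of the solute on this arc.
#' @param C_from,C_to Solute concentration in the upstream ("from") and
#'   downstream ("to") compartments, mmol/L.
#' @return Molar flux in µmol/min, positive from -> to.
#' @export
solvent_drag_molar_flux <- function(J, sigma, C_from, C_to = 0) {
  if (sigma < 0 || sigma > 1) {
    stop("solvent_drag_molar_flux(): sigma must lie in [0, 1]")
  }
  C_donor <- if (J >= 0) C_from else C_to
  (1 - sigma) * J * C_donor / 1000
}
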