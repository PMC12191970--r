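#' Physical constants
#'
#' Returns the fixed physical constants used throughout the simulator.
#' Currently only the universal gas constant.
#'
#' @return A list with element `R`, the universal gas constant in
#'   J mol^-1 K^-1 (8.314462618).
#' @export
#' @examples
#' physicalConstants()$R
physicalConstants <- function() {
  list(R = 8.314462618)
}

## Lowest temperature (K) at which the Murphy-Koop ice vapor-pressure
## correlation is considered valid.
.T_VALID_MIN <- 110

#' Material and transport properties of the frozen matrix
#'
#' Bundles the physical parameters of the frozen trehalose solution and the
#' dried porous cake. Thermal properties default to pure ice, the working
#' simplification for a dilute (100 mg/mL trehalose) solution whose frozen
#' phase is almost entirely ice; the model compares drying rates between
#' vessel orientations rather than reproducing a particular formulation.
#'
#' @param rho_ice Density of ice, kg m^-3.
#' @param epsilon0 Initial porosity: volume fraction of the frozen matrix
#'   occupied by sublimable ice, in (0, 1]. Default 0.97 corresponds to
#'   ~3\% v/v solids of a 100 mg/mL trehalose solution.
#' @param Sv Specific surface area of sublimating ice, m^2 m^-3. Used by the
#'   closed-form volumetric rate; the voxel solver resolves the front
#'   interface area geometrically instead.
#' @param alpha Evaporation (accommodation) coefficient, dimensionless in
#'   (0, 1]. The model's single calibrated parameter; see
#'   [calibrateAlpha()]. The default is the value calibrated against the
#'   tilted-vessel drying time (see the methods vignette).
#' @param Mv Molar mass of water vapor, kg mol^-1.
#' @param dHs Heat of sublimation of ice, J kg^-1.
#' @param k_thermal Thermal conductivity, W m^-1 K^-1 (pure ice).
#' @param cp Specific heat capacity, J kg^-1 K^-1 (pure ice).
#' @param kappa_dried Permeability of the dried porous layer, m^2. Default
#'   1e-8 m^2 follows a Kozeny-Carman estimate for the ultra-open cake left
#'   by a 97\%-porosity frozen matrix with ice-templated pores of order
#'   50 um, and yields centimetre-scale cake resistances at the low end of
#'   the range reported for dilute amorphous formulations.
#' @param mu_vapor Dynamic viscosity of water vapor, Pa s (~230-260 K).
#' @param h_exposed Heat-exchange coefficient of the vacuum-exposed cake
#'   surface with the chamber environment, W m^-2 K^-1: radiative exchange
#'   with near-ambient chamber walls (~5-7 for high-emissivity surfaces at
#'   near-unity view factor) plus free-molecular gas conduction at 5 Pa.
#'   This is the dominant heat path during primary drying on a
#'   maximum-cooled shelf.
#' @param h_shelf Contact heat-exchange coefficient between vessel wall and
#'   shelf, W m^-2 K^-1, applied over the resolved shelf-contact faces. A
#'   polypropylene tube base couples more weakly than the glass-vial values
#'   (~20-65) used in vial lyophilization models.
#' @param T_ambient Chamber/ambient wall temperature, K.
#'
#' @return An object of class `materialProperties` (a validated list).
#' @export
#' @examples
#' props <- materialProperties()
#' props$rho_ice
materialProperties <- function(rho_ice = 917,
                               epsilon0 = 0.97,
                               Sv = 1e4,
                               alpha = 4.86968e-3,
                               Mv = 0.018015,
                               dHs = 2.838e6,
                               k_thermal = 2.2,
                               cp = 2050,
                               kappa_dried = 1e-8,
                               mu_vapor = 8e-6,
                               h_exposed = 12,
                               h_shelf = 13,
                               T_ambient = 293.15) {
  props <- list(rho_ice = rho_ice, epsilon0 = epsilon0, Sv = Sv,
                alpha = alpha, Mv = Mv, dHs = dHs,
                k_thermal = k_thermal, cp = cp,
                kappa_dried = kappa_dried, mu_vapor = mu_vapor,
                h_exposed = h_exposed, h_shelf = h_shelf,
                T_ambient = T_ambient)
  for (nm in names(props)) {
    v <- props[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("materialProperties: '", nm, "' must be a finite numeric scalar")
  }
  strict_pos <- setdiff(names(props), c("h_exposed", "h_shelf"))
  for (nm in strict_pos)
    if (props[[nm]] <= 0)
      stop("materialProperties: '", nm, "' must be strictly positive")
  if (props$h_exposed < 0 || props$h_shelf < 0)
    stop("materialProperties: heat-exchange coefficients must be >= 0")
  if (epsilon0 > 1) stop("materialProperties: 'epsilon0' must be <= 1")
  if (alpha > 1) stop("materialProperties: 'alpha' must be <= 1")
  class(props) <- "materialProperties"
  props
}

#' @export
print.materialProperties <- function(x, ...) {
  cat("Material properties (SI units):\n")
  for (nm in names(x)) cat(sprintf("  %-12s %g\n", nm, x[[nm]]))
  invisible(x)
}

.checkTemperature <- function(T) {
  if (!is.numeric(T) || any(!is.finite(T)))
    stop("temperature must be finite numeric")
  if (any(T <= .T_VALID_MIN))
    stop("temperature below the ", .T_VALID_MIN,
         " K validity bound of the ice vapor-pressure correlation")
  invisible(TRUE)
}

#' Saturation vapor pressure over ice (Murphy-Koop correlation)
#'
#' Empirical correlation for the equilibrium vapor pressure over hexagonal
#' ice, valid for temperatures above 110 K:
#' \deqn{p_v = \exp(9.550426 - 5723.265/T + 3.53068 \ln T - 0.00728332\, T).}
#'
#' @param T Temperature, K (vectorized). Must exceed 110 K.
#' @return Saturation vapor pressure, Pa; strictly positive and strictly
#'   increasing in `T` on the valid range.
#' @export
#' @examples
#' vaporPressure(273.16)  # ~611.7 Pa, the triple point of water
vaporPressure <- function(T) {
  .checkTemperature(T)
  exp(9.550426 - 5723.265 / T + 3.53068 * log(T) - 0.00728332 * T)
}

#' Hertz-Knudsen sublimation mass flux per unit interface area
#'
#' Kinetic-theory net sublimation flux driven by the vapor-pressure deficit
#' at the ice surface, neglecting secondary mass-transfer effects:
#' \deqn{J = \alpha\,(p_v(T) - p)\sqrt{M_v/(2\pi R T)}.}
#' When the ambient pressure exceeds saturation the flux is clamped to zero
#' (no re-deposition is modeled): primary drying at 5 Pa chamber pressure
#' never approaches deposition, and the clamp keeps ice content monotone.
#'
#' @param T Temperature, K (> 110 K). Vectorized with `p`.
#' @param p Ambient (local vapor) pressure, Pa; must be >= 0.
#' @param props A [materialProperties()] object.
#' @param consts [physicalConstants()].
#' @return Mass flux per unit interface area, kg m^-2 s^-1; >= 0.
#' @export
#' @examples
#' arealSublimationFlux(253.15, 5, materialProperties(alpha = 1))
arealSublimationFlux <- function(T, p, props = materialProperties(),
                                 consts = physicalConstants()) {
  .checkTemperature(T)
  if (!is.numeric(p) || any(!is.finite(p)) || any(p < 0))
    stop("ambient pressure must be finite and >= 0")
  pv <- vaporPressure(T)
  pmax(0, props$alpha * (pv - p) * sqrt(props$Mv / (2 * pi * consts$R * T)))
}

#' Volumetric sublimation rate
#'
#' Mass sink per unit volume and time: the areal Hertz-Knudsen flux scaled
#' by the specific surface area of sublimating ice,
#' \eqn{\dot m = S_v\, J(T, p)}.
#'
#' @inheritParams arealSublimationFlux
#' @return Volumetric sublimation rate, kg m^-3 s^-1; >= 0.
#' @export
volumetricSublimationRate <- function(T, p, props = materialProperties(),
                                      consts = physicalConstants()) {
  if (props$Sv <= 0) stop("Sv must be strictly positive")
  props$Sv * arealSublimationFlux(T, p, props, consts)
}

#' Rate of change of normalized remaining ice content
#'
#' \deqn{ds/dt = -\dot m / (\rho_{ice}\,\epsilon_0).}
#'
#' @param m_dot Volumetric sublimation rate, kg m^-3 s^-1; must be >= 0.
#' @param props A [materialProperties()] object.
#' @return Rate of change of normalized ice content, s^-1; <= 0.
#' @export
iceContentRate <- function(m_dot, props = materialProperties()) {
  if (!is.numeric(m_dot) || any(!is.finite(m_dot)) || any(m_dot < 0))
    stop("m_dot must be finite and >= 0")
  -m_dot / (props$rho_ice * props$epsilon0)
}

#' Volumetric heat sink due to sublimation
#'
#' \deqn{\dot Q_{subl} = \dot m\, \Delta H_s,} interpreted as a heat sink in
#' the energy balance.
#'
#' @inheritParams iceContentRate
#' @return Volumetric heat sink, W m^-3; >= 0.
#' @export
sublimationHeatSink <- function(m_dot, props = materialProperties()) {
  if (!is.numeric(m_dot) || any(!is.finite(m_dot)) || any(m_dot < 0))
    stop("m_dot must be finite and >= 0")
  m_dot * props$dHs
}
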