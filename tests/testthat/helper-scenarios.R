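## Small, fast-drying scenario used by solver conservation tests: a short
## upright tube with strong surface heating so primary drying completes in
## a fraction of the window.
fastScenario <- function(tilt = 90, alpha = 0.5, h_exposed = 50,
                         r = 0.005, L = 0.02, fill = 0.2e-6) {
  vesselScenario(
    vesselGeometry(r, L, tilt, fill),
    schedule = sbrSchedule(),
    props = materialProperties(alpha = alpha, h_exposed = h_exposed),
    T_init = 233.15,
    label = "fast-test")
}

## Kinetics-limited setup with pinned front temperature: huge surface
## exchange and thermal conductivity, negligible Darcy resistance. The
## drying time has the closed form L * rho_ice * eps0 / J with
## J = alpha * (pv(T) - p) * sqrt(Mv / (2 pi R T)).
pinnedScenario <- function(alpha, tilt = 90, T_pin = 250) {
  sc <- sbrScenarios(props = materialProperties(
    alpha = alpha, h_exposed = 1e6, h_shelf = 0, k_thermal = 1e5,
    kappa_dried = 1, T_ambient = T_pin))[[
      if (tilt == 90) "upright" else "tilted"]]
  sc
}

closedFormDryingTime_h <- function(scenario, T_pin = 250) {
  props <- scenario$props
  A <- exposedSurfaceArea(scenario$geometry)
  L <- scenario$geometry$fill_volume / A
  J <- arealSublimationFlux(T_pin, 5, props)
  L * props$rho_ice * props$epsilon0 / J / 3600
}
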