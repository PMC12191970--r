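## Coupled pressure / ice / heat stepping and the reduced 1-D front model.

test_that("initial state: unit average ice, fractional boundary cells", {
  v <- vesselGeometry(0.0145, 0.115, 22, 16e-6)
  mesh <- voxelize(v, 2.5e-3)
  st <- initialState(mesh, materialProperties(), 233.15, 5)
  expect_equal(averageIce(st), 1)
  expect_true(all(st$s >= 0 & st$s <= 1))
  expect_identical(st$s, mesh$solid_frac)
  expect_true(any(st$s < 1))            # rim cells carry partial ice
  expect_equal(st$ledger_mass, 0)
  expect_equal(st$initial_ice_mass,
               917 * 0.97 * meshFrozenVolume(mesh), tolerance = 1e-12)
  expect_error(initialState(mesh, materialProperties(), 100), "validity")
})

test_that("pressure solve: no sources gives uniform chamber pressure", {
  v <- vesselGeometry(0.0145, 0.115, 90, 16e-6)
  mesh <- voxelize(v, 2.5e-3)
  props <- materialProperties()
  st <- initialState(mesh, props, 233.15, 5)
  st$s[] <- 0                           # fully dried: no sublimation sources
  p <- darcyPressureSolve(st, mesh, props, 5)
  expect_equal(as.numeric(p), rep(5, length(st$s)), tolerance = 1e-9)
  expect_equal(nrow(attr(p, "front")), 0L)
})

test_that("pressure solve: 1-D column matches the series-resistance closed form", {
  ## small fluxes: compressibility negligible, linear pressure profile
  v <- vesselGeometry(0.0145, 0.115, 90, 16e-6)
  mesh <- voxelize(v, 2e-3)
  props <- materialProperties(alpha = 1e-6)
  consts <- physicalConstants()
  st <- initialState(mesh, props, 250, 5)
  z <- mesh$solid_centers[, 3]
  z_front <- max(z) - 4.5 * mesh$cell_size   # dry the top 4 layers
  st$s[z > z_front] <- 0
  p <- darcyPressureSolve(st, mesh, props, 5)
  front <- attr(p, "front")
  expect_gt(sum(front$flux), 0)
  ## closed form: the same total flux crosses every dried layer, dropping
  ## Q / (ncol * Gcell) per layer with the ideal-gas face transmissibility
  rho <- 5 * props$Mv / (consts$R * 250)
  Gcell <- rho * props$kappa_dried / props$mu_vapor * mesh$cell_size
  Q <- sum(front$flux)
  lay_of <- floor(round(z / mesh$cell_size, 6))
  open <- st$s == 0
  lays <- sort(unique(lay_of[open]))
  p_lay <- vapply(lays, function(l) mean(p[open & lay_of == l]), numeric(1))
  ncol_cells <- sum(open & lay_of == lays[1])
  dp_pred <- Q / (ncol_cells * Gcell)
  dp_obs <- -diff(p_lay)                # bottom (front) to top (surface)
  expect_equal(mean(dp_obs), dp_pred, tolerance = 0.01)
  ## linear profile across the dried layers (endpoint interpolation)
  n_l <- length(p_lay)
  p_lin <- p_lay[1] + (p_lay[n_l] - p_lay[1]) *
    (lays - lays[1]) / (lays[n_l] - lays[1])
  expect_lt(max(abs(p_lay - p_lin)) / (p_lay[1] - p_lay[n_l]), 0.01)
  ## doubling the permeability halves the front-to-surface pressure drop
  props2 <- materialProperties(alpha = 1e-6, kappa_dried = 2 * props$kappa_dried)
  p2 <- darcyPressureSolve(st, mesh, props2, 5)
  expect_equal(max(p2[open]) - 5, (max(p[open]) - 5) / 2, tolerance = 0.02)
})

test_that("interior frozen cells sit at saturation; network pressure above chamber", {
  v <- vesselGeometry(0.0145, 0.115, 90, 16e-6)
  mesh <- voxelize(v, 2.5e-3)
  props <- materialProperties()
  st <- initialState(mesh, props, 250, 5)
  z <- mesh$solid_centers[, 3]
  st$s[z > max(z) - 3 * mesh$cell_size] <- 0
  p <- darcyPressureSolve(st, mesh, props, 5)
  interior <- st$s > 0 & z < max(z) - 5 * mesh$cell_size
  expect_equal(as.numeric(p[interior]),
               rep(vaporPressure(250), sum(interior)), tolerance = 1e-9)
  expect_true(all(p >= 5 - 1e-9))
})

test_that("heat step: steady state, uniform sink cooling, linear slab profile", {
  v <- vesselGeometry(0.0145, 0.115, 90, 16e-6)
  mesh <- voxelize(v, 2.5e-3)
  ## boundary at the initial temperature: field unchanged
  props <- materialProperties(T_ambient = 240, h_shelf = 20)
  st <- initialState(mesh, props, 240, 5)
  st2 <- heatStep(st, mesh, props, shelf_T = 240, dt = 100)
  expect_equal(st2$T, st$T, tolerance = 1e-12)
  ## no boundary coupling, uniform sink: uniform cooling at Q/(rho cp)
  propsA <- materialProperties(h_exposed = 0, h_shelf = 0)
  stA <- initialState(mesh, propsA, 240, 5)
  q_J <- 0.01  # J per cell over the step
  stA$sink_J <- rep(q_J, length(stA$s))
  stA2 <- heatStep(stA, mesh, propsA, shelf_T = 218, dt = 50)
  dT_pred <- -q_J / (propsA$rho_ice * propsA$cp * mesh$cell_volume)
  expect_equal(stA2$T - stA$T, rep(dT_pred, length(stA$T)), tolerance = 1e-9)
  ## 1-D slab with pinned face temperatures: after long integration the
  ## profile is the analytic steady linear ramp between the faces
  N <- 24L; dz <- 1e-3
  chain <- list(cell_size = dz, cell_volume = dz^3,
                solid_cells = seq_len(N), solid_frac = rep(1, N),
                int_faces = cbind(a = 1:(N - 1), b = 2:N),
                exposed_faces = list(cell = N, weight = 1,
                                     center = matrix(0, 1, 3)),
                shelf_contact_faces = list(cell = 1L, scale = 1))
  propsB <- materialProperties(h_exposed = 1e7, h_shelf = 1e7,
                               T_ambient = 260)
  stB <- initialState(chain, propsB, 250, 5)
  for (i in 1:200) stB <- heatStep(stB, chain, propsB, shelf_T = 240,
                                   dt = 5000)
  z_ctr <- (seq_len(N) - 0.5) * dz
  T_pred <- 240 + (260 - 240) * z_ctr / (N * dz)
  expect_lt(max(abs(stB$T - T_pred)) / 20, 0.005)
})

test_that("heat step aborts when temperature leaves the validity range", {
  v <- vesselGeometry(0.0145, 0.115, 90, 16e-6)
  mesh <- voxelize(v, 2.5e-3)
  props <- materialProperties(T_ambient = 111)
  st <- initialState(mesh, props, 112, 5)
  st$sink_J <- rep(1e3, length(st$s))    # monstrous sink
  expect_error(heatStep(st, mesh, props, shelf_T = 111, dt = 300),
               "validity")
})

test_that("ice step: equilibrium no-op, constant-rate depletion, flooring and ledger", {
  ## synthetic single-cell front table driven at constant flux
  mesh <- list(cell_volume = 1e-9)
  props <- materialProperties()
  cap_mass <- props$rho_ice * props$epsilon0 * mesh$cell_volume
  st <- list(s = 1, s0 = 1, sink_J = 0, ledger_mass = 0, ledger_heat = 0,
             front = data.frame(cell = 1L, area = 1e-6, flux = 0,
                                p_local = 5))
  st0 <- iceStep(st, mesh, props, 100)
  expect_equal(st0$s, 1)                 # zero flux: unchanged
  flux <- 2e-10                          # kg/s
  st$front$flux <- flux
  t_star <- cap_mass / flux              # closed-form depletion time
  dt <- 50
  n <- 0
  while (st$s > 0 && n < 1e5) { st <- iceStep(st, mesh, props, dt); n <- n + 1 }
  expect_lt(abs(n * dt - t_star), dt + 1e-9)
  ## flooring: ledger holds exactly the initial ice mass, heat = dHs * mass
  expect_equal(st$ledger_mass, cap_mass, tolerance = 1e-12)
  expect_equal(st$ledger_heat, props$dHs * st$ledger_mass, tolerance = 1e-12)
  expect_error(iceStep(st, mesh, props, -1), "positive")
})

test_that("full run conserves mass and energy and keeps ice monotone", {
  res <- runScenario(fastScenario(), cell_size = 1e-3, output_interval = 0.1)
  expect_false(is.na(res$zero_ice_time))
  expect_equal(res$avg_ice[1], 1)
  expect_true(all(diff(res$avg_ice) <= 1e-12))
  expect_true(all(res$avg_ice >= 0 & res$avg_ice <= 1))
  expect_lt(res$mass_balance_error, 1e-3)
  expect_equal(res$energy_ledger$sublimation_heat_J,
               res$energy_ledger$sublimated_mass_kg *
                 materialProperties()$dHs, tolerance = 1e-12)
  ## after full depletion all cells are empty
  expect_true(all(res$final_state$s == 0))
})

test_that("vanishing evaporation coefficient leaves the ice untouched", {
  sc <- fastScenario(alpha = 1e-12)
  res <- runScenario(sc, cell_size = 1e-3)
  expect_true(is.na(res$zero_ice_time))
  expect_gt(res$final_avg_ice, 1 - 1e-6)
})

test_that("run is deterministic for fixed inputs", {
  r1 <- runScenario(fastScenario(), cell_size = 1.2e-3)
  r2 <- runScenario(fastScenario(), cell_size = 1.2e-3)
  expect_identical(r1$zero_ice_time, r2$zero_ice_time)
  expect_identical(r1$avg_ice, r2$avg_ice)
})

test_that("1-D front model: kinetics-limited closed form and area scaling", {
  sc <- pinnedScenario(alpha = 0.01)
  res <- movingFront1d(sc, dt = 10)
  expect_equal(res$zero_ice_time, closedFormDryingTime_h(sc),
               tolerance = 0.01)
  expect_lt(res$mass_balance_error, 1e-3)
  ## drying time scales inversely with the exposed area at fixed fill
  sct <- pinnedScenario(alpha = 0.01, tilt = 22)
  rest <- movingFront1d(sct, dt = 10)
  A_ratio <- exposedSurfaceArea(sct$geometry) /
    exposedSurfaceArea(sc$geometry)
  expect_equal(res$zero_ice_time / rest$zero_ice_time, A_ratio,
               tolerance = 0.02)
})
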