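## Coupled primary-drying solver on the voxel mesh.
##
## Operator-split step: (1) boundary conditions from the schedule,
## (2) quasi-steady Darcy vapor pressure in the dried (open) cell network
## with the Hertz-Knudsen front flux coupled implicitly as a linear
## exchange term, (3) explicit per-cell ice depletion with a per-step cap,
## (4) implicit heat conduction with the sublimation heat sink.
##
## The dried network carries vapor by Darcy's law; face transmissibilities
## use ideal-gas density lagged from the previous pressure iterate. The
## sublimation front is sharp: frozen cells adjacent to open cells (or to
## the chamber through exposed faces) sublime with the areal Hertz-Knudsen
## flux over the resolved interface area, which makes the front speed
## independent of the cell size.

.S_OPEN_EPS <- 1e-12   # s below this counts as fully dried (open to vapor)

#' Initial simulation state
#'
#' Per-cell normalized ice content set to the frozen volume fraction of each
#' cell (1 in interior cells), uniform temperature, vapor pressure equal to
#' the chamber pressure, ledgers zeroed.
#'
#' @param mesh A [voxelize()] mesh.
#' @param props A [materialProperties()].
#' @param T_init Initial temperature of the frozen mass, K (> 110).
#' @param p_chamber Chamber pressure, Pa.
#' @return An object of class `simulationState`.
#' @export
initialState <- function(mesh, props, T_init = 233.15, p_chamber = 5) {
  .checkTemperature(T_init)
  n <- length(mesh$solid_cells)
  st <- list(t = 0,
             s = mesh$solid_frac,
             s0 = mesh$solid_frac,
             T = rep(T_init, n),
             p = rep(p_chamber, n),
             sink_J = numeric(n),
             ledger_mass = 0,
             ledger_heat = 0,
             initial_ice_mass = props$rho_ice * props$epsilon0 *
               sum(mesh$solid_frac) * mesh$cell_volume,
             front = NULL)
  class(st) <- "simulationState"
  st
}

#' @export
print.simulationState <- function(x, ...) {
  cat(sprintf(paste0("Simulation state at t = %.2f h: avg ice %.4f, ",
                     "T range [%.1f, %.1f] K, sublimated %.3g kg\n"),
              x$t, averageIce(x), min(x$T), max(x$T), x$ledger_mass))
  invisible(x)
}

#' Average normalized remaining ice content of a state
#'
#' Volume-weighted mean of the per-cell ice content, normalized so the
#' initial state reads exactly 1.
#'
#' @param state A [initialState()] state.
#' @return Dimensionless value in \[0, 1\].
#' @export
averageIce <- function(state) sum(state$s) / sum(state$s0)

#' Quasi-steady Darcy vapor-pressure solve
#'
#' Solves the quasi-steady mass balance on the dried (open) cell network:
#' the divergence of the Darcy mass flux equals the sublimation source
#' entering each open cell from adjacent frozen faces, with Dirichlet
#' chamber pressure on exposed faces and no-flux walls. The Hertz-Knudsen
#' front flux, linear in the local pressure, is coupled implicitly; fluxes
#' that would turn negative (deposition) are clamped to zero. Frozen cells
#' not adjacent to the open network are assigned their saturation pressure
#' (vapor cannot escape, so the local pressure equilibrates); frozen front
#' cells are assigned the pressure of their open/exposed neighbor.
#'
#' @param state A `simulationState`.
#' @param mesh A [voxelize()] mesh.
#' @param props A [materialProperties()].
#' @param p_chamber Chamber pressure, Pa.
#' @return Numeric per-cell pressure field (Pa) with attribute `front`: a
#'   data frame of front faces (`cell` = frozen solid-cell index, `area` m^2,
#'   `flux` kg s^-1, `p_local` Pa).
#' @export
darcyPressureSolve <- function(state, mesh, props, p_chamber) {
  n <- length(state$s)
  consts <- physicalConstants()
  open <- state$s <= .S_OPEN_EPS
  frozen <- !open
  if (length(mesh$exposed_faces$cell) == 0L)
    stop("darcyPressureSolve: no exposed faces connect the fill to the ",
         "chamber; vapor escape is blocked for this geometry")

  dx <- mesh$cell_size
  kmu <- props$kappa_dried / props$mu_vapor
  pv <- vaporPressure(state$T)
  Ck <- props$alpha * sqrt(props$Mv / (2 * pi * consts$R * state$T))

  p_new <- ifelse(frozen, pv, p_chamber)

  fa <- mesh$int_faces[, 1]; fb <- mesh$int_faces[, 2]
  oo <- open[fa] & open[fb]
  front_int <- xor(open[fa], open[fb])
  ec <- mesh$exposed_faces$cell; ew <- mesh$exposed_faces$weight
  exp_open <- open[ec]; exp_front <- frozen[ec]

  ## front faces: frozen cell, interface area, conductance, neighbor node
  ## (0 = chamber, otherwise open-cell index)
  f_cell <- c(ifelse(open[fa[front_int]], fb[front_int], fa[front_int]),
              ec[exp_front])
  f_nb   <- c(ifelse(open[fa[front_int]], fa[front_int], fb[front_int]),
              rep(0L, sum(exp_front)))
  f_area <- c(rep(dx^2, sum(front_int)), ew[exp_front] * dx^2)
  f_k    <- f_area * Ck[f_cell]           # kg s^-1 Pa^-1
  f_pv   <- pv[f_cell]

  no <- sum(open)
  if (no > 0L) {
    oidx <- integer(n); oidx[open] <- seq_len(no)
    ## lagged ideal-gas face density
    rho <- function(p, T) p * props$Mv / (consts$R * T)
    a <- fa[oo]; b <- fb[oo]
    G_oo <- rho((state$p[a] + state$p[b]) / 2, (state$T[a] + state$T[b]) / 2) *
      kmu * dx                              # area dx^2 over distance dx
    dc <- ec[exp_open]; wc <- ew[exp_open]
    G_dir <- rho((state$p[dc] + p_chamber) / 2, state$T[dc]) *
      kmu * wc * dx^2 / (dx / 2)

    active <- rep(TRUE, length(f_cell))
    onb <- f_nb > 0L
    ii <- oidx[a]; jj <- oidx[b]
    for (iter in 1:6) {
      kf <- ifelse(active, f_k, 0)
      diag_v <- numeric(no); rhs <- numeric(no)
      if (length(ii)) {
        diag_v <- diag_v + .acc(ii, G_oo, no) + .acc(jj, G_oo, no)
      }
      if (length(dc)) {
        di <- oidx[dc]
        diag_v <- diag_v + .acc(di, G_dir, no)
        rhs <- rhs + .acc(di, G_dir * p_chamber, no)
      }
      if (any(onb)) {
        fi <- oidx[f_nb[onb]]
        diag_v <- diag_v + .acc(fi, kf[onb], no)
        rhs <- rhs + .acc(fi, kf[onb] * f_pv[onb], no)
      }
      ## open cells momentarily cut off from any flux path: hold at chamber
      iso <- diag_v == 0
      if (any(iso)) { diag_v[iso] <- 1; rhs[iso] <- p_chamber }
      A <- Matrix::sparseMatrix(i = c(seq_len(no), pmin(ii, jj)),
                                j = c(seq_len(no), pmax(ii, jj)),
                                x = c(diag_v, -G_oo),
                                dims = c(no, no), symmetric = TRUE,
                                repr = "C")
      po <- as.numeric(Matrix::solve(A, rhs))
      p_new[open] <- po
      ## clamp fronts whose neighbor pressure exceeds saturation
      viol <- rep(FALSE, length(f_cell))
      if (any(onb))
        viol[onb] <- active[onb] & (po[oidx[f_nb[onb]]] > f_pv[onb] + 1e-9)
      if (!any(viol)) break
      active <- active & !viol
    }
    f_ploc <- rep(p_chamber, length(f_cell))
    if (any(onb)) f_ploc[onb] <- p_new[f_nb[onb]]
    f_flux <- ifelse(active, pmax(0, f_k * (f_pv - f_ploc)), 0)
  } else {
    f_ploc <- rep(p_chamber, length(f_cell))
    f_flux <- pmax(0, f_k * (f_pv - f_ploc))
  }
  p_new[f_cell] <- f_ploc
  attr(p_new, "front") <- data.frame(cell = f_cell, area = f_area,
                                     flux = f_flux, p_local = f_ploc)
  p_new
}

## index-accumulated sum (tabulate-based) for assembly
.acc <- function(i, x, n) {
  out <- numeric(n)
  if (length(i)) {
    agg <- rowsum(x, group = i)
    out[as.integer(rownames(agg))] <- agg[, 1]
  }
  out
}

#' Ice-depletion step
#'
#' Decrements the per-cell ice content using the front fluxes of the last
#' pressure solve, floors at zero (the residual demand of an emptying cell
#' is truncated, not sublimated), and updates the mass and energy ledgers.
#' The energy ledger accumulates exactly `dHs` times the sublimated mass.
#'
#' @param state A `simulationState` whose `front` attribute has been set by
#'   [darcyPressureSolve()] (stored in `state$front`).
#' @param mesh A [voxelize()] mesh.
#' @param props A [materialProperties()].
#' @param dt Time step, s.
#' @return The updated state; `state$sink_J` holds the per-cell sublimation
#'   heat (J) consumed during this step.
#' @export
iceStep <- function(state, mesh, props, dt) {
  if (dt <= 0) stop("iceStep: dt must be positive")
  fr <- state$front
  n <- length(state$s)
  state$sink_J <- numeric(n)
  if (is.null(fr) || nrow(fr) == 0L) return(state)
  V <- mesh$cell_volume
  cap_mass <- props$rho_ice * props$epsilon0 * V   # mass per unit s
  m_cell <- .acc(fr$cell, fr$flux * dt, n)          # demanded mass, kg
  ds <- m_cell / cap_mass
  ds_act <- pmin(state$s, ds)
  removed <- ds_act * cap_mass
  state$s <- state$s - ds_act
  state$s[state$s < .S_OPEN_EPS] <- 0
  state$ledger_mass <- state$ledger_mass + sum(removed)
  state$ledger_heat <- state$ledger_heat + props$dHs * sum(removed)
  state$sink_J <- removed * props$dHs
  state
}

## Assemble the constant part of the heat operator: conduction stiffness K
## (sparse, n x n), Robin conductances and the capacity vector.
.heatOperator <- function(mesh, props) {
  n <- length(mesh$solid_cells)
  dx <- mesh$cell_size
  fa <- mesh$int_faces[, 1]; fb <- mesh$int_faces[, 2]
  g <- rep(props$k_thermal * dx, length(fa))        # k * dx^2 / dx
  diag_v <- .acc(fa, g, n) + .acc(fb, g, n)
  ## boundary exchange in series with the half-cell conduction resistance
  robin <- function(h, area) {
    if (h <= 0) return(rep(0, length(area)))
    1 / (1 / (h * area) + (dx / 2) / (props$k_thermal * area))
  }
  g_exp <- .acc(mesh$exposed_faces$cell,
                robin(props$h_exposed, mesh$exposed_faces$weight * dx^2), n)
  sc <- mesh$shelf_contact_faces$scale %||% 1
  g_shelf <- .acc(mesh$shelf_contact_faces$cell,
                  robin(props$h_shelf,
                        rep(dx^2 * sc,
                            length(mesh$shelf_contact_faces$cell))), n)
  K <- Matrix::sparseMatrix(i = c(seq_len(n), fa, fb),
                            j = c(seq_len(n), fb, fa),
                            x = c(diag_v + g_exp + g_shelf, -g, -g),
                            dims = c(n, n))
  Cv <- rep(props$rho_ice * props$cp * dx^3, n)     # ice-like thermal mass
  list(K = K, Cv = Cv, g_exp = g_exp, g_shelf = g_shelf)
}

#' Implicit heat-conduction step
#'
#' Backward-Euler (unconditionally stable) conduction update with the
#' volumetric sublimation heat sink of the preceding ice step. Exposed
#' faces exchange heat with the chamber environment at `props$T_ambient`
#' (radiative-equivalent coefficient `props$h_exposed`); shelf-contact
#' faces exchange with the shelf at `shelf_T` via `props$h_shelf`; all
#' other walls are adiabatic. Dried cells retain ice-like thermal mass and
#' conductivity (pure-ice property simplification).
#'
#' @param state A `simulationState` (with `sink_J` from [iceStep()]).
#' @param mesh A [voxelize()] mesh.
#' @param props A [materialProperties()].
#' @param shelf_T Shelf temperature, K.
#' @param dt Time step, s.
#' @param op Optional precomputed operator (internal use).
#' @param factor Optional cached Cholesky factor of `C/dt + K`.
#' @return The updated state.
#' @export
heatStep <- function(state, mesh, props, shelf_T, dt, op = NULL,
                     factor = NULL) {
  if (dt <= 0) stop("heatStep: dt must be positive")
  if (is.null(op)) op <- .heatOperator(mesh, props)
  rhs <- op$Cv / dt * state$T +
    op$g_exp * props$T_ambient + op$g_shelf * shelf_T -
    state$sink_J / dt
  if (is.null(factor)) {
    M <- Matrix::Diagonal(x = op$Cv / dt) + op$K
    Tn <- as.numeric(Matrix::solve(M, rhs))
  } else {
    Tn <- as.numeric(Matrix::solve(factor, rhs))
  }
  if (any(Tn <= .T_VALID_MIN))
    stop("heatStep: temperature fell below the ", .T_VALID_MIN,
         " K validity bound (min ", signif(min(Tn), 5), " K at t = ",
         signif(state$t, 5), " h); aborting")
  state$T <- Tn
  state
}

## quantized time steps (geometric ladder under dt_max) so cached heat
## factorizations are reused across steps
.dtLadder <- function(dt_req, dt_min = 1, dt_max = 300) {
  dt <- dt_max
  while (dt > dt_req && dt > dt_min) dt <- dt / 1.5
  max(dt, dt_min)
}

#' Run the primary-drying simulation for one scenario
#'
#' Advances the coupled pressure/ice/heat system over the schedule's
#' primary-drying window with adaptive time stepping (per-cell ice change
#' capped per step) and returns the average-remaining-ice time series,
#' the zero-ice crossing time and the conservation ledgers. Deterministic
#' for fixed inputs.
#'
#' @param scenario A [vesselScenario()].
#' @param cell_size Voxel edge length, m. Default 2 mm resolves the
#'   reference vessel with ~14 cells across the diameter.
#' @param cap Maximum per-cell change of normalized ice content per step.
#'   Cells already within one cap of empty do not constrain the step: they
#'   floor at zero and the truncated residual is accounted in the ledger.
#' @param output_interval Output sampling interval, h.
#' @param dt_max,dt_min Bounds of the adaptive time step, s.
#' @return A `dryingResult` object.
#' @export
runScenario <- function(scenario, cell_size = 2e-3, cap = 0.02,
                        output_interval = 0.25, dt_max = 300, dt_min = 1) {
  stopifnot(inherits(scenario, "vesselScenario"))
  props <- scenario$props
  mesh <- voxelize(scenario$geometry, cell_size)
  win <- primaryDryingWindow(scenario$schedule)
  W <- win[2] - win[1]
  cond0 <- conditionsAt(scenario$schedule, win[1] + 1e-6)
  state <- initialState(mesh, props, scenario$T_init, cond0$p_chamber)
  op <- .heatOperator(mesh, props)
  factors <- new.env(parent = emptyenv())
  V <- mesh$cell_volume
  cap_mass <- props$rho_ice * props$epsilon0 * V

  times <- 0; avg <- 1
  tau <- 0; next_out <- output_interval
  zero_t <- NA_real_
  prev_tau <- 0; prev_avg <- 1
  s0sum <- sum(state$s0)

  while (tau < W - 1e-12) {
    cond <- conditionsAt(scenario$schedule, win[1] + min(tau + 1e-6, W))
    p <- darcyPressureSolve(state, mesh, props, cond$p_chamber)
    state$front <- attr(p, "front")
    attr(p, "front") <- NULL
    state$p <- p
    rate_s <- .acc(state$front$cell, state$front$flux, length(state$s)) /
      cap_mass
    lim <- rate_s[state$s > cap]      # near-empty cells floor harmlessly
    dt_req <- if (length(lim) && max(lim) > 0) cap / max(lim) else dt_max
    dt <- .dtLadder(dt_req, dt_min, dt_max)
    dt <- min(dt, (W - tau) * 3600)
    state <- iceStep(state, mesh, props, dt)
    key <- format(dt, digits = 12)
    if (is.null(factors[[key]]))
      factors[[key]] <- Matrix::Cholesky(
        methods::as(Matrix::Diagonal(x = op$Cv / dt) + op$K, "symmetricMatrix"))
    state <- heatStep(state, mesh, props, cond$shelf_T, dt, op = op,
                      factor = factors[[key]])
    tau <- tau + dt / 3600
    state$t <- tau
    a <- sum(state$s) / s0sum
    if (is.na(zero_t) && a < 1e-3) {
      zero_t <- prev_tau + (prev_avg - 1e-3) / (prev_avg - a) * (tau - prev_tau)
    }
    prev_tau <- tau; prev_avg <- a
    if (tau >= next_out - 1e-9 || tau >= W - 1e-12) {
      times <- c(times, tau); avg <- c(avg, a)
      next_out <- next_out + output_interval
    }
    if (a == 0) {   # fully dried: ice content can no longer change
      if (tau < W - 1e-9) { times <- c(times, W); avg <- c(avg, 0) }
      tau <- W
      break
    }
  }

  remaining <- props$rho_ice * props$epsilon0 * sum(state$s) * V
  mbe <- abs(state$ledger_mass + remaining - state$initial_ice_mass) /
    state$initial_ice_mass
  res <- list(times = times, avg_ice = avg,
              zero_ice_time = zero_t,
              final_avg_ice = avg[length(avg)],
              mass_balance_error = mbe,
              energy_ledger = list(sublimated_mass_kg = state$ledger_mass,
                                   sublimation_heat_J = state$ledger_heat),
              initial_ice_mass_kg = state$initial_ice_mass,
              window_h = W, model = "voxel",
              n_cells = length(mesh$solid_cells),
              cell_size = cell_size, cap = cap,
              label = scenario$label,
              final_state = state, mesh = mesh)
  class(res) <- "dryingResult"
  res
}

#' @export
print.dryingResult <- function(x, ...) {
  zi <- if (is.na(x$zero_ice_time)) "not reached"
        else sprintf("%.2f h", x$zero_ice_time)
  cat(sprintf("Drying result [%s, %s]:\n", x$model,
              if (nzchar(x$label %||% "")) x$label else "unnamed"))
  cat(sprintf("  window %.1f h, zero-ice crossing: %s, final avg ice %.4f\n",
              x$window_h, zi, x$final_avg_ice))
  cat(sprintf("  sublimated %.3g kg of %.3g kg; mass-balance error %.2e\n",
              x$energy_ledger$sublimated_mass_kg, x$initial_ice_mass_kg,
              x$mass_balance_error))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reduced one-dimensional moving-front model
#'
#' Collapses a scenario onto an effective column of area equal to the
#' exposed surface and length `fill_volume / area`. A planar sublimation
#' front recedes from the exposed surface; the front flux is the areal
#' Hertz-Knudsen expression at the front temperature with a series Darcy
#' resistance proportional to the dried-layer thickness (quasi-steady
#' compressible flow, closed-form front pressure). The remaining ice is a
#' thermal lump heated through the exposed surface (series: surface
#' exchange + dried-layer conduction) and exchanging with the shelf when
#' the vessel is upright.
#'
#' @param scenario A [vesselScenario()].
#' @param dt Base time step, s.
#' @param output_interval Output sampling interval, h.
#' @return A `dryingResult` with `model = "front1d"`.
#' @export
movingFront1d <- function(scenario, dt = 30, output_interval = 0.25) {
  stopifnot(inherits(scenario, "vesselScenario"))
  props <- scenario$props
  consts <- physicalConstants()
  ves <- scenario$geometry
  A <- exposedSurfaceArea(ves)
  L <- ves$fill_volume / A
  As <- shelfContactArea(ves)   # full base disk upright, ~point tilted
  win <- primaryDryingWindow(scenario$schedule)
  W <- win[2] - win[1]

  xf <- 0; Tl <- scenario$T_init
  ledger_mass <- 0; ledger_heat <- 0
  m0 <- props$rho_ice * props$epsilon0 * L * A
  times <- 0; avg <- 1
  tau <- 0; next_out <- output_interval
  zero_t <- NA_real_; prev <- c(0, 1)

  frontFlux <- function(Tf, xf, p_c) {
    pv <- vaporPressure(Tf)
    Ck <- props$alpha * sqrt(props$Mv / (2 * pi * consts$R * Tf))
    B <- 2 * props$mu_vapor * xf * consts$R * Tf /
      (props$Mv * props$kappa_dried)
    pf <- (-B * Ck + sqrt(B^2 * Ck^2 + 4 * (p_c^2 + B * Ck * pv))) / 2
    max(0, Ck * (pv - pf))
  }

  while (tau < W - 1e-12) {
    cond <- conditionsAt(scenario$schedule, win[1] + min(tau + 1e-6, W))
    J <- frontFlux(Tl, xf, cond$p_chamber)
    U <- 1 / (1 / props$h_exposed + xf / props$k_thermal)
    m_ice <- props$rho_ice * props$epsilon0 * (L - xf) * A
    dts <- min(dt, (W - tau) * 3600)
    ## sub-step so the front never jumps more than 1% of the column
    if (J > 0) dts <- min(dts, 0.01 * L * props$rho_ice * props$epsilon0 / J)
    dxf <- min(L - xf, J * dts / (props$rho_ice * props$epsilon0))
    m_rem <- dxf * props$rho_ice * props$epsilon0 * A
    ledger_mass <- ledger_mass + m_rem
    ledger_heat <- ledger_heat + props$dHs * m_rem
    xf <- xf + dxf
    if (m_ice > 1e-12 * m0) {
      ## exact relaxation of the linear lump energy balance (stable for
      ## any step, no oscillation against stiff exchange coefficients)
      G <- U * A + props$h_shelf * As
      if (G > 0) {
        T_eq <- (U * A * props$T_ambient +
                 props$h_shelf * As * cond$shelf_T -
                 J * props$dHs * A) / G
        Tl <- T_eq + (Tl - T_eq) * exp(-G * dts / (m_ice * props$cp))
      } else {
        Tl <- Tl - J * props$dHs * A * dts / (m_ice * props$cp)
      }
      Tl <- max(Tl, .T_VALID_MIN + 1)
    }
    tau <- tau + dts / 3600
    a <- 1 - xf / L
    if (is.na(zero_t) && a < 1e-3)
      zero_t <- prev[1] + (prev[2] - 1e-3) / (prev[2] - a) * (tau - prev[1])
    prev <- c(tau, a)
    if (tau >= next_out - 1e-9 || tau >= W - 1e-12) {
      times <- c(times, tau); avg <- c(avg, a)
      next_out <- next_out + output_interval
    }
    if (a <= 0) {
      if (tau < W - 1e-9) { times <- c(times, W); avg <- c(avg, 0) }
      break
    }
  }
  remaining <- props$rho_ice * props$epsilon0 * (L - xf) * A
  res <- list(times = times, avg_ice = avg, zero_ice_time = zero_t,
              final_avg_ice = avg[length(avg)],
              mass_balance_error = abs(ledger_mass + remaining - m0) / m0,
              energy_ledger = list(sublimated_mass_kg = ledger_mass,
                                   sublimation_heat_J = ledger_heat),
              initial_ice_mass_kg = m0, window_h = W, model = "front1d",
              n_cells = 1L, cell_size = NA_real_, cap = NA_real_,
              label = scenario$label)
  class(res) <- "dryingResult"
  res
}
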