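#' One complete simulation case
#'
#' Bundles geometry, schedule, material properties and the initial frozen
#' temperature into a self-consistent scenario.
#'
#' @param geometry A [vesselGeometry()].
#' @param schedule A [processSchedule()].
#' @param props A [materialProperties()].
#' @param T_init Initial temperature of the frozen mass, K. Default
#'   233.15 K (-40 degrees C): the product temperature reached at the end
#'   of the freezing hold on a maximum-cooling shelf under ambient-wall
#'   radiation.
#' @param label Free-text label for reports.
#' @return An object of class `vesselScenario`.
#' @export
vesselScenario <- function(geometry, schedule = sbrSchedule(),
                           props = materialProperties(),
                           T_init = 233.15, label = "") {
  stopifnot(inherits(geometry, "vesselGeometry"),
            inherits(schedule, "processSchedule"),
            inherits(props, "materialProperties"))
  .checkTemperature(T_init)
  sc <- list(geometry = geometry, schedule = schedule, props = props,
             T_init = T_init, label = label)
  class(sc) <- "vesselScenario"
  sc
}

#' @export
print.vesselScenario <- function(x, ...) {
  cat(sprintf("Scenario%s:\n",
              if (nzchar(x$label)) paste0(" '", x$label, "'") else ""))
  print(x$geometry)
  cat(sprintf("  T_init = %.1f K, alpha = %g, schedule total %.1f h\n",
              x$T_init, x$props$alpha, x$schedule$total))
  invisible(x)
}

#' The paired upright/tilted SBR scenarios
#'
#' Two scenarios identical in every respect except the tilt angle: a
#' cylindrical SBR with 16 mL of frozen solution, run through the
#' reference freeze-drying cycle ([sbrSchedule()]), oriented 22 degrees
#' (tilted, "ready-to-use") and 90 degrees (upright) to the shelf.
#'
#' @param props A [materialProperties()]; defaults include the calibrated
#'   evaporation coefficient.
#' @param fill_volume Fill volume, m^3. Default 16 mL; 17.6 mL corresponds
#'   to the alternative poloxamer-containing formulation.
#' @param T_init Initial frozen temperature, K.
#' @return A named list with elements `tilted` and `upright`, each a
#'   [vesselScenario()].
#' @export
#' @examples
#' sc <- sbrScenarios()
#' sc$tilted$geometry$tilt_angle
sbrScenarios <- function(props = materialProperties(), fill_volume = 16e-6,
                         T_init = 233.15) {
  sched <- sbrSchedule()
  mk <- function(tilt, label)
    vesselScenario(vesselGeometry(inner_radius = 0.0145,
                                  inner_length = 0.115,
                                  tilt_angle = tilt,
                                  fill_volume = fill_volume),
                   schedule = sched, props = props, T_init = T_init,
                   label = label)
  list(tilted = mk(22, "tilted-22deg"), upright = mk(90, "upright-90deg"))
}

#' Calibrate the evaporation coefficient against a drying time
#'
#' Bisection (in log alpha) on the single kinetic free parameter so that
#' the scenario's zero-ice crossing matches `target_zero_ice_time`.
#' Monotonicity (larger alpha never dries slower) is verified at the
#' bracket endpoints; a scenario that never reaches zero ice within the
#' window counts as an infinite drying time.
#'
#' @param scenario A [vesselScenario()]; its `props$alpha` is overridden.
#' @param target_zero_ice_time Target zero-ice crossing, h.
#' @param bracket Numeric `c(lo, hi)` bracket for alpha, within (0, 1].
#' @param tol Convergence tolerance on the achieved time, h.
#' @param max_iter Maximum bisection iterations.
#' @param solver `"voxel"` ([runScenario()]) or `"front1d"`
#'   ([movingFront1d()]).
#' @param ... Passed to the solver (e.g. `cell_size`).
#' @return A list with `alpha`, `achieved_time` (h), `iterations`, and the
#'   evaluation `history` data frame.
#' @export
calibrateAlpha <- function(scenario, target_zero_ice_time,
                           bracket = c(1e-5, 0.1), tol = 0.25,
                           max_iter = 20, solver = c("voxel", "front1d"),
                           ...) {
  solver <- match.arg(solver)
  if (bracket[1] <= 0 || bracket[2] > 1 || bracket[1] >= bracket[2])
    stop("calibrateAlpha: bracket must satisfy 0 < lo < hi <= 1")
  runner <- function(alpha) {
    sc <- scenario
    pr <- unclass(sc$props); pr$alpha <- alpha
    sc$props <- do.call(materialProperties, pr)
    res <- if (solver == "voxel") runScenario(sc, ...)
           else movingFront1d(sc, ...)
    if (is.na(res$zero_ice_time)) Inf else res$zero_ice_time
  }
  t_lo <- runner(bracket[1])   # small alpha: slow
  t_hi <- runner(bracket[2])   # large alpha: fast
  if (t_hi > t_lo)
    stop("calibrateAlpha: drying time is not monotone decreasing in alpha ",
         "over the bracket (", signif(t_lo, 4), " h at lo, ",
         signif(t_hi, 4), " h at hi)")
  if (!(t_hi <= target_zero_ice_time && t_lo >= target_zero_ice_time))
    stop("calibrateAlpha: target ", target_zero_ice_time,
         " h not bracketed: endpoints give ", signif(t_lo, 4), " h (lo) and ",
         signif(t_hi, 4), " h (hi)")
  hist <- data.frame(alpha = bracket, time_h = c(t_lo, t_hi))
  lo <- log(bracket[1]); hi <- log(bracket[2])
  best <- c(alpha = bracket[2], time = t_hi)
  iter <- 0
  while (iter < max_iter) {
    iter <- iter + 1
    mid <- exp((lo + hi) / 2)
    tm <- runner(mid)
    hist <- rbind(hist, data.frame(alpha = mid, time_h = tm))
    if (abs(tm - target_zero_ice_time) < abs(best["time"] -
                                             target_zero_ice_time))
      best <- c(alpha = mid, time = tm)
    if (is.finite(tm) && abs(tm - target_zero_ice_time) < tol) break
    if (tm > target_zero_ice_time) lo <- log(mid) else hi <- log(mid)
  }
  list(alpha = unname(best["alpha"]), achieved_time = unname(best["time"]),
       iterations = iter, history = hist)
}

#' Compare drying of the upright and tilted orientations
#'
#' Runs the paired SBR scenarios with identical parameters and reports the
#' tilted zero-ice time, the upright remaining ice fraction at the end of
#' the primary-drying window, and both average-ice curves on a common time
#' grid.
#'
#' @param props A [materialProperties()] (normally carrying the calibrated
#'   evaporation coefficient).
#' @param cell_size Voxel edge length, m.
#' @param ... Passed to [runScenario()].
#' @return An object of class `orientationComparison`: a list with
#'   `tilted`, `upright` (both `dryingResult`), `curves` (data frame
#'   `t_h`, `avg_ice_tilted`, `avg_ice_upright`),
#'   `tilted_zero_ice_time_h` and `upright_final_fraction`.
#' @export
compareOrientations <- function(props = materialProperties(),
                                cell_size = 2e-3, ...) {
  sc <- sbrScenarios(props = props)
  rt <- runScenario(sc$tilted, cell_size = cell_size, ...)
  ru <- runScenario(sc$upright, cell_size = cell_size, ...)
  grid <- seq(0, rt$window_h, by = 0.25)
  curves <- data.frame(
    t_h = grid,
    avg_ice_tilted = stats::approx(rt$times, rt$avg_ice, grid, rule = 2)$y,
    avg_ice_upright = stats::approx(ru$times, ru$avg_ice, grid, rule = 2)$y)
  out <- list(tilted = rt, upright = ru, curves = curves,
              tilted_zero_ice_time_h = rt$zero_ice_time,
              upright_final_fraction = ru$final_avg_ice,
              parameters = unclass(props))
  class(out) <- "orientationComparison"
  out
}

#' @export
print.orientationComparison <- function(x, ...) {
  zi <- if (is.na(x$tilted_zero_ice_time_h)) "not reached"
        else sprintf("%.2f h", x$tilted_zero_ice_time_h)
  cat("Orientation comparison (identical parameters, tilt only):\n")
  cat(sprintf("  tilted (22 deg):  zero-ice crossing %s\n", zi))
  cat(sprintf("  upright (90 deg): %.1f%% ice remaining at %.1f h\n",
              100 * x$upright_final_fraction, x$upright$window_h))
  invisible(x)
}

## run `expr` under a seed without disturbing the caller's RNG stream
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Random but physically valid scenario (property-test generator)
#'
#' Samples vessel radius 10-20 mm, length 80-150 mm, tilt 15-90 degrees,
#' fill 20-60\% of capacity, evaporation coefficient in \[1e-3, 1\] (log
#' uniform) and chamber pressure 1-20 Pa, rejecting combinations whose
#' free-surface plane is clipped by the vessel ends. Deterministic for a
#' fixed seed and leaves the caller's RNG state untouched.
#'
#' @param seed Integer seed.
#' @return A [vesselScenario()] whose schedule is the reference cycle with
#'   the primary-drying pressure replaced by the sampled value.
#' @export
randomScenario <- function(seed) {
  .withSeed(seed, {
    for (try in 1:100) {
      r <- stats::runif(1, 0.010, 0.020)
      L <- stats::runif(1, 0.080, 0.150)
      tilt <- stats::runif(1, 15, 90)
      fillfrac <- stats::runif(1, 0.20, 0.60)
      alpha <- exp(stats::runif(1, log(1e-3), log(1)))
      p_mbar <- stats::runif(1, 1, 20) / 100
      ves <- vesselGeometry(r, L, tilt, fillfrac * pi * r^2 * L)
      if (!fillPlaneInside(ves)) next
      segs <- list(
        scheduleSegment("ramp", 2.5, "maximum-cooling", "ambient", "freezing"),
        scheduleSegment("hold", 12, "maximum-cooling", "ambient", "freezing"),
        scheduleSegment("ramp", 1.5, "maximum-cooling", p_mbar, "primary_drying"),
        scheduleSegment("hold", 30, "maximum-cooling", p_mbar, "primary_drying"),
        scheduleSegment("ramp", 5, 20, 0.1, "secondary_drying"),
        scheduleSegment("hold", 8, 20, 0.1, "secondary_drying"))
      pr <- unclass(materialProperties()); pr$alpha <- alpha
      return(vesselScenario(ves, processSchedule(segs),
                            do.call(materialProperties, pr),
                            label = sprintf("random-seed-%d", seed)))
    }
    stop("randomScenario: rejection sampling failed after 100 tries")
  })
}
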