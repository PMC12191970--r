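## Sentinel resolution defaults
.AMBIENT_MBAR <- 1013.25
.AMBIENT_T_C <- 20
.MAX_COOLING_C <- -55   # lowest shelf setpoint of the dryer class modeled

#' One ramp or hold segment of a freeze-drying cycle
#'
#' @param kind `"ramp"` or `"hold"`.
#' @param duration Segment duration, h; > 0.
#' @param shelf_temperature_end End-of-segment shelf temperature in degrees
#'   Celsius, or the sentinel `"maximum-cooling"` (the dryer's lowest shelf
#'   setpoint, -55 degrees C by default, configurable via
#'   [processSchedule()]).
#' @param chamber_pressure Chamber pressure in mbar, or the sentinel
#'   `"ambient"` (1013.25 mbar).
#' @param event_label One of `"freezing"`, `"primary_drying"`,
#'   `"secondary_drying"`.
#' @return An object of class `scheduleSegment`.
#' @export
scheduleSegment <- function(kind, duration, shelf_temperature_end,
                            chamber_pressure, event_label) {
  kind <- match.arg(kind, c("ramp", "hold"))
  event_label <- match.arg(event_label,
                           c("freezing", "primary_drying", "secondary_drying"))
  if (!is.numeric(duration) || duration <= 0 || !is.finite(duration))
    stop("scheduleSegment: duration must be positive (hours)")
  if (is.numeric(chamber_pressure)) {
    if (chamber_pressure <= 0) stop("scheduleSegment: pressure must be positive")
  } else if (!identical(chamber_pressure, "ambient")) {
    stop("scheduleSegment: chamber_pressure must be numeric (mbar) or \"ambient\"")
  }
  if (!is.numeric(shelf_temperature_end) &&
      !identical(shelf_temperature_end, "maximum-cooling"))
    stop("scheduleSegment: shelf_temperature_end must be numeric (degC) or \"maximum-cooling\"")
  structure(list(kind = kind, duration = duration,
                 shelf_temperature_end = shelf_temperature_end,
                 chamber_pressure = chamber_pressure,
                 event_label = event_label),
            class = "scheduleSegment")
}

#' Freeze-drying process schedule
#'
#' An ordered list of ramp/hold segments tiling the cycle without gaps.
#' Sentinels are resolved at construction: `"maximum-cooling"` to
#' `max_cooling_C` and `"ambient"` to 1013.25 mbar. Shelf temperature starts
#' at ambient (20 degrees C) at t = 0; ramps interpolate linearly from the
#' previous segment's end temperature, holds stay at their setpoint.
#'
#' @param segments List of [scheduleSegment()] objects.
#' @param t0 Start time of the simulated window, h (bookkeeping only).
#' @param max_cooling_C Resolution of the `"maximum-cooling"` sentinel,
#'   degrees Celsius.
#' @return An object of class `processSchedule`.
#' @export
processSchedule <- function(segments, t0 = 0, max_cooling_C = .MAX_COOLING_C) {
  if (!length(segments)) stop("processSchedule: need at least one segment")
  lapply(segments, function(s)
    if (!inherits(s, "scheduleSegment")) stop("processSchedule: all elements must be scheduleSegment"))
  dur <- vapply(segments, `[[`, numeric(1), "duration")
  t_start <- cumsum(c(0, dur[-length(dur)]))
  t_end <- cumsum(dur)
  T_end_C <- vapply(segments, function(s) {
    if (identical(s$shelf_temperature_end, "maximum-cooling")) max_cooling_C
    else s$shelf_temperature_end
  }, numeric(1))
  p_Pa <- vapply(segments, function(s) {
    mbar <- if (identical(s$chamber_pressure, "ambient")) .AMBIENT_MBAR
            else s$chamber_pressure
    mbar * 100
  }, numeric(1))
  T_start_C <- c(.AMBIENT_T_C, T_end_C[-length(T_end_C)])
  sched <- list(segments = segments, t0 = t0,
                t_start = t_start, t_end = t_end,
                T_start_K = T_start_C + 273.15, T_end_K = T_end_C + 273.15,
                p_Pa = p_Pa,
                kind = vapply(segments, `[[`, character(1), "kind"),
                event = vapply(segments, `[[`, character(1), "event_label"),
                total = t_end[length(t_end)])
  class(sched) <- "processSchedule"
  sched
}

#' @export
print.processSchedule <- function(x, ...) {
  cat(sprintf("Freeze-drying schedule: %d segments, %.1f h total\n",
              length(x$segments), x$total))
  for (i in seq_along(x$segments))
    cat(sprintf("  [%5.1f-%5.1f h] %-4s %-16s shelf -> %6.1f degC, %g Pa\n",
                x$t_start[i], x$t_end[i], x$kind[i], x$event[i],
                x$T_end_K[i] - 273.15, x$p_Pa[i]))
  invisible(x)
}

#' The reference freeze-drying cycle for the SBR process
#'
#' The six-segment cycle used for the microcarrier freeze-drying runs:
#' freezing ramp 2.5 h plus hold 12 h at maximum shelf cooling and ambient
#' pressure; primary drying ramp 1.5 h plus hold 30 h at 0.05 mbar (the
#' 31.5 h comparison window); secondary drying ramp 5 h to 20 degrees C plus
#' hold 8 h at 0.1 mbar.
#'
#' @param max_cooling_C Shelf temperature reached at `"maximum-cooling"`,
#'   degrees Celsius.
#' @param secondary_hold_h Duration of the final storage hold, h (the cycle
#'   specifies "at least 8").
#' @return A [processSchedule()].
#' @export
#' @examples
#' sbrSchedule()
sbrSchedule <- function(max_cooling_C = .MAX_COOLING_C, secondary_hold_h = 8) {
  segs <- list(
    scheduleSegment("ramp", 2.5, "maximum-cooling", "ambient", "freezing"),
    scheduleSegment("hold", 12,  "maximum-cooling", "ambient", "freezing"),
    scheduleSegment("ramp", 1.5, "maximum-cooling", 0.05, "primary_drying"),
    scheduleSegment("hold", 30,  "maximum-cooling", 0.05, "primary_drying"),
    scheduleSegment("ramp", 5,   20, 0.1, "secondary_drying"),
    scheduleSegment("hold", secondary_hold_h, 20, 0.1, "secondary_drying"))
  processSchedule(segs, max_cooling_C = max_cooling_C)
}

#' Boundary conditions at a time point
#'
#' Piecewise-linear shelf temperature and piecewise-constant chamber
#' pressure at time `t`. Segment boundaries take the end state of the
#' earlier segment; `t = 0` returns the initial ambient state.
#'
#' @param schedule A [processSchedule()].
#' @param t Time since cycle start, h (vectorized). Must lie in
#'   `[0, total duration]`.
#' @return A list with numeric vectors `shelf_T` (K) and `p_chamber` (Pa).
#' @export
conditionsAt <- function(schedule, t) {
  if (any(!is.finite(t)) || any(t < 0) || any(t > schedule$total + 1e-9))
    stop("conditionsAt: t outside the schedule [0, ", schedule$total, "] h")
  idx <- findInterval(t, schedule$t_start, left.open = TRUE)
  idx[idx < 1L] <- 1L
  frac <- (t - schedule$t_start[idx]) /
    (schedule$t_end[idx] - schedule$t_start[idx])
  frac <- pmin(1, pmax(0, frac))
  is_ramp <- schedule$kind[idx] == "ramp"
  Tt <- ifelse(is_ramp,
               schedule$T_start_K[idx] +
                 frac * (schedule$T_end_K[idx] - schedule$T_start_K[idx]),
               schedule$T_end_K[idx])
  list(shelf_T = Tt, p_chamber = schedule$p_Pa[idx])
}

#' Primary-drying window of a schedule
#'
#' @param schedule A [processSchedule()].
#' @return Numeric `c(start, end)` in hours of the contiguous
#'   primary-drying segments.
#' @export
primaryDryingWindow <- function(schedule) {
  k <- which(schedule$event == "primary_drying")
  if (!length(k)) stop("schedule has no primary-drying segments")
  c(schedule$t_start[min(k)], schedule$t_end[max(k)])
}
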