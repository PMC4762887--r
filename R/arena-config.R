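#' Arena configuration
#'
#' Describes the circular two-choice arena and its imaging calibration. The
#' arena is a 76 mm disc whose two halves carry sugar and plain (water)
#' substrate; the boundary between the halves is a diameter of zero width, so
#' the halves partition the disc exactly.
#'
#' @param diameter Arena diameter in mm (default 76).
#' @param mm_per_pixel Imaging calibration, mm per pixel (default 0.15).
#' @param fps Frame rate of the (synthetic) video in frames per second
#'   (default 10).
#' @param sugar_side Which half of the disc carries sugar: `"east"` (x > 0),
#'   `"west"` (x < 0), `"north"` (y > 0) or `"south"` (y < 0). Coordinates are
#'   arena-centred mm with y pointing up.
#' @param duration Recording duration in seconds (default 60).
#' @param wall_margin Distance in mm that agent centres keep from the wall so
#'   a rendered body never protrudes beyond the arena (default 1.5).
#'
#' @return An object of class `arena_config`.
#' @examples
#' cfg <- arena_config()
#' cfg$diameter
#' @export
arena_config <- function(diameter = 76, mm_per_pixel = 0.15, fps = 10,
                         sugar_side = c("east", "west", "north", "south"),
                         duration = 60, wall_margin = 1.5) {
  sugar_side <- match.arg(sugar_side)
  stopifnot(is.finite(diameter), diameter > 0,
            is.finite(mm_per_pixel), mm_per_pixel > 0,
            is.finite(fps), fps > 0,
            is.finite(duration), duration > 0,
            is.finite(wall_margin), wall_margin >= 0)
  structure(list(diameter = diameter, mm_per_pixel = mm_per_pixel,
                 fps = fps, sugar_side = sugar_side, duration = duration,
                 wall_margin = wall_margin),
            class = "arena_config")
}

#' @export
print.arena_config <- function(x, ...) {
  cat(sprintf(
    "Circular arena: %.0f mm diameter, %.3f mm/px, %g fps, sugar on %s half, %g s\n",
    x$diameter, x$mm_per_pixel, x$fps, x$sugar_side, x$duration))
  invisible(x)
}

#' Agent dynamics for the synthetic arena
#'
#' Rates and speeds governing the four behavioural states of a simulated fly:
#' free to walk on the sugar side (FS), free to walk on the water side (FW),
#' feeding on sugar (S) and feeding on water (W). Free agents perform a
#' correlated random walk at a side-dependent speed; feeding agents are
#' stationary. Feeding entry/exit is sampled per time step from the
#' exponential-rate probability 1 - exp(-k dt). Side changes happen only
#' through walking across the boundary, so feeding flies cannot change side.
#'
#' The default rates give sugar affinity A = k_sin/k_sout = 2, water affinity
#' D = k_win/k_wout = 0.001 (flies essentially never feed on water) and, with
#' the default speeds, a sugar/water speed ratio B = 0.5 (sugar halves the
#' walking speed of a hungry fly).
#'
#' @param k_sin,k_sout Feeding entry/exit rates on the sugar side (1/s).
#' @param k_win,k_wout Feeding entry/exit rates on the water side (1/s).
#' @param speed_sugar,speed_water Mean walking speed on each side (mm/s).
#' @param turn_sd Heading diffusion per step (degrees); heading at each step
#'   is the previous heading plus Gaussian noise with this SD.
#' @param startle_multiplier,startle_window Optional initial-activity
#'   transient: walking speed is multiplied by a factor that decays linearly
#'   from `startle_multiplier` to 1 over the first `startle_window` seconds.
#'   Defaults (1, 0) disable the transient.
#' @param seed Integer RNG seed; with a fixed seed the simulation is
#'   bit-reproducible.
#'
#' @return An object of class `agent_dynamics`.
#' @export
agent_dynamics <- function(k_sin = 0.2, k_sout = 0.1,
                           k_win = 1e-4, k_wout = 0.1,
                           speed_sugar = 2.5, speed_water = 5,
                           turn_sd = 10,
                           startle_multiplier = 1, startle_window = 0,
                           seed = 1L) {
  rates <- c(k_sin = k_sin, k_sout = k_sout, k_win = k_win, k_wout = k_wout)
  speeds <- c(speed_sugar = speed_sugar, speed_water = speed_water)
  if (any(!is.finite(rates)) || any(rates < 0))
    stop("transition rates must be finite and non-negative")
  if (any(!is.finite(speeds)) || any(speeds < 0))
    stop("walking speeds must be finite and non-negative")
  stopifnot(is.finite(turn_sd), turn_sd >= 0,
            is.finite(startle_multiplier), startle_multiplier >= 1,
            is.finite(startle_window), startle_window >= 0)
  structure(list(k_sin = k_sin, k_sout = k_sout, k_win = k_win,
                 k_wout = k_wout, speed_sugar = speed_sugar,
                 speed_water = speed_water, turn_sd = turn_sd,
                 startle_multiplier = startle_multiplier,
                 startle_window = startle_window, seed = as.integer(seed)),
            class = "agent_dynamics")
}

# Signed coordinate along the sugar axis: positive on the sugar half.
sugar_axis_coord <- function(x, y, sugar_side) {
  switch(sugar_side, east = x, west = -x, north = y, south = -y)
}

# Side label from arena-centred mm coordinates ("sugar"/"water"/"boundary").
side_of <- function(x, y, sugar_side) {
  s <- sugar_axis_coord(x, y, sugar_side)
  out <- ifelse(s > 0, "sugar", ifelse(s < 0, "water", "boundary"))
  out
}
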