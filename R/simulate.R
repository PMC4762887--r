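#' Simulate ground-truthed fly trajectories
#'
#' Runs the four-state behavioural dynamics on a population of independent
#' agents in the circular arena and returns a complete ground-truth table.
#' Free-walking agents advance each frame by `speed * dt` along a heading that
#' diffuses by `turn_sd` degrees per step (a correlated random walk); the
#' arena wall reflects them specularly, preserving step length. Feeding agents
#' are stationary, so side crossing occurs only in the free-walking state.
#' State switches are sampled each step with probability `1 - exp(-k * dt)`
#' from the side-appropriate feeding entry/exit rate.
#'
#' @param dynamics An [agent_dynamics()] object.
#' @param config An [arena_config()] object.
#' @param n_flies Number of agents (may be 0).
#' @param seed Optional integer seed overriding `dynamics$seed`.
#'
#' @return A data.frame with one row per frame and agent: `frame` (1-based),
#'   `time` (s), `id`, `x_mm`, `y_mm` (arena-centred, y up), `heading_deg`
#'   (in \[0, 360)), `orientation_deg` (heading reduced mod 180), `state`
#'   (`"free_walk"` or `"feeding"`) and `side` (`"sugar"`/`"water"`).
#' @examples
#' truth <- simulate_agents(agent_dynamics(), arena_config(duration = 2), 5)
#' head(truth)
#' @export
simulate_agents <- function(dynamics, config, n_flies, seed = NULL) {
  stopifnot(inherits(dynamics, "agent_dynamics"),
            inherits(config, "arena_config"),
            n_flies >= 0)
  n_frames <- max(1L, as.integer(round(config$duration * config$fps)))
  cols <- c("frame", "time", "id", "x_mm", "y_mm", "heading_deg",
            "orientation_deg")
  if (n_flies == 0) {
    out <- as.data.frame(stats::setNames(rep(list(numeric(0)), length(cols)), cols))
    out$state <- character(0)
    out$side <- character(0)
    return(out)
  }
  set.seed(if (is.null(seed)) dynamics$seed else as.integer(seed))

  dt <- 1 / config$fps
  r_eff <- config$diameter / 2 - config$wall_margin
  # initial placement: uniform over the admissible disc, walking, random heading
  rr <- r_eff * sqrt(stats::runif(n_flies))
  th <- stats::runif(n_flies, 0, 2 * pi)
  x <- rr * cos(th)
  y <- rr * sin(th)
  heading <- stats::runif(n_flies, 0, 360)
  feeding <- rep(FALSE, n_flies)

  p_in <- c(sugar = 1 - exp(-dynamics$k_sin * dt),
            water = 1 - exp(-dynamics$k_win * dt))
  p_out <- c(sugar = 1 - exp(-dynamics$k_sout * dt),
             water = 1 - exp(-dynamics$k_wout * dt))
  speeds <- c(sugar = dynamics$speed_sugar, water = dynamics$speed_water)

  X <- Y <- H <- matrix(NA_real_, n_frames, n_flies)
  FEED <- matrix(FALSE, n_frames, n_flies)
  X[1, ] <- x; Y[1, ] <- y; H[1, ] <- heading

  for (t in seq_len(n_frames)[-1]) {
    free <- !feeding
    if (any(free)) {
      heading[free] <- (heading[free] +
        stats::rnorm(sum(free), 0, dynamics$turn_sd)) %% 360
      side_now <- ifelse(sugar_axis_coord(x[free], y[free],
                                          config$sugar_side) >= 0,
                         "sugar", "water")
      mult <- startle_factor((t - 2) * dt, dynamics)
      step <- speeds[side_now] * dt * mult
      rad <- heading[free] * pi / 180
      moved <- reflect_in_disc(x[free], y[free],
                               x[free] + step * cos(rad),
                               y[free] + step * sin(rad), r_eff)
      # reflection may change the direction of travel; keep heading consistent
      dx <- moved$x - x[free]; dy <- moved$y - y[free]
      turned <- moved$reflected & (dx != 0 | dy != 0)
      heading[free][turned] <- (atan2(dy[turned], dx[turned]) * 180 / pi) %% 360
      x[free] <- moved$x; y[free] <- moved$y
    }
    side <- ifelse(sugar_axis_coord(x, y, config$sugar_side) >= 0,
                   "sugar", "water")
    u <- stats::runif(n_flies)
    start_feed <- !feeding & (u < p_in[side])
    stop_feed <- feeding & (u < p_out[side])
    feeding <- (feeding | start_feed) & !stop_feed
    X[t, ] <- x; Y[t, ] <- y; H[t, ] <- heading; FEED[t, ] <- feeding
  }

  out <- data.frame(
    frame = rep(seq_len(n_frames), each = n_flies),
    time = rep((seq_len(n_frames) - 1) * dt, each = n_flies),
    id = rep(seq_len(n_flies), times = n_frames),
    x_mm = as.vector(t(X)),
    y_mm = as.vector(t(Y)),
    heading_deg = as.vector(t(H)))
  out$orientation_deg <- out$heading_deg %% 180
  out$state <- ifelse(as.vector(t(FEED)), "feeding", "free_walk")
  out$side <- side_of(out$x_mm, out$y_mm, config$sugar_side)
  class(out) <- c("fly_truth", class(out))
  out
}

startle_factor <- function(time_s, dynamics) {
  if (dynamics$startle_window <= 0 || dynamics$startle_multiplier <= 1)
    return(1)
  frac <- pmax(0, 1 - time_s / dynamics$startle_window)
  1 + (dynamics$startle_multiplier - 1) * frac
}

# Specular reflection of the segment (x0,y0)->(x1,y1) at the circle of radius
# r centred on the origin. Step length is preserved; up to 8 successive
# reflections are applied (more would require a pathological step length).
reflect_in_disc <- function(x0, y0, x1, y1, r) {
  reflected <- rep(FALSE, length(x0))
  for (iter in 1:8) {
    out <- x1 * x1 + y1 * y1 > r * r
    if (!any(out)) break
    reflected <- reflected | out
    xa <- x0[out]; ya <- y0[out]; xb <- x1[out]; yb <- y1[out]
    dx <- xb - xa; dy <- yb - ya
    aa <- dx * dx + dy * dy
    bb <- 2 * (xa * dx + ya * dy)
    cc <- xa * xa + ya * ya - r * r
    disc <- pmax(bb * bb - 4 * aa * cc, 0)
    tt <- (-bb + sqrt(disc)) / (2 * aa)
    tt <- pmin(pmax(tt, 0), 1)
    # hit point on the wall and outward normal there
    hx <- xa + tt * dx; hy <- ya + tt * dy
    nn <- sqrt(hx * hx + hy * hy)
    nn[nn == 0] <- 1
    nx <- hx / nn; ny <- hy / nn
    # reflect the remaining portion of the step about the tangent
    rx <- xb - hx; ry <- yb - hy
    dot <- rx * nx + ry * ny
    x1[out] <- hx + rx - 2 * dot * nx
    y1[out] <- hy + ry - 2 * dot * ny
    x0[out] <- hx; y0[out] <- hy
  }
  # numerical safety: clamp anything still marginally outside onto the wall
  d <- sqrt(x1 * x1 + y1 * y1)
  bad <- d > r
  if (any(bad)) {
    x1[bad] <- x1[bad] * r / d[bad]
    y1[bad] <- y1[bad] * r / d[bad]
  }
  list(x = x1, y = y1, reflected = reflected)
}

#' Occupancy-based preference index of a simulated population
#'
#' Per-frame preference index implied by the ground-truth sides, and a
#' per-fly time-average that supports an honest Monte-Carlo standard error
#' (flies are independent; frames within a fly are not).
#'
#' @param truth A ground-truth table from [simulate_agents()].
#' @param burn_in Fraction of initial frames discarded before averaging
#'   (default 0.2).
#' @return A list with `pi_mean` (grand mean PI), `se` (standard error over
#'   flies), `per_fly` (signed mean occupancy per fly) and `n_frames` used.
#' @export
occupancy_pi <- function(truth, burn_in = 0.2) {
  stopifnot(nrow(truth) > 0)
  keep <- truth$frame > burn_in * max(truth$frame)
  tr <- truth[keep, ]
  sgn <- ifelse(tr$side == "sugar", 1, ifelse(tr$side == "water", -1, 0))
  per_fly <- tapply(sgn, tr$id, mean)
  list(pi_mean = mean(per_fly),
       se = stats::sd(per_fly) / sqrt(length(per_fly)),
       per_fly = per_fly,
       n_frames = length(unique(tr$frame)))
}
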