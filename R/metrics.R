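#' Preference index from side counts
#'
#' The standard two-choice read-out: `PI = (n_sugar - n_water) /
#' (n_sugar + n_water)`, +1 when every fly sits on the sugar half. Frames
#' with no flies counted yield `NA` (undefined, excluded from downstream
#' pooling).
#'
#' @param n_sugar,n_water Non-negative counts (vectorized).
#' @return Numeric vector of PIs in \[-1, 1\], `NA` where the total is 0.
#' @examples
#' preference_index(7, 3)   # 0.4
#' @export
preference_index <- function(n_sugar, n_water) {
  stopifnot(all(n_sugar >= 0), all(n_water >= 0))
  total <- n_sugar + n_water
  ifelse(total > 0, (n_sugar - n_water) / total, NA_real_)
}

#' Count flies on each arena half
#'
#' Assigns each detection to the sugar or water half by the sign of its
#' centroid along the sugar axis; a centroid exactly on the boundary counts
#' neither.
#'
#' @param detections Detection table with `frame`, `x_mm`, `y_mm`.
#' @param config An [arena_config()] (for the sugar side and frame rate).
#' @return A data.frame `frame`, `time`, `n_sugar`, `n_water`, `pi` with one
#'   row per frame present in `detections`.
#' @export
count_sides <- function(detections, config) {
  stopifnot(inherits(config, "arena_config"))
  side <- side_of(detections$x_mm, detections$y_mm, config$sugar_side)
  frames <- sort(unique(detections$frame))
  n_s <- vapply(frames, function(f)
    sum(side == "sugar" & detections$frame == f), numeric(1))
  n_w <- vapply(frames, function(f)
    sum(side == "water" & detections$frame == f), numeric(1))
  data.frame(frame = frames, time = (frames - 1) / config$fps,
             n_sugar = n_s, n_water = n_w,
             pi = preference_index(n_s, n_w))
}

#' Pool a preference-index series over a time window
#'
#' Unweighted mean of the defined per-frame PIs with `time` inside
#' `window` (inclusive); the conventional pooling window is 30-60 s, after
#' the introduction transient has decayed.
#'
#' @param counts Data.frame with `time` and `pi` columns (see
#'   [count_sides()]).
#' @param window Numeric `(start, end)` in seconds, default `c(30, 60)`.
#' @return The pooled PI (scalar).
#' @export
pooled_pi <- function(counts, window = c(30, 60)) {
  stopifnot(length(window) == 2, window[1] <= window[2])
  sel <- counts$time >= window[1] & counts$time <= window[2] &
    !is.na(counts$pi)
  if (!any(sel)) stop("no defined PI frames inside the pooling window")
  mean(counts$pi[sel])
}

#' Pooled velocity summary over a time window
#'
#' Mean linear velocity and mean absolute angular velocity over all flies
#' and track steps whose time falls in the window.
#'
#' @param steps Track-step table from [track_stack()] (columns `frame_t`,
#'   `v_mm_s`, `abs_w_deg_s`).
#' @param fps Frame rate used to convert frames to seconds.
#' @param window Numeric `(start, end)` in seconds, default `c(30, 60)`.
#' @return A list `mean_linear_mm_s`, `mean_abs_angular_deg_s`, `n_steps`.
#' @export
velocity_summary <- function(steps, fps, window = c(30, 60)) {
  stopifnot(length(window) == 2, window[1] <= window[2], fps > 0)
  t0 <- (steps$frame_t - 1) / fps
  sel <- t0 >= window[1] & t0 <= window[2]
  if (!any(sel)) stop("no track steps inside the window")
  list(mean_linear_mm_s = mean(steps$v_mm_s[sel]),
       mean_abs_angular_deg_s = mean(steps$abs_w_deg_s[sel]),
       n_steps = sum(sel))
}

#' Proboscis extension fraction per concentration
#'
#' Aggregates binary PER scores (0 = no extension, 1 = extension; solutions
#' presented in triplicate to each fly) into the mean extension fraction per
#' concentration.
#'
#' @param scores Data.frame with columns `concentration` and `score`
#'   (0/1); any further columns (fly id, presentation) are ignored.
#' @return A data.frame `concentration`, `per_fraction`, `n`.
#' @export
per_fraction <- function(scores) {
  stopifnot(all(scores$score %in% c(0, 1)))
  agg <- stats::aggregate(score ~ concentration, data = scores, FUN = mean)
  n <- stats::aggregate(score ~ concentration, data = scores, FUN = length)
  data.frame(concentration = agg$concentration,
             per_fraction = agg$score, n = n$score)
}

#' Fit a monotone sigmoid dose-response curve
#'
#' Least-squares fit of `y = floor + (ceiling - floor) /
#' (1 + exp(-slope * (x - threshold)))`, the logistic form used for
#' preference and proboscis-extension dose-response data. The floor and
#' ceiling can be fixed (e.g. 0 and 1 for extension fractions) or fitted.
#'
#' @param x Predictor (e.g. log10 concentration or starvation time);
#'   at least 4 distinct values.
#' @param y Response.
#' @param floor,ceiling Fixed asymptotes, or `NA` to fit them.
#' @return An object of class `sigmoid_fit`: list with `slope`, `threshold`,
#'   `floor`, `ceiling`, `residuals`, `fitted`, and a `predict` closure.
#'   Flat responses (zero spread) raise an error: the slope is
#'   unidentifiable.
#' @examples
#' x <- seq(-2, 4, length.out = 9)
#' y <- 1 / (1 + exp(-1.5 * (x - 1)))
#' f <- fit_sigmoid(x, y, floor = 0, ceiling = 1)
#' c(f$slope, f$threshold)
#' @export
fit_sigmoid <- function(x, y, floor = NA, ceiling = NA) {
  stopifnot(length(x) == length(y))
  if (length(unique(x)) < 4)
    stop("need at least 4 distinct predictor values")
  if (stats::sd(y) == 0)
    stop("constant responses: sigmoid slope unidentifiable")
  fit_floor <- is.na(floor); fit_ceiling <- is.na(ceiling)
  lo <- if (fit_floor) min(y) else floor
  hi <- if (fit_ceiling) max(y) else ceiling
  increasing <- stats::cor(x, y) >= 0
  start <- list(slope = if (increasing) 2 else -2,
                threshold = stats::median(x))
  lower <- c(slope = -Inf, threshold = min(x) - 3 * diff(range(x)))
  upper <- c(slope = Inf, threshold = max(x) + 3 * diff(range(x)))
  if (fit_floor) {
    start$floor <- lo; lower <- c(lower, floor = -Inf)
    upper <- c(upper, floor = Inf)
  }
  if (fit_ceiling) {
    start$ceiling <- hi; lower <- c(lower, ceiling = -Inf)
    upper <- c(upper, ceiling = Inf)
  }
  form <- if (fit_floor && fit_ceiling)
    y ~ floor + (ceiling - floor) / (1 + exp(-slope * (x - threshold)))
  else if (fit_floor)
    stats::as.formula(sprintf(
      "y ~ floor + (%g - floor) / (1 + exp(-slope * (x - threshold)))", hi))
  else if (fit_ceiling)
    stats::as.formula(sprintf(
      "y ~ %g + (ceiling - %g) / (1 + exp(-slope * (x - threshold)))",
      lo, lo))
  else
    stats::as.formula(sprintf(
      "y ~ %g + (%g - %g) / (1 + exp(-slope * (x - threshold)))",
      lo, hi, lo))
  dat <- data.frame(x = x, y = y)
  fit <- tryCatch(
    minpack.lm::nlsLM(form, data = dat, start = start,
                      lower = lower, upper = upper,
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) stop("sigmoid fit did not converge: ",
                             conditionMessage(e)))
  cf <- stats::coef(fit)
  pars <- list(slope = unname(cf["slope"]),
               threshold = unname(cf["threshold"]),
               floor = if (fit_floor) unname(cf["floor"]) else lo,
               ceiling = if (fit_ceiling) unname(cf["ceiling"]) else hi)
  pars$extrapolated <- pars$threshold < min(x) || pars$threshold > max(x)
  pars$fitted <- stats::fitted(fit)
  pars$residuals <- y - pars$fitted
  pars$predict <- function(xnew)
    pars$floor + (pars$ceiling - pars$floor) /
      (1 + exp(-pars$slope * (xnew - pars$threshold)))
  class(pars) <- "sigmoid_fit"
  pars
}

#' @export
print.sigmoid_fit <- function(x, ...) {
  cat(sprintf(
    "sigmoid fit: slope %.4g, threshold %.4g, floor %.4g, ceiling %.4g (RSS %.3g)\n",
    x$slope, x$threshold, x$floor, x$ceiling, sum(x$residuals^2)))
  invisible(x)
}
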