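#' Transition rates of the four-state preference model
#'
#' Flies in the two-choice arena occupy one of four states: free to walk on
#' the sugar side (FS), free to walk on the water side (FW), feeding on
#' sugar (S), feeding on water (W). All transitions are reversible and
#' governed by constant rates: `k_sw`/`k_ws` move free flies between the
#' sides (these scale with the walking speed on the side being left), and
#' `k_sin`/`k_sout`, `k_win`/`k_wout` move flies into and out of feeding on
#' each side.
#'
#' @param k_sw,k_ws Side-crossing rates sugar->water and water->sugar (1/s).
#' @param k_sin,k_sout Feeding entry/exit rates on sugar (1/s).
#' @param k_win,k_wout Feeding entry/exit rates on water (1/s).
#' @return An object of class `transition_rates`.
#' @export
transition_rates <- function(k_sw, k_ws, k_sin, k_sout, k_win, k_wout) {
  r <- c(k_sw = k_sw, k_ws = k_ws, k_sin = k_sin, k_sout = k_sout,
         k_win = k_win, k_wout = k_wout)
  if (any(!is.finite(r)) || any(r < 0))
    stop("all transition rates must be finite and non-negative")
  structure(as.list(r), class = "transition_rates")
}

#' Dimensionless ratios of the preference model
#'
#' `A = k_sin / k_sout` is the sugar affinity, `B = k_sw / k_ws` the
#' sugar/water speed ratio (crossing rates are proportional to walking
#' speeds, so the proportionality constant cancels) and
#' `D = k_win / k_wout` the water affinity, fixed by default at the
#' arbitrarily low 0.001 because flies are never seen feeding on water.
#' `A = Inf` is a legal value (feeding exit rate zero) and propagates as a
#' limit.
#'
#' @param A,B,D Non-negative ratios; `A` may be `Inf`.
#' @return An object of class `model_ratios`.
#' @export
model_ratios <- function(A, B, D = 0.001) {
  stopifnot(all(A >= 0), all(is.finite(B)), all(B >= 0),
            all(is.finite(D)), all(D >= 0))
  structure(list(A = A, B = B, D = D), class = "model_ratios")
}

#' Dimensionless ratios implied by a rate set
#'
#' @param rates A [transition_rates()] object.
#' @return A [model_ratios()] object with `A`, `B`, `D` computed from the
#'   rates (`Inf` affinity when the exit rate is zero).
#' @export
ratios_from_rates <- function(rates) {
  stopifnot(inherits(rates, "transition_rates"))
  model_ratios(A = if (rates$k_sout == 0) Inf else rates$k_sin / rates$k_sout,
               B = rates$k_sw / rates$k_ws,
               D = if (rates$k_wout == 0) 0 else rates$k_win / rates$k_wout)
}

#' Integrate the four-state transition dynamics
#'
#' Solves the linear system
#' \deqn{dFS/dt = -(k_{SW}+k_{Sin}) FS + k_{WS} FW + k_{Sout} S}
#' \deqn{dFW/dt = k_{SW} FS - (k_{WS}+k_{Win}) FW + k_{Wout} W}
#' \deqn{dS/dt  = k_{Sin} FS - k_{Sout} S}
#' \deqn{dW/dt  = k_{Win} FW - k_{Wout} W}
#' for the occupancy fractions of the four states. Total mass is conserved
#' exactly by the system and to better than 1e-9 by the integrator.
#'
#' @param rates A [transition_rates()] object.
#' @param initial Named numeric `(FS, FW, S, W)`, summing to 1.
#' @param duration Integration time (s).
#' @param dt Output time step (s), default `duration / 200`.
#' @return A data.frame `time`, `FS`, `FW`, `S`, `W`, `pi` where
#'   `pi = (FS + S) - (FW + W)`.
#' @export
solve_transient <- function(rates, initial = c(FS = 0.25, FW = 0.25,
                                               S = 0.25, W = 0.25),
                            duration = 60, dt = duration / 200) {
  stopifnot(inherits(rates, "transition_rates"),
            abs(sum(initial) - 1) < 1e-8, all(initial >= 0))
  deriv <- function(t, y, p) {
    with(p, list(c(
      FS = -(k_sw + k_sin) * y["FS"] + k_ws * y["FW"] + k_sout * y["S"],
      FW = k_sw * y["FS"] - (k_ws + k_win) * y["FW"] + k_wout * y["W"],
      S = k_sin * y["FS"] - k_sout * y["S"],
      W = k_win * y["FW"] - k_wout * y["W"])))
  }
  times <- seq(0, duration, by = dt)
  sol <- deSolve::ode(y = initial[c("FS", "FW", "S", "W")], times = times,
                      func = deriv, parms = rates, method = "lsoda",
                      rtol = 1e-10, atol = 1e-12)
  if (attr(sol, "istate")[1] < 0)
    stop("ODE integration failed; solver diagnostics: ",
         paste(attr(sol, "istate"), collapse = " "))
  out <- as.data.frame(sol)
  out$pi <- (out$FS + out$S) - (out$FW + out$W)
  out
}

#' Equilibrium state of the transition dynamics
#'
#' Stationary occupancy implied by the rates: side-crossing balances
#' (`FS k_sw = FW k_ws`) and each feeding state balances against its free
#' state (`S = A FS`, `W = D FW`), giving `FS : FW : S : W =
#' 1 : B : A : BD` after normalization.
#'
#' @param rates A [transition_rates()] object; `k_ws > 0` required.
#' @return Named numeric `(FS, FW, S, W)` summing to 1.
#' @export
equilibrium_state <- function(rates) {
  stopifnot(inherits(rates, "transition_rates"), rates$k_ws > 0,
            rates$k_sout > 0, rates$k_wout > 0)
  B <- rates$k_sw / rates$k_ws
  A <- rates$k_sin / rates$k_sout
  D <- rates$k_win / rates$k_wout
  v <- c(FS = 1, FW = B, S = A, W = B * D)
  v / sum(v)
}

#' Closed-form equilibrium preference index
#'
#' At stationarity the four-state model yields
#' \deqn{PI = \frac{(1 + A) - B (1 + D)}{(1 + A) + B (1 + D)}}
#' with sugar affinity A, speed ratio B and water affinity D. Limits:
#' `A = Inf` (flies never stop feeding on sugar) gives PI = 1 for any finite
#' B; `B = 0` (flies never leave the sugar side) also gives PI = 1; `A = D`
#' with `B = 1` (no sugar signal at all) gives PI = 0 exactly. All arguments
#' are vectorized.
#'
#' @param ratios A [model_ratios()] object, or the affinity `A` if `B`/`D`
#'   are given separately.
#' @param B,D Speed ratio and water affinity when `ratios` is numeric.
#' @return PI in \[-1, 1\].
#' @examples
#' equilibrium_pi(model_ratios(A = 2, B = 0.5))   # about 0.714
#' @export
equilibrium_pi <- function(ratios, B = NULL, D = 0.001) {
  if (inherits(ratios, "model_ratios")) {
    A <- ratios$A; B <- ratios$B; D <- ratios$D
  } else {
    A <- ratios
    if (is.null(B)) stop("supply B when A is given as a plain number")
  }
  n <- max(length(A), length(B), length(D))
  A <- rep_len(A, n); B <- rep_len(B, n); D <- rep_len(D, n)
  num <- (1 + A) - B * (1 + D)
  den <- (1 + A) + B * (1 + D)
  out <- num / den
  out[is.infinite(A)] <- 1          # absorbing sugar feeding
  out[B == 0 & is.finite(A)] <- 1   # no route off the sugar side
  out
}

#' Affinity calibration constants
#'
#' Parameters linking proboscis-extension (PER) dose-response data to the
#' model's sugar affinity: the PER sigmoid's `slope` and threshold
#' `thrd_per` (on log10 concentration in mM), and the two correction
#' factors that account for the different conditions of the PER and arena
#' experiments — `thrd_shift`, a shift of the threshold along the
#' concentration axis, and `c`, a scale factor on the affinity. The default
#' corrections are `c = 0.83` and `thrd_shift = 3.1`.
#'
#' @param slope,thrd_per PER sigmoid parameters.
#' @param thrd_shift Concentration-axis correction (log10 units).
#' @param c Affinity scale correction, > 0.
#' @return An object of class `affinity_calibration`.
#' @export
affinity_calibration <- function(slope, thrd_per, thrd_shift = 3.1,
                                 c = 0.83) {
  stopifnot(is.finite(slope), is.finite(thrd_per), is.finite(thrd_shift),
            is.finite(c), c > 0)
  structure(list(slope = slope, thrd_per = thrd_per,
                 thrd_shift = thrd_shift, c = c),
            class = "affinity_calibration")
}

#' Transform PER dose-response into sugar affinity
#'
#' Tarsal PER recapitulates sugar affinity. The fitted PER sigmoid is first
#' shifted along the concentration axis by `thrd_shift`, then the extension
#' probability `p` is mapped onto the affinity scale by the odds transform
#' `A = c * p / (1 - p)`, which carries \[0, 1\] onto \[0, Inf\]: `A = 0`
#' when feeding entry never happens and `A = Inf` when feeding exit never
#' happens (p = 1 exactly).
#'
#' @param concentration_mM Sucrose concentrations (mM); 0 maps to `A = 0`.
#' @param calibration An [affinity_calibration()].
#' @return Numeric vector of affinities `A(concentration)`, possibly `Inf`.
#' @export
per_to_affinity <- function(concentration_mM, calibration) {
  stopifnot(inherits(calibration, "affinity_calibration"),
            all(concentration_mM >= 0))
  out <- numeric(length(concentration_mM))
  pos <- concentration_mM > 0
  x <- log10(concentration_mM[pos])
  p <- stats::plogis(calibration$slope *
    (x - (calibration$thrd_per + calibration$thrd_shift)))
  out[pos] <- ifelse(p >= 1, Inf, calibration$c * p / (1 - p))
  out
}

# Inverse of per_to_affinity on the shifted sigmoid; used for round-trip
# checks and for generating synthetic calibration data.
affinity_to_per <- function(A, calibration) {
  A / (calibration$c + A)
}

#' Speed ratio as a function of sucrose concentration
#'
#' The speed ratio `B(conc) = v_sugar(conc) / v_water` is interpolated under
#' the assumption that linear walking velocity is a sigmoidal function of
#' sucrose concentration, anchored at the measured velocities without sugar
#' and with 2 M sucrose: `B(conc) = 1 + (B_2M - 1) * p(conc)` where `p` is a
#' logistic in log10 concentration rising from 0 to 1 and equal to ~1 at
#' 2 M.
#'
#' @param concentration_mM Concentrations to evaluate (mM).
#' @param v_sugar_2M Mean linear velocity on 2 M sucrose (mm/s).
#' @param v_water Mean linear velocity without sugar (mm/s), > 0.
#' @param slope,threshold Parameters of the suppression sigmoid on log10
#'   concentration (mM); defaults place the transition near 100 mM with a
#'   moderate slope, and the 2 M anchor is enforced by rescaling so that
#'   `B(2000 mM) = v_sugar_2M / v_water` exactly.
#' @return Numeric vector `B(concentration)`, equal to 1 at 0 mM.
#' @export
speed_ratio_from_velocity <- function(concentration_mM, v_sugar_2M, v_water,
                                      slope = 2, threshold = 2) {
  if (v_water <= 0) stop("v_water must be positive")
  stopifnot(v_sugar_2M >= 0, all(concentration_mM >= 0))
  b2 <- v_sugar_2M / v_water
  p <- numeric(length(concentration_mM))
  pos <- concentration_mM > 0
  p[pos] <- stats::plogis(slope * (log10(concentration_mM[pos]) - threshold))
  p_anchor <- stats::plogis(slope * (log10(2000) - threshold))
  1 + (b2 - 1) * p / p_anchor
}

#' Calibrate the affinity corrections on control data
#'
#' Determines the free parameters `c` and `thrd_shift` of the
#' PER-to-affinity transform by bounded least squares against observed
#' control preference indices: for each candidate pair, affinities are
#' computed from the control PER sigmoid, combined with the control speed
#' ratios through [equilibrium_pi()], and compared with the observed pooled
#' PIs. Three fixed starting points guard against local minima.
#'
#' @param per_fit A `sigmoid_fit` of PER fraction against log10
#'   concentration (mM) (see [fit_sigmoid()]), or an
#'   [affinity_calibration()] carrying `slope`/`thrd_per`.
#' @param B Speed ratios at the tested concentrations (same length as
#'   `concentration_mM`), e.g. from [speed_ratio_from_velocity()].
#' @param concentration_mM Tested concentrations (mM); at least 3.
#' @param pi_obs Observed pooled PIs at those concentrations.
#' @param D Water affinity (default 0.001).
#' @return An [affinity_calibration()] with fitted `c` and `thrd_shift`,
#'   plus attributes `residuals` and `rss`.
#' @export
calibrate_affinity <- function(per_fit, B, concentration_mM, pi_obs,
                               D = 0.001) {
  if (length(unique(concentration_mM)) < 3)
    stop("calibration needs PI data at >= 3 concentrations")
  if (stats::sd(pi_obs) == 0)
    stop("flat PI curve: calibration constants are unidentifiable")
  slope <- per_fit$slope
  thrd <- if (inherits(per_fit, "affinity_calibration")) per_fit$thrd_per
          else per_fit$threshold
  obj <- function(par) {
    cal <- affinity_calibration(slope, thrd, thrd_shift = par[2],
                                c = exp(par[1]))
    A <- per_to_affinity(concentration_mM, cal)
    sum((equilibrium_pi(model_ratios(A, B, D)) - pi_obs)^2)
  }
  starts <- list(c(log(0.83), 3.1), c(log(0.1), 1), c(log(5), 5))
  best <- NULL
  for (s in starts) {
    fit <- stats::optim(s, obj, method = "L-BFGS-B",
                        lower = c(log(1e-4), -5), upper = c(log(1e3), 8))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  cal <- affinity_calibration(slope, thrd, thrd_shift = best$par[2],
                              c = exp(best$par[1]))
  A <- per_to_affinity(concentration_mM, cal)
  res <- pi_obs - equilibrium_pi(model_ratios(A, B, D))
  attr(cal, "residuals") <- res
  attr(cal, "rss") <- sum(res^2)
  cal
}

#' Predict the preference dose-response curve
#'
#' Evaluates the equilibrium PI at each concentration from the calibrated
#' affinity curve `A(conc)` and speed-ratio curve `B(conc)`.
#'
#' @param concentration_mM Concentrations (mM).
#' @param calibration An [affinity_calibration()].
#' @param B Speed ratios at those concentrations (scalar or vector).
#' @param D Water affinity.
#' @return A data.frame `concentration_mM`, `A`, `B`, `pi`.
#' @export
predict_dose_response <- function(concentration_mM, calibration, B,
                                  D = 0.001) {
  A <- per_to_affinity(concentration_mM, calibration)
  B <- rep_len(B, length(concentration_mM))
  data.frame(concentration_mM = concentration_mM, A = A, B = B,
             pi = equilibrium_pi(model_ratios(A, B, D)))
}

#' Simulate theoretical mutants of the preference model
#'
#' Dissects the two behavioural channels by re-predicting the dose-response
#' with one or both of them silenced: the affinity mutant has `A = D`
#' (set to 0.001, i.e. sugar tastes like water), the suppression mutant has
#' `B = 1` (sugar no longer slows walking), and the double mutant has both.
#' Only the double mutant is fully sugar-blind: its PI is exactly 0 at every
#' concentration, while each single mutant retains preference through the
#' surviving channel.
#'
#' @param concentration_mM Concentrations (mM).
#' @param calibration Calibrated [affinity_calibration()] of the wild type.
#' @param B Wild-type speed ratios at those concentrations.
#' @param D Water affinity; also the affinity assigned to the affinity
#'   mutant (default 0.001).
#' @return A data.frame `concentration_mM`, `genotype` (`"wild_type"`,
#'   `"affinity_mutant"`, `"suppression_mutant"`, `"double_mutant"`) and
#'   `pi`.
#' @export
simulate_mutants <- function(concentration_mM, calibration, B, D = 0.001) {
  A_wt <- per_to_affinity(concentration_mM, calibration)
  B <- rep_len(B, length(concentration_mM))
  curves <- list(
    wild_type = equilibrium_pi(model_ratios(A_wt, B, D)),
    affinity_mutant = equilibrium_pi(model_ratios(rep(D, length(B)), B, D)),
    suppression_mutant = equilibrium_pi(model_ratios(A_wt, rep(1, length(B)), D)),
    double_mutant = equilibrium_pi(model_ratios(rep(D, length(B)),
                                                rep(1, length(B)), D)))
  data.frame(
    concentration_mM = rep(concentration_mM, 4),
    genotype = rep(names(curves), each = length(concentration_mM)),
    pi = unlist(curves, use.names = FALSE))
}

#' Preference surface over affinity and speed ratios
#'
#' Equilibrium PI on a grid of affinity and speed ratios, exposing the
#' affinity axis both as raw `A` and as the `A/D` ratio (with D fixed the
#' two differ by a constant factor).
#'
#' @param A,B Grid vectors of affinities and speed ratios.
#' @param D Water affinity.
#' @return A data.frame `A`, `A_over_D`, `B`, `pi` (full grid).
#' @export
preference_surface <- function(A, B, D = 0.001) {
  g <- expand.grid(A = A, B = B)
  data.frame(A = g$A, A_over_D = g$A / D, B = g$B,
             pi = equilibrium_pi(model_ratios(g$A, g$B, D)))
}
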