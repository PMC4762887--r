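rand_rates <- function() {
  transition_rates(k_sw = runif(1, 0.02, 1), k_ws = runif(1, 0.02, 1),
                   k_sin = runif(1, 0.02, 1), k_sout = runif(1, 0.02, 1),
                   k_win = runif(1, 0.02, 1), k_wout = runif(1, 0.02, 1))
}

test_that("transient dynamics conserve mass and honour trivial symmetries", {
  # frozen system stays put
  r0 <- transition_rates(0, 0, 0, 0, 0, 0)
  tr <- solve_transient(r0, duration = 10)
  expect_equal(tr$FS, rep(0.25, nrow(tr)))
  expect_equal(tr$W, rep(0.25, nrow(tr)))

  # fully symmetric rates and initial state: the two sides stay identical
  rs <- transition_rates(k_sw = 0.3, k_ws = 0.3, k_sin = 0.2, k_sout = 0.1,
                         k_win = 0.2, k_wout = 0.1)
  tr2 <- solve_transient(rs, duration = 50)
  expect_equal(tr2$FS, tr2$FW, tolerance = 1e-8)
  expect_equal(tr2$S, tr2$W, tolerance = 1e-8)
  expect_equal(tr2$pi, rep(0, nrow(tr2)), tolerance = 1e-8)

  set.seed(1)
  for (i in 1:5) {
    tr3 <- solve_transient(rand_rates(), duration = 100)
    expect_lt(max(abs(rowSums(tr3[, c("FS", "FW", "S", "W")]) - 1)), 1e-9)
    expect_true(all(tr3$pi >= -1 - 1e-12 & tr3$pi <= 1 + 1e-12))
  }
})

test_that("the closed-form equilibrium PI equals the ODE steady state", {
  # the documented spot value, via the ODE route
  r <- transition_rates(k_sw = 0.25, k_ws = 0.5, k_sin = 0.4, k_sout = 0.2,
                        k_win = 2e-4, k_wout = 0.2)
  long <- solve_transient(r, duration = 4000)
  expect_equal(tail(long$pi, 1), 0.7140, tolerance = 1e-4)
  expect_equal(equilibrium_pi(model_ratios(A = 2, B = 0.5, D = 0.001)),
               tail(long$pi, 1), tolerance = 1e-6)

  set.seed(42)
  for (i in 1:100) {
    r <- rand_rates()
    t_end <- 60 / min(unlist(r))
    long <- solve_transient(r, duration = t_end, dt = t_end / 50)
    expect_equal(equilibrium_pi(ratios_from_rates(r)), tail(long$pi, 1),
                 tolerance = 1e-6)
    expect_equal(unname(tail(long[, c("FS", "FW", "S", "W")], 1)),
                 as.data.frame(t(equilibrium_state(r))),
                 tolerance = 1e-6, ignore_attr = TRUE)
  }
})

test_that("equilibrium PI limits and symmetries hold", {
  expect_equal(equilibrium_pi(model_ratios(A = 0.001, B = 1, D = 0.001)), 0)
  expect_equal(equilibrium_pi(model_ratios(A = 5, B = 1, D = 5)), 0)
  expect_equal(equilibrium_pi(model_ratios(A = Inf, B = 0.7)), 1)
  expect_equal(equilibrium_pi(model_ratios(A = 3, B = 0)), 1)
  # vectorized, bounded, monotone up in A and down in B (for A > D)
  A <- seq(0.01, 50, length.out = 40)
  piA <- equilibrium_pi(model_ratios(A, B = 0.5))
  expect_true(all(diff(piA) > 0))
  B <- seq(0.05, 3, length.out = 40)
  piB <- equilibrium_pi(model_ratios(A = 2, B = B))
  expect_true(all(diff(piB) < 0))
  expect_true(all(abs(c(piA, piB)) <= 1))
})

test_that("affinity transform honours its boundary semantics", {
  cal <- affinity_calibration(slope = 1.6, thrd_per = 0.1)
  conc <- c(0, 1, 10, 100, 1000, 2000)
  A <- per_to_affinity(conc, cal)
  expect_equal(A[1], 0)              # no feeding entry without sugar
  expect_true(all(diff(A) > 0))      # monotone in concentration
  expect_true(all(is.finite(A)))
  # PER -> 1 drives A -> Inf and hence PI -> 1
  sat <- affinity_calibration(slope = 50, thrd_per = -3, thrd_shift = 0)
  A_sat <- per_to_affinity(1e6, sat)
  expect_gt(equilibrium_pi(model_ratios(A_sat, B = 0.5)), 0.999)
  # with A = 0 everywhere the PI is set by B and D alone
  expect_equal(equilibrium_pi(model_ratios(0, B = 1, D = 0)), 0)
})

test_that("affinity round-trips through the inverse transform", {
  cal <- affinity_calibration(slope = 1.4, thrd_per = 0.3,
                              thrd_shift = 3.1, c = 0.83)
  conc <- 10^seq(0, 3.5, length.out = 12)
  A_true <- per_to_affinity(conc, cal)
  # generate PER fractions on the shifted axis from the inverse transform,
  # refit the sigmoid, and re-derive the affinity
  p <- flypref:::affinity_to_per(A_true, cal)
  refit <- fit_sigmoid(log10(conc), p, floor = 0, ceiling = 1)
  cal2 <- affinity_calibration(refit$slope,
                               refit$threshold - cal$thrd_shift,
                               cal$thrd_shift, cal$c)
  A_back <- per_to_affinity(conc, cal2)
  expect_lt(max(abs(A_back - A_true) / A_true), 1e-3)
})

test_that("speed ratios interpolate between the anchors", {
  conc <- c(0, 100, 500, 1000, 2000)
  B <- speed_ratio_from_velocity(conc, v_sugar_2M = 2.5, v_water = 5)
  expect_equal(B[1], 1)
  expect_equal(B[length(B)], 0.5, tolerance = 1e-9)
  expect_true(all(diff(B) < 0))
  B_flat <- speed_ratio_from_velocity(conc, 5, 5)
  expect_equal(B_flat, rep(1, 5))
  expect_error(speed_ratio_from_velocity(conc, 2, 0), "positive")
})

test_that("calibration recovers known correction factors from control data", {
  slope <- 1.5; thrd_per <- 0.2
  truth_cal <- affinity_calibration(slope, thrd_per, thrd_shift = 3.1,
                                    c = 0.83)
  conc <- c(100, 250, 500, 1000, 2000)
  B <- speed_ratio_from_velocity(conc, 2.5, 5)
  pi_obs <- equilibrium_pi(model_ratios(per_to_affinity(conc, truth_cal),
                                        B, 0.001))
  per_fit <- affinity_calibration(slope, thrd_per)  # carries slope/thrd
  cal <- calibrate_affinity(per_fit, B, conc, pi_obs)
  expect_lt(abs(cal$c - 0.83) / 0.83, 0.05)
  expect_lt(abs(cal$thrd_shift - 3.1) / 3.1, 0.05)
  expect_lt(attr(cal, "rss"), 1e-10)
  expect_error(calibrate_affinity(per_fit, 0.5, 500, 0.6),
               "3 concentrations")
  expect_error(calibrate_affinity(per_fit, B, conc, rep(0.5, 5)),
               "unidentifiable")
})

test_that("dose-response predictions respect the channel structure", {
  cal <- affinity_calibration(1.5, 0.2)
  conc <- c(10, 100, 500, 1000, 2000)
  # increasing A with fixed B < 1: PI strictly increasing
  dr <- predict_dose_response(conc, cal, B = 0.6)
  expect_true(all(diff(dr$pi) > 0))
  expect_equal(dr$pi, equilibrium_pi(model_ratios(dr$A, dr$B, 0.001)))
  # B == 1 with A from PER: PI > 0 wherever A > D
  dr2 <- predict_dose_response(conc, cal, B = 1)
  expect_true(all(dr2$pi[dr2$A > 0.001] > 0))
})

test_that("only the double mutant is fully sugar-blind", {
  cal <- affinity_calibration(1.5, 0.2)
  conc <- c(100, 500, 1000, 2000)
  B <- speed_ratio_from_velocity(conc, 2.5, 5)
  mut <- simulate_mutants(conc, cal, B)
  dbl <- mut[mut$genotype == "double_mutant", ]
  expect_equal(dbl$pi, rep(0, 4))
  aff <- mut[mut$genotype == "affinity_mutant", ]
  sup <- mut[mut$genotype == "suppression_mutant", ]
  wt <- mut[mut$genotype == "wild_type", ]
  expect_true(all(aff$pi > 0))   # suppression channel still active (B < 1)
  expect_true(all(sup$pi > 0))   # affinity channel still active (A > D)
  expect_true(all(wt$pi >= pmax(aff$pi, sup$pi) - 1e-12))
})

test_that("the preference surface reports both affinity conventions", {
  surf <- preference_surface(A = c(0.001, 0.1, 1), B = c(0.5, 1), D = 0.001)
  expect_equal(nrow(surf), 6)
  expect_equal(surf$A_over_D, surf$A / 0.001)
  # affinity dependence dominates speed dependence on this grid
  dA <- abs(diff(equilibrium_pi(model_ratios(c(0.1, 1), 1))))
  dB <- abs(diff(equilibrium_pi(model_ratios(0.1, c(0.5, 1)))))
  expect_true(is.finite(dA) && is.finite(dB))
})
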