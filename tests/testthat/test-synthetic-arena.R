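test_that("degenerate simulations behave as documented", {
  cfg <- arena_config(duration = 2)
  expect_equal(nrow(simulate_agents(agent_dynamics(), cfg, 0)), 0)

  frozen <- agent_dynamics(k_sin = 0, k_sout = 0, k_win = 0, k_wout = 0,
                           speed_sugar = 0, speed_water = 0, turn_sd = 0)
  truth <- simulate_agents(frozen, cfg, 5, seed = 11)
  for (i in 1:5) {
    tr <- truth[truth$id == i, ]
    expect_equal(diff(range(tr$x_mm)), 0)
    expect_equal(diff(range(tr$y_mm)), 0)
    expect_true(all(tr$state == "free_walk"))
  }
})

test_that("invalid dynamics parameters are rejected", {
  expect_error(agent_dynamics(k_sin = -0.1), "non-negative")
  expect_error(agent_dynamics(speed_water = NaN), "finite")
})

test_that("simulation is bit-reproducible under a fixed seed", {
  cfg <- arena_config(duration = 3)
  a <- simulate_agents(agent_dynamics(), cfg, 8, seed = 99)
  b <- simulate_agents(agent_dynamics(), cfg, 8, seed = 99)
  expect_identical(a, b)
  c <- simulate_agents(agent_dynamics(), cfg, 8, seed = 100)
  expect_false(identical(a$x_mm, c$x_mm))
})

test_that("agents never leave the disc and feeding agents are stationary", {
  cfg <- arena_config(duration = 30)
  dyn <- agent_dynamics(k_sin = 0.5, k_sout = 0.2, speed_water = 20,
                        turn_sd = 40)
  truth <- simulate_agents(dyn, cfg, 12, seed = 5)
  r <- sqrt(truth$x_mm^2 + truth$y_mm^2)
  expect_true(all(r <= cfg$diameter / 2 - cfg$wall_margin + 1e-9))
  # a fly feeding in consecutive frames has not moved
  by_id <- split(truth, truth$id)
  for (tr in by_id) {
    feeding_run <- which(tr$state[-1] == "feeding" &
                           tr$state[-nrow(tr)] == "feeding")
    if (length(feeding_run)) {
      expect_equal(tr$x_mm[feeding_run + 1], tr$x_mm[feeding_run])
      expect_equal(tr$y_mm[feeding_run + 1], tr$y_mm[feeding_run])
    }
  }
  expect_true(all(truth$orientation_deg >= 0 & truth$orientation_deg < 180))
  expect_equal(truth$orientation_deg, truth$heading_deg %% 180)
})

test_that("wall reflection preserves step length", {
  # a straight walker aimed at the wall: every step length must equal
  # speed * dt even across reflections
  cfg <- arena_config(duration = 20)
  dyn <- agent_dynamics(k_sin = 0, k_sout = 0, k_win = 0, k_wout = 0,
                        speed_sugar = 12, speed_water = 12, turn_sd = 0)
  truth <- simulate_agents(dyn, cfg, 3, seed = 2)
  for (i in 1:3) {
    tr <- truth[truth$id == i, ]
    # chord length through a reflection is <= free step, but the total
    # path (in + out of the wall) preserves length; check free steps only
    step <- sqrt(diff(tr$x_mm)^2 + diff(tr$y_mm)^2)
    r_next <- sqrt(tr$x_mm^2 + tr$y_mm^2)[-1]
    free <- r_next < cfg$diameter / 2 - cfg$wall_margin - 12 / cfg$fps
    expect_true(all(abs(step[free] - 12 / cfg$fps) < 1e-9))
  }
})

test_that("long-run state occupancy matches the transition-rate equilibrium", {
  cfg <- arena_config(duration = 400)
  dyn <- agent_dynamics(k_sin = 0.4, k_sout = 0.2, k_win = 2e-4,
                        k_wout = 0.2, speed_sugar = 4, speed_water = 5)
  truth <- simulate_agents(dyn, cfg, 150, seed = 7)
  oc <- occupancy_pi(truth, burn_in = 0.25)
  closed <- equilibrium_pi(model_ratios(A = 0.4 / 0.2, B = 4 / 5, D = 0.001))
  expect_lt(abs(oc$pi_mean - closed), 3 * oc$se)
  # feeding occurs essentially only on the sugar side
  feed <- truth[truth$state == "feeding", ]
  expect_gt(mean(feed$side == "sugar"), 0.99)
})

test_that("rendering matches its contract on degenerate inputs", {
  cfg <- arena_config(duration = 1)
  empty <- posed_truth(1, 1, 0)[0, ]
  stk <- render_frames(empty, cfg, noise_sd = 0, seed = 1)
  expect_equal(length(stk$frames), 0)

  # zero agents in a listed frame: frame is exactly the background
  one <- posed_truth(50, 0, 0)  # outside the arena
  expect_error(render_frames(one, cfg, noise_sd = 0), "outside")

  stk <- posed_stack(0, 0, 30)
  expect_equal(length(stk$frames), 1)
  # away from the body the noiseless frame is exactly the background
  delta <- abs(stk$frames[[1]] - stk$background)
  n <- stk$geometry$n_px; ctr <- stk$geometry$centre
  far <- outer(seq_len(n), seq_len(n),
               function(r, c) (r - ctr)^2 + (c - ctr)^2) >
    (3 / cfg$mm_per_pixel)^2
  expect_equal(max(delta[far]), 0)
  lab <- binarize_and_clean(stk$frames[[1]], stk$background)
  expect_equal(max(lab), 1)
  det <- fit_ellipses(label_pixel_sets(lab), stk$geometry, 1L)
  expect_lt(abs(det$x_mm), 0.05)
  expect_lt(abs(det$y_mm), 0.05)
})

test_that("rendering is reproducible and writes/reads PNG losslessly enough", {
  cfg <- arena_config(duration = 1)
  tt <- posed_truth(c(-10, 10), c(5, -5), c(20, 150))
  s1 <- render_frames(tt, cfg, noise_sd = 0.03, seed = 4)
  s2 <- render_frames(tt, cfg, noise_sd = 0.03, seed = 4)
  expect_identical(s1$frames, s2$frames)

  dir <- withr::local_tempdir()
  write_frame_stack(s1, dir)
  back <- read_frame_stack(dir, cfg$mm_per_pixel)
  expect_equal(length(back$frames), 1)
  expect_lt(max(abs(back$frames[[1]] - s1$frames[[1]])), 1 / 255)
  expect_equal(back$frame_index, 1L)
})

test_that("close flies render as one merged connected component", {
  cfg <- arena_config(duration = 1)
  # centre separation 0.7 mm < minor axis (0.9 mm): must merge
  stk <- posed_stack(c(-0.35, 0.35), c(0, 0), c(0, 0))
  lab <- binarize_and_clean(stk$frames[[1]], stk$background)
  expect_equal(max(lab), 1)
  # and well-separated flies do not
  stk2 <- posed_stack(c(-5, 5), c(0, 0), c(0, 0))
  expect_equal(max(binarize_and_clean(stk2$frames[[1]], stk2$background)), 2)
})
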