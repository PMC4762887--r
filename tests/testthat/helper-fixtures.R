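# Shared fixtures, built in code at test time.

# Ground-truth table for hand-placed flies in a single frame.
posed_truth <- function(x, y, orientation, frame = 1L) {
  data.frame(frame = frame, time = (frame - 1) / 10, id = seq_along(x),
             x_mm = x, y_mm = y, heading_deg = orientation %% 360,
             orientation_deg = orientation %% 180,
             state = "free_walk", side = "sugar")
}

# Noiseless single-frame stack with flies at given poses.
posed_stack <- function(x, y, orientation, config = arena_config(),
                        noise_sd = 0, ...) {
  render_frames(posed_truth(x, y, orientation), config,
                noise_sd = noise_sd, ...)
}

# Brute-force minimal-total-distance assignment between two detection sets
# (enumerates every injective mapping); the independent oracle for the
# greedy matcher on tiny cases.
brute_force_match <- function(det_t, det_t1, max_dist = Inf) {
  n0 <- nrow(det_t); n1 <- nrow(det_t1)
  k <- min(n0, n1)
  dmat <- sqrt(outer(det_t$x_mm, det_t1$x_mm, "-")^2 +
                 outer(det_t$y_mm, det_t1$y_mm, "-")^2)
  best <- NULL; best_cost <- Inf
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    out
  }
  from <- utils::combn(seq_len(n0), k, simplify = FALSE)
  for (f in from) for (p in perms(seq_len(n1))) {
    to <- p[seq_len(k)]
    cost <- sum(dmat[cbind(f, to)])
    if (cost < best_cost) { best_cost <- cost; best <- cbind(i = f, j = to) }
  }
  keep <- dmat[best] <= max_dist
  best[keep, , drop = FALSE]
}

# Default dynamics/arena used across end-to-end tests: the standard 76 mm
# assay filmed at 10 fps, hungry flies walking ~5 mm/s on water and half
# that on 2 M sucrose (speed ratio 0.5), sugar affinity 2, water affinity
# 0.001.
study_dynamics <- function(...) agent_dynamics(...)
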