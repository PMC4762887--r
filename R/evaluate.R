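#' Match detections to ground-truth agents
#'
#' Greedy nearest-neighbour assignment of detections to ground-truth
#' positions within each frame, used to benchmark the tracker on synthetic
#' video. Each detection is assigned to at most one ground-truth agent and
#' vice versa; assignments farther than `max_dist` mm are discarded.
#'
#' @param detections Detection table (see [detect_flies()]).
#' @param truth Ground-truth table from [simulate_agents()].
#' @param max_dist Assignment gate, mm (default 2).
#' @return `detections` with added columns `truth_id`, `position_error_mm`
#'   and `orientation_error_deg` (minimal mod-180 difference); unassigned
#'   detections carry `NA`.
#' @export
match_truth <- function(detections, truth, max_dist = 2) {
  detections$truth_id <- NA_integer_
  detections$position_error_mm <- NA_real_
  detections$orientation_error_deg <- NA_real_
  for (f in unique(detections$frame)) {
    di <- which(detections$frame == f)
    tr <- truth[truth$frame == f, , drop = FALSE]
    if (nrow(tr) == 0) next
    dmat <- sqrt(outer(detections$x_mm[di], tr$x_mm, "-")^2 +
                   outer(detections$y_mm[di], tr$y_mm, "-")^2)
    availd <- rep(TRUE, length(di)); availt <- rep(TRUE, nrow(tr))
    repeat {
      sub <- dmat
      sub[!availd, ] <- Inf; sub[, !availt] <- Inf
      k <- which.min(sub)
      if (!length(k) || !is.finite(sub[k]) || sub[k] > max_dist) break
      a <- ((k - 1) %% length(di)) + 1
      b <- ((k - 1) %/% length(di)) + 1
      availd[a] <- FALSE; availt[b] <- FALSE
      row <- di[a]
      detections$truth_id[row] <- tr$id[b]
      detections$position_error_mm[row] <- dmat[a, b]
      detections$orientation_error_deg[row] <-
        abs(angle_diff_mod180(tr$orientation_deg[b],
                              detections$orientation_deg[row]))
    }
  }
  detections
}

#' Benchmark tracking accuracy against ground truth
#'
#' Computes the three headline accuracy figures of the tracker on synthetic
#' video: the identity-assignment error rate over consecutive-frame pairs,
#' and the mean absolute orientation and centroid errors over detections.
#' A track step counts as an identity error when its two detections map to
#' different ground-truth agents; steps with an unassigned endpoint are
#' ignored.
#'
#' @param tracks A `fly_tracks` object from [track_stack()].
#' @param truth The generating ground-truth table.
#' @param max_dist Gate for detection/truth assignment, mm.
#' @return A list: `n_pairs`, `n_errors`, `identity_error_rate` (fraction),
#'   `n_detections`, `mean_orientation_error_deg`,
#'   `mean_position_error_mm` and the annotated `detections` table.
#' @export
evaluate_tracking <- function(tracks, truth, max_dist = 2) {
  det <- match_truth(tracks$detections, truth, max_dist)
  st <- tracks$steps
  id_t <- det$truth_id[st$det_i]
  id_t1 <- det$truth_id[st$det_j]
  ok <- !is.na(id_t) & !is.na(id_t1)
  n_pairs <- sum(ok)
  n_err <- sum(id_t[ok] != id_t1[ok])
  matched <- !is.na(det$truth_id)
  list(n_pairs = n_pairs, n_errors = n_err,
       identity_error_rate = if (n_pairs > 0) n_err / n_pairs else NA_real_,
       n_detections = sum(matched),
       mean_orientation_error_deg =
         mean(det$orientation_error_deg[matched]),
       mean_position_error_mm = mean(det$position_error_mm[matched]),
       detections = det)
}

#' Benchmark the tracker on synthetic ground-truthed videos
#'
#' Simulates one or more arena videos under the standard assay conditions
#' (76 mm arena, side-dependent walking speeds, rendering noise), runs the
#' full tracking pipeline on each and pools the accuracy figures across
#' videos: identity-assignment error rate over all consecutive-frame fly
#' pairs, and mean absolute orientation / centroid errors over all
#' ground-truth-matched detections.
#'
#' @param seeds One integer seed per video.
#' @param n_flies Flies per video (default 15).
#' @param duration Video duration in seconds (default 5).
#' @param dynamics An [agent_dynamics()] template; its seed is replaced per
#'   video.
#' @param config An [arena_config()].
#' @param tracker A [tracker_config()].
#' @param noise_sd Rendering noise SD.
#' @return A list: `n_pairs`, `n_errors`, `identity_error_rate`,
#'   `n_detections`, `mean_orientation_error_deg`,
#'   `mean_position_error_mm`, plus `per_video` with the raw evaluations.
#' @export
benchmark_tracker <- function(seeds, n_flies = 15, duration = 5,
                              dynamics = agent_dynamics(),
                              config = arena_config(duration = duration),
                              tracker = tracker_config(), noise_sd = 0.03) {
  evs <- lapply(seeds, function(s) {
    dynamics$seed <- as.integer(s)
    truth <- simulate_agents(dynamics, config, n_flies)
    stk <- render_frames(truth, config, noise_sd = noise_sd,
                         seed = as.integer(s) + 1L)
    tracks <- track_stack(stk, tracker, fps = config$fps)
    ev <- evaluate_tracking(tracks, truth)
    ev$detections <- NULL
    ev
  })
  n_pairs <- sum(vapply(evs, `[[`, numeric(1), "n_pairs"))
  n_err <- sum(vapply(evs, `[[`, numeric(1), "n_errors"))
  n_det <- vapply(evs, `[[`, numeric(1), "n_detections")
  list(n_pairs = n_pairs, n_errors = n_err,
       identity_error_rate = n_err / n_pairs,
       n_detections = sum(n_det),
       mean_orientation_error_deg = sum(n_det * vapply(
         evs, `[[`, numeric(1), "mean_orientation_error_deg")) / sum(n_det),
       mean_position_error_mm = sum(n_det * vapply(
         evs, `[[`, numeric(1), "mean_position_error_mm")) / sum(n_det),
       per_video = evs)
}
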