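# Minimal signed mod-180 angle difference, in (-90, 90]. Ellipse orientation
# is an axis, not a direction, so 178 -> 2 degrees is a +4 degree turn.
angle_diff_mod180 <- function(from, to) {
  d <- (to - from) %% 180
  ifelse(d > 90, d - 180, d)
}

#' Pair detections across two consecutive frames
#'
#' Greedy closest-neighbour association: among all detection pairs between
#' the two frames, repeatedly take the pair with the smallest centroid
#' distance and remove both members from the candidate set, until the set is
#' empty. Pairs whose displacement exceeds `max_pair_distance` (mm) or whose
#' minimal mod-180 orientation change exceeds `max_pair_angle` (degrees) are
#' rejected and their members reported unmatched. Exact distance ties are
#' broken by lower detection index, so the pairing is deterministic.
#'
#' @param det_t,det_t1 Detection data.frames (see [detect_flies()]) for
#'   frames t and t+1.
#' @param config A [tracker_config()] supplying the two gates.
#' @return A list with `pairs` (data.frame `i`, `j`, `distance_mm`,
#'   `delta_angle_deg` indexing rows of `det_t` / `det_t1`), and
#'   `unmatched_t`, `unmatched_t1` (integer row indices).
#' @export
match_frames <- function(det_t, det_t1, config = tracker_config()) {
  n0 <- nrow(det_t); n1 <- nrow(det_t1)
  empty <- data.frame(i = integer(0), j = integer(0),
                      distance_mm = numeric(0), delta_angle_deg = numeric(0))
  if (n0 == 0 || n1 == 0)
    return(list(pairs = empty, unmatched_t = seq_len(n0),
                unmatched_t1 = seq_len(n1)))
  dmat <- sqrt(outer(det_t$x_mm, det_t1$x_mm, "-")^2 +
                 outer(det_t$y_mm, det_t1$y_mm, "-")^2)
  avail0 <- rep(TRUE, n0); avail1 <- rep(TRUE, n1)
  pairs <- empty
  repeat {
    if (!any(avail0) || !any(avail1)) break
    sub <- dmat
    sub[!avail0, ] <- Inf
    sub[, !avail1] <- Inf
    k <- which.min(sub)  # which.min returns the first (lowest index) minimum
    if (!is.finite(sub[k])) break
    i <- ((k - 1) %% n0) + 1
    j <- ((k - 1) %/% n0) + 1
    avail0[i] <- FALSE; avail1[j] <- FALSE
    da <- angle_diff_mod180(det_t$orientation_deg[i],
                            det_t1$orientation_deg[j])
    if (dmat[i, j] <= config$max_pair_distance &&
        abs(da) <= config$max_pair_angle) {
      pairs <- rbind(pairs, data.frame(i = i, j = j,
                                       distance_mm = dmat[i, j],
                                       delta_angle_deg = da))
    }
  }
  list(pairs = pairs,
       unmatched_t = which(!seq_len(n0) %in% pairs$i),
       unmatched_t1 = which(!seq_len(n1) %in% pairs$j))
}

#' Compute per-step kinematics from paired detections
#'
#' @param steps Data.frame with columns `dx_mm`, `dy_mm` (or `distance_mm`)
#'   and `delta_angle_deg`.
#' @param fps Frame rate (frames per second), > 0.
#' @return `steps` with added `v_mm_s` (linear velocity), `w_deg_s`
#'   (signed angular velocity) and `abs_w_deg_s`.
#' @export
compute_kinematics <- function(steps, fps) {
  stopifnot(fps > 0)
  d <- if ("distance_mm" %in% names(steps)) steps$distance_mm
       else sqrt(steps$dx_mm^2 + steps$dy_mm^2)
  steps$v_mm_s <- d * fps
  steps$w_deg_s <- steps$delta_angle_deg * fps
  steps$abs_w_deg_s <- abs(steps$w_deg_s)
  steps
}

#' Track a frame stack end to end
#'
#' Runs [detect_flies()] on every frame and [match_frames()] on every
#' consecutive frame pair, returning per-frame detections and per-pair track
#' steps with kinematics.
#'
#' @param stack A `frame_stack` (from [render_frames()] or
#'   [read_frame_stack()]).
#' @param config A [tracker_config()].
#' @param fps Frame rate used for velocities; defaults to 10 if the stack
#'   carries no rate.
#' @return A list of class `fly_tracks`: `detections` (one data.frame, all
#'   frames), `steps` (data.frame with `frame_t`, `frame_t1`, `det_i`,
#'   `det_j` row indices into `detections`, displacement, angle change and
#'   velocities) and `config`.
#' @export
track_stack <- function(stack, config = tracker_config(), fps = 10) {
  stopifnot(inherits(stack, "frame_stack"))
  dets <- vector("list", length(stack$frames))
  for (k in seq_along(stack$frames)) {
    dets[[k]] <- detect_flies(stack$frames[[k]], stack$background,
                              stack$geometry, config,
                              frame_index = stack$frame_index[k])
  }
  detections <- do.call(rbind, dets)
  offsets <- cumsum(c(0, vapply(dets, nrow, integer(1))))
  steps <- list()
  for (k in seq_len(length(dets) - 1)) {
    # only truly consecutive frames form a step
    if (stack$frame_index[k + 1] != stack$frame_index[k] + 1) next
    m <- match_frames(dets[[k]], dets[[k + 1]], config)
    if (nrow(m$pairs) == 0) next
    p <- m$pairs
    steps[[length(steps) + 1]] <- data.frame(
      frame_t = stack$frame_index[k],
      frame_t1 = stack$frame_index[k + 1],
      det_i = offsets[k] + p$i,
      det_j = offsets[k + 1] + p$j,
      dx_mm = dets[[k + 1]]$x_mm[p$j] - dets[[k]]$x_mm[p$i],
      dy_mm = dets[[k + 1]]$y_mm[p$j] - dets[[k]]$y_mm[p$i],
      distance_mm = p$distance_mm,
      delta_angle_deg = p$delta_angle_deg)
  }
  steps <- if (length(steps)) do.call(rbind, steps) else
    data.frame(frame_t = integer(0), frame_t1 = integer(0),
               det_i = integer(0), det_j = integer(0), dx_mm = numeric(0),
               dy_mm = numeric(0), distance_mm = numeric(0),
               delta_angle_deg = numeric(0))
  steps <- compute_kinematics(steps, fps)
  structure(list(detections = detections, steps = steps, config = config),
            class = "fly_tracks")
}

#' @export
print.fly_tracks <- function(x, ...) {
  cat(sprintf("fly_tracks: %d detections over %d frames, %d track steps\n",
              nrow(x$detections), length(unique(x$detections$frame)),
              nrow(x$steps)))
  invisible(x)
}
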