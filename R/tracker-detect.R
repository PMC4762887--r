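#' Score how likely each particle is to be a single fly
#'
#' Fits a robust Gaussian reference (median and MAD) to the particles'
#' bounding-box diagonals and eccentricities and evaluates each particle's
#' likelihood under it. Particles in the extreme tail are classed `"low"`:
#' they are either flies segmented at an unsuitable threshold or several
#' flies merged into one blob, and are handed to [resolve_merged()].
#'
#' @param particles Data.frame from [measure_particles()].
#' @param cutoff Tail probability for the low-likelihood class (default
#'   0.01): a particle is `"low"` if its squared robust z-scores exceed the
#'   `1 - cutoff` quantile of a chi-squared(2) reference.
#' @return `particles` with added columns `likelihood` (Gaussian density)
#'   and `class` (`"high"`/`"low"`). With fewer than 4 particles or a
#'   degenerate (zero-spread) reference, all particles are classed high with
#'   a warning.
#' @export
score_likelihood <- function(particles, cutoff = 0.01) {
  stopifnot(nrow(particles) >= 1)
  d <- particles$bbox_diagonal
  e <- particles$eccentricity
  md <- stats::median(d); me <- stats::median(e)
  # bbox diagonals are quantized, so the MAD can collapse to zero in frames
  # with many ties; fall back to the SD before declaring degeneracy
  sd_d <- stats::mad(d); sd_e <- stats::mad(e)
  if (sd_d == 0) sd_d <- stats::sd(d)
  if (sd_e == 0) sd_e <- stats::sd(e)
  if (nrow(particles) < 4 || sd_d == 0 || sd_e == 0) {
    if (nrow(particles) >= 4)
      warning("degenerate particle reference; classifying all as high")
    particles$likelihood <- rep(1, nrow(particles))
    particles$class <- "high"
    return(particles)
  }
  z2 <- ((d - md) / sd_d)^2 + ((e - me) / sd_e)^2
  particles$likelihood <- exp(-z2 / 2) / (2 * pi * sd_d * sd_e)
  particles$class <- ifelse(z2 > stats::qchisq(1 - cutoff, df = 2),
                            "low", "high")
  particles
}

#' Split a merged blob by local iterative re-thresholding
#'
#' Estimates the number of flies inside a low-likelihood particle as its
#' area divided by the mean single-fly area (rounded, minimum 1), then
#' re-binarizes the particle's local image region at progressively stricter
#' thresholds — stepping by 1/`max_iterations` of the local intensity range —
#' until the local particle count equals the estimate. If the count is never
#' matched within `max_iterations` iterations the particle is excluded and
#' contributes no detections in this frame.
#'
#' @param frame,background Full grayscale images.
#' @param particle One row of a scored particle table (class `"low"`).
#' @param labels Label matrix the particle came from.
#' @param mean_single_area Mean area (px) of high-likelihood particles.
#' @param config A [tracker_config()].
#' @return A data.frame of sub-particles measured in the full-image pixel
#'   frame (same columns as [measure_particles()], plus `pixels`, a list
#'   column of pixel indices), or `NULL` if the particle was excluded.
#' @export
resolve_merged <- function(frame, background, particle, labels,
                           mean_single_area, config = tracker_config()) {
  stopifnot(mean_single_area > 0)
  est <- max(1L, as.integer(round(particle$area / mean_single_area)))
  idx <- which(labels == particle$label)
  rr <- range(((idx - 1) %% nrow(labels)) + 1)
  cc <- range(((idx - 1) %/% nrow(labels)) + 1)
  pad <- 2L
  rsel <- max(1, rr[1] - pad):min(nrow(frame), rr[2] + pad)
  csel <- max(1, cc[1] - pad):min(ncol(frame), cc[2] + pad)
  local <- frame[rsel, csel, drop = FALSE]
  local_bg <- background[rsel, csel, drop = FALSE]
  lo <- min(local); hi <- config$threshold
  step <- (hi - lo) / config$max_iterations
  if (step <= 0) return(NULL)
  for (i in seq_len(config$max_iterations)) {
    thr <- hi - i * step
    if (thr <= lo) break
    lab <- binarize_and_clean(local, local_bg, threshold = thr,
                              morphology_radius = config$morphology_radius)
    parts <- measure_particles(lab, min_px = config$min_particle_px)
    if (nrow(parts) == est) {
      parts$row <- parts$row + rsel[1] - 1
      parts$col <- parts$col + csel[1] - 1
      parts$pixels <- lapply(parts$label, function(l) {
        li <- which(lab == l)
        lr <- ((li - 1) %% nrow(lab)) + 1 + rsel[1] - 1
        lc <- ((li - 1) %/% nrow(lab)) + 1 + csel[1] - 1
        cbind(row = lr, col = lc)
      })
      return(parts)
    }
  }
  NULL
}

#' Fit second-moment ellipses to particles
#'
#' For each particle, fits the ellipse with the same second central moments
#' as the pixel set and converts it to arena coordinates: centroid in mm
#' (arena-centred, y up), orientation of the major axis in degrees in
#' \[0, 180) and full major/minor axis lengths in mm.
#'
#' @param pixel_sets List of `cbind(row, col)` matrices, one per particle.
#' @param geometry Geometry list of a `frame_stack` (`centre`,
#'   `mm_per_pixel`).
#' @param frame_index Frame number to stamp on the detections.
#' @param source_labels Optional particle labels to carry through.
#' @return A data.frame of detections: `frame`, `x_mm`, `y_mm`,
#'   `orientation_deg`, `major_mm`, `minor_mm`, `area_px`, `source_label`.
#'   Particles of fewer than 3 pixels are skipped with a warning.
#' @export
fit_ellipses <- function(pixel_sets, geometry, frame_index = NA_integer_,
                         source_labels = seq_along(pixel_sets)) {
  stopifnot(geometry$mm_per_pixel > 0)
  s <- geometry$mm_per_pixel
  rows <- lapply(seq_along(pixel_sets), function(i) {
    px <- pixel_sets[[i]]
    if (nrow(px) < 3) {
      warning("particle with fewer than 3 pixels skipped")
      return(NULL)
    }
    mom <- pixel_moments(px[, "row"], px[, "col"])
    data.frame(frame = frame_index,
               x_mm = (mean(px[, "col"]) - geometry$centre) * s,
               y_mm = (geometry$centre - mean(px[, "row"])) * s,
               orientation_deg = mom$theta,
               major_mm = 4 * sqrt(mom$l1) * s,
               minor_mm = 4 * sqrt(mom$l2) * s,
               area_px = nrow(px),
               source_label = source_labels[i])
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(frame = integer(0), x_mm = numeric(0),
                      y_mm = numeric(0), orientation_deg = numeric(0),
                      major_mm = numeric(0), minor_mm = numeric(0),
                      area_px = numeric(0), source_label = integer(0))
  out
}

# Pixel index sets per label as cbind(row, col) matrices.
label_pixel_sets <- function(labels) {
  idx <- which(labels > 0)
  if (length(idx) == 0) return(list())
  lab <- labels[idx]
  rr <- ((idx - 1) %% nrow(labels)) + 1
  cc <- ((idx - 1) %/% nrow(labels)) + 1
  lapply(split(seq_along(lab), lab),
         function(sel) cbind(row = rr[sel], col = cc[sel]))
}

#' Detect flies in a single frame
#'
#' The full per-frame pipeline: segmentation ([binarize_and_clean()]),
#' particle measurement, likelihood classification, merged-blob resolution
#' and ellipse fitting.
#'
#' @param frame,background Grayscale matrices.
#' @param geometry Geometry list of the `frame_stack`.
#' @param config A [tracker_config()].
#' @param frame_index Frame number stamped on the detections.
#' @return A detections data.frame (see [fit_ellipses()]); excluded merged
#'   blobs contribute no rows.
#' @export
detect_flies <- function(frame, background, geometry,
                         config = tracker_config(),
                         frame_index = NA_integer_) {
  labels <- binarize_and_clean(frame, background, config$threshold,
                               config$morphology_radius)
  parts <- measure_particles(labels, min_px = config$min_particle_px)
  if (nrow(parts) == 0)
    return(fit_ellipses(list(), geometry, frame_index))
  parts <- score_likelihood(parts, config$likelihood_cutoff)
  sets <- label_pixel_sets(labels)
  keep_sets <- list(); keep_labels <- integer(0)
  high <- parts$class == "high"
  for (i in which(high)) {
    keep_sets <- c(keep_sets, sets[as.character(parts$label[i])])
    keep_labels <- c(keep_labels, parts$label[i])
  }
  if (any(!high)) {
    mean_area <- mean(parts$area[high])
    if (!is.finite(mean_area) || mean_area <= 0)
      mean_area <- stats::median(parts$area)
    for (i in which(!high)) {
      res <- resolve_merged(frame, background, parts[i, ], labels,
                            mean_area, config)
      if (!is.null(res)) {
        keep_sets <- c(keep_sets, res$pixels)
        keep_labels <- c(keep_labels, rep(parts$label[i], nrow(res)))
      }
    }
  }
  fit_ellipses(keep_sets, geometry, frame_index, keep_labels)
}
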