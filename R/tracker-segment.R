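#' Tracker configuration
#'
#' Parameters of the multi-fly tracking pipeline.
#'
#' @param threshold Binarization threshold on the unit intensity scale;
#'   pixels darker than this are foreground (flies are dark on a light
#'   arena). Default 0.5.
#' @param morphology_radius Radius (px) of the square structuring element
#'   used for the erosion + dilation noise cleanup. Default 1.
#' @param likelihood_cutoff Tail probability below which a particle's
#'   (bounding-box diagonal, eccentricity) pair is classed as low-likelihood
#'   (candidate merged blob / bad threshold). Default 0.01.
#' @param max_iterations Cap on local re-threshold iterations when splitting
#'   a low-likelihood particle; on failure the particle is excluded.
#'   Default 40.
#' @param max_pair_distance Gate on centroid displacement between consecutive
#'   frames, mm. Default 7.
#' @param max_pair_angle Gate on the minimal mod-180 orientation change
#'   between consecutive frames, degrees. Default 90.
#' @param min_particle_px Particles smaller than this many pixels are ignored
#'   (sub-resolution debris). Default 3.
#' @return An object of class `tracker_config`.
#' @export
tracker_config <- function(threshold = 0.5, morphology_radius = 1L,
                           likelihood_cutoff = 0.01, max_iterations = 40L,
                           max_pair_distance = 7, max_pair_angle = 90,
                           min_particle_px = 3L) {
  stopifnot(threshold > 0, threshold < 1, morphology_radius >= 0,
            likelihood_cutoff > 0, likelihood_cutoff < 1,
            max_iterations >= 1, max_pair_distance > 0, max_pair_angle > 0)
  structure(list(threshold = threshold,
                 morphology_radius = as.integer(morphology_radius),
                 likelihood_cutoff = likelihood_cutoff,
                 max_iterations = as.integer(max_iterations),
                 max_pair_distance = max_pair_distance,
                 max_pair_angle = max_pair_angle,
                 min_particle_px = as.integer(min_particle_px)),
            class = "tracker_config")
}

# 8-connected labelling: EBImage::bwlabel is 4-connected, so labels that
# touch diagonally are merged afterwards ("a cluster of contacting pixels is
# one particle").
label_components <- function(mask) {
  lab <- EBImage::bwlabel(mask)
  n <- max(lab)
  if (n <= 1) return(lab)
  nr <- nrow(lab); nc <- ncol(lab)
  pairs <- rbind(
    cbind(as.vector(lab[-nr, -nc]), as.vector(lab[-1, -1])),
    cbind(as.vector(lab[-1, -nc]), as.vector(lab[-nr, -1])))
  pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 &
                   pairs[, 1] != pairs[, 2], , drop = FALSE]
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (k in seq_len(nrow(pairs))) {
    a <- find(pairs[k, 1]); b <- find(pairs[k, 2])
    if (a != b) parent[max(a, b)] <- min(a, b)
  }
  root <- vapply(seq_len(n), find, integer(1))
  relab <- match(root, sort(unique(root)))
  out <- lab
  out[lab > 0] <- relab[lab[lab > 0]]
  out
}

#' Segment flies from a frame by thresholding and background subtraction
#'
#' Binarizes the frame at a fixed threshold (dark pixels are foreground),
#' removes everything that is already foreground in the binarized empty-arena
#' background, applies one erosion followed by one dilation to strip
#' single-pixel noise, and labels clusters of contacting pixels as particles.
#'
#' @param frame,background Grayscale matrices of identical shape, intensities
#'   in \[0, 1\].
#' @param threshold Binarization threshold; pixels strictly below it are
#'   foreground.
#' @param morphology_radius Radius (px) of the square structuring element;
#'   0 skips the cleanup.
#' @return An integer label matrix (0 = background, 1..n = particles).
#' @export
binarize_and_clean <- function(frame, background, threshold = 0.5,
                               morphology_radius = 1L) {
  if (!all(dim(frame) == dim(background)))
    stop("frame and background must have the same shape")
  stopifnot(threshold > 0, threshold < 1)
  fg <- (frame < threshold) & !(background < threshold)
  mask <- matrix(as.numeric(fg), nrow(frame))
  if (morphology_radius > 0) {
    brush <- EBImage::makeBrush(2L * as.integer(morphology_radius) + 1L,
                                shape = "box")
    mask <- EBImage::dilate(EBImage::erode(mask, brush), brush)
  }
  label_components(mask > 0)
}

#' Measure particle properties
#'
#' For each labelled particle computes its area, centroid (pixel row/col),
#' bounding-box diagonal and the eccentricity of the ellipse with the same
#' second central moments as the particle.
#'
#' @param labels Integer label matrix from [binarize_and_clean()].
#' @param min_px Particles smaller than this are dropped.
#' @return A data.frame with columns `label`, `area`, `row`, `col`,
#'   `bbox_diagonal`, `eccentricity` (one row per particle, possibly empty).
#' @export
measure_particles <- function(labels, min_px = 3L) {
  idx <- which(labels > 0)
  empty <- data.frame(label = integer(0), area = numeric(0),
                      row = numeric(0), col = numeric(0),
                      bbox_diagonal = numeric(0), eccentricity = numeric(0))
  if (length(idx) == 0) return(empty)
  lab <- labels[idx]
  rr <- ((idx - 1) %% nrow(labels)) + 1
  cc <- ((idx - 1) %/% nrow(labels)) + 1
  out <- do.call(rbind, lapply(split(seq_along(lab), lab), function(sel) {
    r <- rr[sel]; c <- cc[sel]
    n <- length(sel)
    if (n < min_px) return(NULL)
    mom <- pixel_moments(r, c)
    data.frame(label = lab[sel[1]], area = n,
               row = mean(r), col = mean(c),
               bbox_diagonal = sqrt((diff(range(r)) + 1)^2 +
                                      (diff(range(c)) + 1)^2),
               eccentricity = mom$eccentricity)
  }))
  if (is.null(out)) return(empty)
  rownames(out) <- NULL
  out[order(out$label), , drop = FALSE]
}

# Second central moments of a pixel set in image coordinates; returns the
# equivalent-ellipse eigenstructure. Orientation is reported in arena
# convention (degrees from +x towards +y, y up, i.e. col right / row up).
pixel_moments <- function(r, c) {
  dr <- r - mean(r)
  dc <- c - mean(c)
  # arena axes: x = +col, y = -row
  x <- dc; y <- -dr
  mu20 <- mean(x * x); mu02 <- mean(y * y); mu11 <- mean(x * y)
  tr2 <- (mu20 + mu02) / 2
  det_ <- sqrt(pmax(((mu20 - mu02) / 2)^2 + mu11^2, 0))
  l1 <- tr2 + det_; l2 <- pmax(tr2 - det_, 0)
  ecc <- if (l1 <= 0) 0 else sqrt(pmax(1 - l2 / l1, 0))
  theta <- (0.5 * atan2(2 * mu11, mu20 - mu02) * 180 / pi) %% 180
  list(l1 = l1, l2 = l2, eccentricity = ecc, theta = theta)
}
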