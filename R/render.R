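#' Render ground-truth trajectories as grayscale arena frames
#'
#' Draws each agent as a filled dark ellipse at its ground-truth pose on a
#' light arena disc, adds Gaussian sensor noise and returns the frame stack
#' together with the matching empty-arena background frame. Body intensity
#' grades from a dark core (`fly`) to a lighter rim (`fly_edge`), as in real
#' overhead video where the body centre absorbs most light; the gradient is
#' what allows merged blobs to be split again at a stricter threshold. Flies
#' whose centres come closer than roughly the minor axis overlap and render
#' as a single merged blob.
#'
#' Pixel/mm convention: the arena centre sits at the image centre; for a
#' pixel at (row, col), `x_mm = (col - col_c) * mm_per_pixel` and
#' `y_mm = (row_c - row) * mm_per_pixel` (y points up).
#'
#' @param truth Ground-truth table from [simulate_agents()] (any subset of
#'   frames; the `frame` column orders the stack).
#' @param config An [arena_config()].
#' @param fly_axes Numeric `(major, minor)` full axis lengths of the rendered
#'   body ellipse in mm; default `c(2.2, 0.9)`, a typical adult body.
#' @param noise_sd SD of additive Gaussian intensity noise on the unit
#'   intensity scale (default 0.03).
#' @param intensities Named numeric vector with elements `fly` (body core),
#'   `fly_edge` (body rim), `arena` (the light disc) and `outside` (beyond
#'   the wall); intensities in \[0, 1\].
#' @param border_px Extra image border beyond the arena, in pixels.
#' @param seed Integer seed for the noise.
#'
#' @return A list of class `frame_stack`: `frames` (list of matrices indexed
#'   by the distinct frames of `truth`), `background` (matrix), `frame_index`
#'   (the frame numbers rendered) and `geometry` (pixel calibration details).
#' @export
render_frames <- function(truth, config, fly_axes = c(2.2, 0.9),
                          noise_sd = 0.03,
                          intensities = c(fly = 0.08, fly_edge = 0.4,
                                          arena = 0.85, outside = 0.25),
                          border_px = 8L, seed = 1L) {
  stopifnot(inherits(config, "arena_config"),
            length(fly_axes) == 2, all(fly_axes > 0),
            fly_axes[1] >= fly_axes[2],
            noise_sd >= 0)
  s <- config$mm_per_pixel
  n_px <- as.integer(ceiling(config$diameter / s)) + 2L * border_px
  centre <- (n_px + 1) / 2
  radius_px <- config$diameter / 2 / s

  # background: light disc on a darker surround
  rows <- matrix(seq_len(n_px), n_px, n_px)
  cols <- matrix(seq_len(n_px), n_px, n_px, byrow = TRUE)
  inside <- (rows - centre)^2 + (cols - centre)^2 <= radius_px^2
  background <- matrix(intensities[["outside"]], n_px, n_px)
  background[inside] <- intensities[["arena"]]

  a <- fly_axes[1] / 2 / s  # semi-axes in px
  b <- fly_axes[2] / 2 / s
  pad <- ceiling(a) + 1

  set.seed(as.integer(seed))
  frame_ids <- sort(unique(truth$frame))
  frames <- vector("list", length(frame_ids))
  for (k in seq_along(frame_ids)) {
    tr <- truth[truth$frame == frame_ids[k], , drop = FALSE]
    img <- background
    for (i in seq_len(nrow(tr))) {
      col0 <- tr$x_mm[i] / s + centre
      row0 <- centre - tr$y_mm[i] / s
      if (col0 < 1 + pad || col0 > n_px - pad ||
          row0 < 1 + pad || row0 > n_px - pad)
        stop("agent outside image bounds: calibration/geometry mismatch")
      theta <- tr$orientation_deg[i] * pi / 180
      ct <- cos(theta); st <- sin(theta)
      rr <- max(1L, floor(row0 - pad)):min(n_px, ceiling(row0 + pad))
      cc <- max(1L, floor(col0 - pad)):min(n_px, ceiling(col0 + pad))
      dx <- matrix(cc - col0, length(rr), length(cc), byrow = TRUE)
      dy <- matrix(row0 - outer(rr, rep(1, length(cc))), length(rr))
      u <- dx * ct + dy * st
      v <- -dx * st + dy * ct
      m <- (u / a)^2 + (v / b)^2
      hit <- m <= 1
      val <- intensities[["fly"]] +
        (intensities[["fly_edge"]] - intensities[["fly"]]) * m
      patch <- img[rr, cc]
      patch[hit] <- pmin(patch[hit], val[hit])
      img[rr, cc] <- patch
    }
    if (noise_sd > 0)
      img <- img + matrix(stats::rnorm(n_px * n_px, 0, noise_sd), n_px)
    frames[[k]] <- pmin(pmax(img, 0), 1)
  }
  bg_out <- background
  if (noise_sd > 0)
    bg_out <- pmin(pmax(bg_out +
      matrix(stats::rnorm(n_px * n_px, 0, noise_sd), n_px), 0), 1)
  structure(list(frames = frames, background = bg_out,
                 frame_index = frame_ids,
                 geometry = list(n_px = n_px, centre = centre,
                                 mm_per_pixel = s, radius_px = radius_px)),
            class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  cat(sprintf("frame_stack: %d frames of %dx%d px (%.3f mm/px)\n",
              length(x$frames), x$geometry$n_px, x$geometry$n_px,
              x$geometry$mm_per_pixel))
  invisible(x)
}

#' Write/read a frame stack as numbered PNG files
#'
#' `write_frame_stack()` writes `frame_000001.png`, ... plus
#' `background.png` into `dir`; `read_frame_stack()` reads them back.
#' Intensities are 8-bit grayscale on disk, so a round trip quantizes to
#' 1/255.
#'
#' @param stack A `frame_stack` from [render_frames()].
#' @param dir Output/input directory.
#' @param mm_per_pixel Calibration to attach on read.
#' @return `write_frame_stack()` returns `dir` invisibly;
#'   `read_frame_stack()` returns a `frame_stack`.
#' @export
write_frame_stack <- function(stack, dir) {
  stopifnot(inherits(stack, "frame_stack"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (k in seq_along(stack$frames)) {
    png::writePNG(stack$frames[[k]],
                  file.path(dir, sprintf("frame_%06d.png",
                                         stack$frame_index[k])))
  }
  png::writePNG(stack$background, file.path(dir, "background.png"))
  invisible(dir)
}

#' @rdname write_frame_stack
#' @export
read_frame_stack <- function(dir, mm_per_pixel) {
  files <- sort(list.files(dir, pattern = "^frame_\\d+\\.png$",
                           full.names = TRUE))
  stopifnot(length(files) > 0,
            file.exists(file.path(dir, "background.png")))
  frames <- lapply(files, function(f) as.matrix(png::readPNG(f)))
  bg <- as.matrix(png::readPNG(file.path(dir, "background.png")))
  n_px <- nrow(bg)
  idx <- as.integer(sub("^frame_0*(\\d+)\\.png$", "\\1", basename(files)))
  structure(list(frames = frames, background = bg, frame_index = idx,
                 geometry = list(n_px = n_px, centre = (n_px + 1) / 2,
                                 mm_per_pixel = mm_per_pixel,
                                 radius_px = NA_real_)),
            class = "frame_stack")
}
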