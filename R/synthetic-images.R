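#' Bright-field field-of-view design parameters
#'
#' Particles are rendered darker than the background (transmitted-light
#' contrast), with the background near the top of the intensity range so
#' histogram thresholding is meaningful.
#'
#' @param image_shape `(rows, cols)` in pixels.
#' @param n_particles number of disks to place.
#' @param radius_range `(min, max)` disk radius in pixels.
#' @param min_separation minimum pairwise centroid distance (px).
#' @param illumination_gradient `NULL` or `(gx, gy)`: linear intensity ramp
#'   per normalized image coordinate.
#' @param noise_sd additive Gaussian pixel noise (intensity units on
#'   `[0, 1]`).
#' @param hole_prob probability a particle carries a central void
#'   (exercises hole filling).
#' @param pixel_size micrometres per pixel.
#' @param frame_index `(row, col)` position within the scan grid; the
#'   default scan layout is a 10 x 10 frame raster.
#' @param seed integer seed.
#' @return Object of class `fov_design`.
#' @export
fov_design <- function(image_shape = c(256, 256), n_particles = 5,
                       radius_range = c(8, 20), min_separation = 0,
                       illumination_gradient = NULL, noise_sd = 0,
                       hole_prob = 0, pixel_size = 1.0,
                       frame_index = c(0L, 0L), seed = 1L) {
  stopifnot(length(image_shape) == 2, all(image_shape >= 1),
            length(radius_range) == 2, radius_range[1] <= radius_range[2],
            min_separation >= 0, noise_sd >= 0,
            hole_prob >= 0, hole_prob <= 1, pixel_size > 0)
  if (2 * radius_range[2] + 4 > min(image_shape)) {
    stop("particles do not fit inside the image", call. = FALSE)
  }
  structure(
    list(image_shape = as.integer(image_shape),
         n_particles = as.integer(n_particles),
         radius_range = radius_range, min_separation = min_separation,
         illumination_gradient = illumination_gradient,
         noise_sd = noise_sd, hole_prob = hole_prob,
         pixel_size = pixel_size, frame_index = as.integer(frame_index),
         seed = as.integer(seed)),
    class = "fov_design"
  )
}

#' Construct a field-of-view image object
#'
#' @param image numeric matrix (rows x cols) of pixel intensities, or an
#'   rows x cols x 3 RGB array.
#' @param pixel_size micrometres per pixel (> 0).
#' @param frame_index `(row, col)` frame position within the scan grid.
#' @return Object of class `fov_image`.
#' @export
fov_image <- function(image, pixel_size = 1.0, frame_index = c(0L, 0L)) {
  if (pixel_size <= 0) stop("pixel_size must be > 0", call. = FALSE)
  structure(list(image = image, pixel_size = pixel_size,
                 frame_index = as.integer(frame_index)),
            class = "fov_image")
}

#' Generate a ground-truthed bright-field image
#'
#' Places `n_particles` non-overlapping dark disks on a bright background by
#' rejection sampling (bounded retries), optionally with central voids, an
#' illumination ramp, and pixel noise. Centroids use 0-based pixel
#' coordinates with `x` = column and `y` = row, origin top-left.
#'
#' @param design a [fov_design()].
#' @return list with elements `fov` (a [fov_image()], intensities on
#'   `[0, 1]`) and `truth` (data.frame `x`, `y`, `radius`, `has_hole`).
#' @export
generate_fov_image <- function(design) {
  with_seed(design$seed, {
    nr <- design$image_shape[1]
    nc <- design$image_shape[2]
    background <- 0.88
    particle_level <- 0.25
    img <- matrix(background, nr, nc)
    if (!is.null(design$illumination_gradient)) {
      g <- design$illumination_gradient
      col_ramp <- (seq_len(nc) - 1) / max(nc - 1, 1)
      row_ramp <- (seq_len(nr) - 1) / max(nr - 1, 1)
      img <- img + outer(row_ramp * g[2], col_ramp * g[1], `+`)
    }
    xs <- ys <- rs <- numeric(0)
    holes <- logical(0)
    attempts <- 0L
    max_attempts <- 400L * max(design$n_particles, 1L)
    while (length(xs) < design$n_particles) {
      attempts <- attempts + 1L
      if (attempts > max_attempts) {
        stop(sprintf(
          "placement error: could not place %d particles with separation %g",
          design$n_particles, design$min_separation), call. = FALSE)
      }
      r <- stats::runif(1, design$radius_range[1], design$radius_range[2])
      margin <- r + 2
      x <- stats::runif(1, margin, nc - 1 - margin)
      y <- stats::runif(1, margin, nr - 1 - margin)
      if (length(xs) > 0 &&
          min(sqrt((xs - x)^2 + (ys - y)^2)) < design$min_separation) {
        next
      }
      xs <- c(xs, x); ys <- c(ys, y); rs <- c(rs, r)
      holes <- c(holes, stats::runif(1) < design$hole_prob)
    }
    for (i in seq_along(xs)) {
      r <- rs[i]
      rows <- max(1, floor(ys[i] - r)):min(nr, ceiling(ys[i] + r + 1))
      cols <- max(1, floor(xs[i] - r)):min(nc, ceiling(xs[i] + r + 1))
      dy <- (rows - 1) - ys[i]
      dx <- (cols - 1) - xs[i]
      d2 <- outer(dy^2, dx^2, `+`)
      inside <- d2 <= r^2
      patch <- img[rows, cols]
      patch[inside] <- particle_level
      if (holes[i]) {
        hole_r <- r / 3
        patch[d2 <= hole_r^2] <- background
      }
      img[rows, cols] <- patch
    }
    if (design$noise_sd > 0) {
      img <- img + matrix(stats::rnorm(nr * nc, 0, design$noise_sd), nr, nc)
    }
    img <- pmin(pmax(img, 0), 1)
    truth <- data.frame(x = xs, y = ys, radius = rs, has_hole = holes)
    list(fov = fov_image(img, design$pixel_size, design$frame_index),
         truth = truth)
  })
}
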