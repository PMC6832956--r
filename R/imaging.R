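#' Convert an image to 8-bit grayscale
#'
#' RGB input is first reduced by Rec. 601 luminance weighting
#' (0.299 R + 0.587 G + 0.114 B), then intensities are min-max rescaled to
#' the 0-255 range and rounded. A constant image maps to all zeros.
#'
#' @param image numeric matrix (grayscale, any bit depth / range) or a
#'   rows x cols x 3 array (RGB), or a [fov_image()].
#' @return integer matrix with values in 0..255.
#' @export
to_grayscale8 <- function(image) {
  if (inherits(image, "fov_image")) image <- image$image
  if (is.array(image) && length(dim(image)) == 3) {
    if (dim(image)[3] < 3) stop("RGB image must have 3 planes", call. = FALSE)
    image <- 0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3]
  }
  image <- as.matrix(image)
  lo <- min(image)
  hi <- max(image)
  if (hi == lo) {
    out <- matrix(0L, nrow(image), ncol(image))
  } else {
    out <- matrix(as.integer(round((image - lo) / (hi - lo) * 255)),
                  nrow(image), ncol(image))
  }
  out
}

#' Otsu threshold from the 256-bin intensity histogram
#'
#' Selects the threshold `t` (0..254) maximizing the between-class variance
#' of the two classes `{<= t}` and `{> t}` over the 8-bit histogram. Ties
#' resolve to the lowest threshold. Foreground, by the bright-field
#' convention of this package, is the darker class (`pixel <= threshold`).
#'
#' @param gray8 integer matrix with values in 0..255.
#' @return list with `threshold` (integer, `NA` when degenerate),
#'   `degenerate` (logical), and `between_class_variance` (the achieved
#'   criterion value).
#' @export
histogram_threshold <- function(gray8) {
  v <- as.integer(gray8)
  if (any(v < 0 | v > 255)) stop("gray8 must be 8-bit (0..255)", call. = FALSE)
  counts <- tabulate(v + 1L, nbins = 256L)
  if (sum(counts > 0) < 2) {
    return(list(threshold = NA_integer_, degenerate = TRUE,
                between_class_variance = 0))
  }
  n <- sum(counts)
  p <- counts / n
  levels <- 0:255
  omega <- cumsum(p)                # class-0 mass for t = 0..255
  mu <- cumsum(p * levels)          # class-0 partial mean numerator
  mu_total <- mu[256]
  t_all <- 1:255                    # candidate cut after level t-1
  w0 <- omega[t_all]
  w1 <- 1 - w0
  valid <- w0 > 0 & w1 > 0
  sigma_b <- rep(-Inf, 255)
  sigma_b[valid] <- (mu_total * w0[valid] - mu[t_all][valid])^2 /
    (w0[valid] * w1[valid])
  best <- which.max(sigma_b)        # which.max takes the first (lowest) tie
  list(threshold = as.integer(best - 1L), degenerate = FALSE,
       between_class_variance = sigma_b[best])
}

#' Binary foreground mask from an 8-bit image and threshold result
#'
#' @param gray8 integer matrix 0..255.
#' @param th result of [histogram_threshold()].
#' @return logical matrix; all-`FALSE` when the threshold is degenerate.
#' @export
foreground_mask <- function(gray8, th) {
  if (isTRUE(th$degenerate)) {
    return(matrix(FALSE, nrow(gray8), ncol(gray8)))
  }
  gray8 <= th$threshold
}

# Label 8-connected foreground components. Returns an integer matrix of
# labels (0 = background); labels are compacted but arbitrary in order.
label_components <- function(binary) {
  binary <- binary != 0
  nr <- nrow(binary)
  nc <- ncol(binary)
  fg <- which(binary)
  labels <- matrix(0L, nr, nc)
  if (length(fg) == 0) return(labels)
  id <- matrix(0L, nr, nc)
  id[fg] <- seq_along(fg)
  # half of the 8-neighbourhood suffices for an undirected adjacency
  shifts <- list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(1L, -1L))
  edges <- vector("list", length(shifts))
  for (s in seq_along(shifts)) {
    dr <- shifts[[s]][1]; dc <- shifts[[s]][2]
    r0 <- max(1L, 1L - dr):min(nr, nr - dr)
    c0 <- max(1L, 1L - dc):min(nc, nc - dc)
    a <- id[r0, c0, drop = FALSE]
    b <- id[r0 + dr, c0 + dc, drop = FALSE]
    keep <- a > 0L & b > 0L
    edges[[s]] <- cbind(a[keep], b[keep])
  }
  edges <- do.call(rbind, edges)
  g <- igraph::make_empty_graph(n = length(fg), directed = FALSE)
  if (nrow(edges) > 0) g <- igraph::add_edges(g, t(edges))
  membership <- igraph::components(g)$membership
  labels[fg] <- as.integer(membership)
  labels
}

#' Remove connected components outside an area range
#'
#' Components (8-connectivity) with pixel area below `min_area` or above
#' `max_area` are erased; all others pass through untouched.
#'
#' @param binary logical/0-1 matrix.
#' @param min_area,max_area inclusive area bounds in px^2.
#' @return logical matrix.
#' @export
remove_particles_by_size <- function(binary, min_area = 0,
                                     max_area = Inf) {
  if (min_area > max_area) stop("min_area must be <= max_area", call. = FALSE)
  labels <- label_components(binary)
  if (max(labels) == 0L) return(binary != 0)
  areas <- tabulate(labels[labels > 0L])
  keep <- which(areas >= min_area & areas <= max_area)
  out <- matrix(labels %in% keep, nrow(labels), ncol(labels))
  out
}

# One 3x3 binary dilation: logical-or of the 8-shifted copies and the input.
dilate3x3 <- function(binary) {
  nr <- nrow(binary); nc <- ncol(binary)
  padded <- matrix(FALSE, nr + 2L, nc + 2L)
  padded[2:(nr + 1), 2:(nc + 1)] <- binary != 0
  out <- matrix(FALSE, nr, nc)
  for (dr in 0:2) {
    for (dc in 0:2) {
      out <- out | padded[(1:nr) + dr, (1:nc) + dc]
    }
  }
  out
}

#' Fill holes and dilate a binary particle mask
#'
#' Both stages are iterative 3 x 3 logical-or thickening: `fill_iterations`
#' passes close interior voids up to roughly that radius, then
#' `dilate_iterations` passes stabilize blob outlines. The operation is
#' monotone (output is a superset of the input) and zero iterations of both
#' is the identity.
#'
#' @param binary logical/0-1 matrix.
#' @param fill_iterations,dilate_iterations nonnegative iteration counts.
#' @return logical matrix.
#' @export
fill_holes_and_dilate <- function(binary, fill_iterations = 3,
                                  dilate_iterations = 1) {
  stopifnot(fill_iterations >= 0, dilate_iterations >= 0)
  out <- binary != 0
  for (i in seq_len(fill_iterations + dilate_iterations)) {
    out <- dilate3x3(out)
  }
  out
}

#' Blob analysis: connected components with morphological statistics
#'
#' One blob per 8-connected foreground component. Centroids are the
#' unweighted mean of member pixel coordinates in the 0-based convention
#' (`x` = column, `y` = row, origin top-left); bounding boxes are inclusive.
#' Blobs are sorted by centroid `(y, x)`.
#'
#' @param binary logical/0-1 matrix.
#' @return data.frame with columns `x`, `y`, `area`, `x0`, `y0`, `x1`,
#'   `y1` (empty for an empty image).
#' @export
blob_analysis <- function(binary) {
  labels <- label_components(binary)
  k <- max(labels)
  empty <- data.frame(x = numeric(0), y = numeric(0), area = numeric(0),
                      x0 = numeric(0), y0 = numeric(0),
                      x1 = numeric(0), y1 = numeric(0))
  if (k == 0L) return(empty)
  idx <- which(labels > 0L, arr.ind = TRUE)
  lab <- labels[labels > 0L]
  xs <- idx[, "col"] - 1
  ys <- idx[, "row"] - 1
  out <- data.frame(
    x = as.numeric(tapply(xs, lab, mean)),
    y = as.numeric(tapply(ys, lab, mean)),
    area = as.numeric(tabulate(lab, nbins = k)),
    x0 = as.numeric(tapply(xs, lab, min)),
    y0 = as.numeric(tapply(ys, lab, min)),
    x1 = as.numeric(tapply(xs, lab, max)),
    y1 = as.numeric(tapply(ys, lab, max))
  )
  out <- out[order(out$y, out$x), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Localization configuration
#'
#' Area bounds default to the pixel areas of 10-100 um diameter disks at
#' the field-of-view pixel size — the typical pollen grain size range.
#'
#' @param min_diameter_um,max_diameter_um admissible particle diameters.
#' @param fill_iterations,dilate_iterations morphology iteration counts.
#' @return list of class `localization_config`.
#' @export
localization_config <- function(min_diameter_um = 10, max_diameter_um = 100,
                                fill_iterations = 3, dilate_iterations = 1) {
  structure(list(min_diameter_um = min_diameter_um,
                 max_diameter_um = max_diameter_um,
                 fill_iterations = fill_iterations,
                 dilate_iterations = dilate_iterations),
            class = "localization_config")
}

#' Localize pollen particles in a bright-field frame
#'
#' Sequential composition of the detection stages: 8-bit conversion,
#' histogram (Otsu) thresholding with dark foreground, component size
#' filtering, hole filling + dilation, and blob analysis.
#'
#' @param fov a [fov_image()].
#' @param config a [localization_config()].
#' @return data.frame of blobs as from [blob_analysis()], with the stage
#'   provenance attached as `attr(, "provenance")`.
#' @export
localize_pollen <- function(fov, config = localization_config()) {
  gray8 <- to_grayscale8(fov$image)
  th <- histogram_threshold(gray8)
  mask <- foreground_mask(gray8, th)
  px <- fov$pixel_size
  min_area <- pi * (config$min_diameter_um / 2 / px)^2
  max_area <- pi * (config$max_diameter_um / 2 / px)^2
  sized <- remove_particles_by_size(mask, min_area, max_area)
  filled <- fill_holes_and_dilate(sized, config$fill_iterations,
                                  config$dilate_iterations)
  blobs <- blob_analysis(filled)
  attr(blobs, "provenance") <- list(
    threshold = th$threshold, degenerate = th$degenerate,
    min_area_px = min_area, max_area_px = max_area,
    fill_iterations = config$fill_iterations,
    dilate_iterations = config$dilate_iterations)
  blobs
}

#' Affine pixel-to-stage transform
#'
#' @param linear 2 x 2 matrix (um/px scale, rotation and shear terms); must
#'   be invertible.
#' @param offset length-2 stage offset in um.
#' @return list of class `stage_transform`.
#' @export
stage_transform <- function(linear = diag(2), offset = c(0, 0)) {
  linear <- matrix(as.numeric(linear), 2, 2)
  if (abs(det(linear)) < .Machine$double.eps) {
    stop("linear part of the stage transform is singular", call. = FALSE)
  }
  structure(list(linear = linear, offset = as.numeric(offset)),
            class = "stage_transform")
}

#' Convert blob pixel coordinates to stage coordinates
#'
#' `stage = linear %*% (x, y) + offset + frame_index * frame_pitch`, with
#' `frame_index = (row, col)` contributing `col * pitch` to the stage x and
#' `row * pitch` to the stage y axis.
#'
#' @param blobs data.frame with `x`, `y` pixel centroids.
#' @param transform a [stage_transform()].
#' @param frame_index `(row, col)` of the frame within the scan grid.
#' @param frame_pitch frame spacing in um (scalar or `(x, y)` pair).
#' @return data.frame with columns `stage_x`, `stage_y` (um), one row per
#'   blob.
#' @export
pixel_to_stage <- function(blobs, transform, frame_index = c(0L, 0L),
                           frame_pitch = 0) {
  if (length(frame_pitch) == 1) frame_pitch <- rep(frame_pitch, 2)
  pix <- rbind(blobs$x, blobs$y)
  stage <- transform$linear %*% pix + transform$offset +
    c(frame_index[2] * frame_pitch[1], frame_index[1] * frame_pitch[2])
  data.frame(stage_x = stage[1, ], stage_y = stage[2, ])
}

#' Invert a stage transform back to pixel coordinates
#'
#' @param stage data.frame with `stage_x`, `stage_y` in um.
#' @inheritParams pixel_to_stage
#' @return data.frame with columns `x`, `y` in pixels.
#' @export
stage_to_pixel <- function(stage, transform, frame_index = c(0L, 0L),
                           frame_pitch = 0) {
  if (length(frame_pitch) == 1) frame_pitch <- rep(frame_pitch, 2)
  shifted <- rbind(
    stage$stage_x - transform$offset[1] - frame_index[2] * frame_pitch[1],
    stage$stage_y - transform$offset[2] - frame_index[1] * frame_pitch[2])
  pix <- solve(transform$linear) %*% shifted
  data.frame(x = pix[1, ], y = pix[2, ])
}
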