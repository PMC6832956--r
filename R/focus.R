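#' Sharpness metric: variance of the Laplacian response
#'
#' Standard autofocus figure of merit for bright-field frames; peaks at the
#' best focal plane.
#'
#' @param image numeric matrix.
#' @return scalar variance of the 4-neighbour Laplacian over the interior.
#' @export
focus_metric <- function(image) {
  image <- as.matrix(image)
  nr <- nrow(image); nc <- ncol(image)
  if (nr < 3 || nc < 3) stop("image too small for a Laplacian", call. = FALSE)
  core <- image[2:(nr - 1), 2:(nc - 1)]
  lap <- image[1:(nr - 2), 2:(nc - 1)] + image[3:nr, 2:(nc - 1)] +
    image[2:(nr - 1), 1:(nc - 2)] + image[2:(nr - 1), 3:nc] - 4 * core
  stats::var(as.vector(lap))
}

#' Fit a Gaussian autofocus curve
#'
#' Least-squares fit of `amplitude * exp(-(z - center)^2 / (2 width^2)) +
#' offset` to sampled (z, focus-metric) pairs; the fitted center is the
#' best-focus position. Fails (focus-failure error) when the optimizer does
#' not converge or the center lies outside the sampled z range, as happens
#' for monotone metric profiles with no interior peak.
#'
#' @param z stage z positions (um), strictly increasing, length >= 4.
#' @param metric focus metric values at `z`.
#' @return list of class `focus_fit`: `amplitude`, `center`, `width`,
#'   `offset`, `fitted`, `residuals`.
#' @export
fit_focus_gaussian <- function(z, metric) {
  if (length(z) < 4) stop("need at least 4 focus samples", call. = FALSE)
  if (any(diff(z) <= 0)) stop("z must be strictly increasing", call. = FALSE)
  if (length(metric) != length(z)) stop("length mismatch", call. = FALSE)
  start <- list(A = max(metric) - min(metric),
                c = z[which.max(metric)],
                w = diff(range(z)) / 4,
                o = min(metric))
  fit <- tryCatch(
    minpack.lm::nlsLM(metric ~ A * exp(-(z - c)^2 / (2 * w^2)) + o,
                      start = start,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) stop("focus-failure: Gaussian fit did not converge",
                         call. = FALSE)
  p <- stats::coef(fit)
  center <- unname(p["c"])
  width <- abs(unname(p["w"]))
  if (center < min(z) || center > max(z) || !is.finite(center) ||
      width <= 0) {
    stop("focus-failure: fitted center outside the sampled z range",
         call. = FALSE)
  }
  structure(list(amplitude = unname(p["A"]), center = center,
                 width = width, offset = unname(p["o"]),
                 fitted = stats::fitted(fit),
                 residuals = stats::resid(fit)),
            class = "focus_fit")
}

#' Fit a slide tilt plane
#'
#' Least squares plane `z = a x + b y + c` through sampled best-focus
#' points; used to pre-correct the focal offset of each frame.
#'
#' @param points data.frame with columns `x`, `y`, `z` (um), >= 3
#'   non-collinear rows.
#' @return list of class `tilt_plane`: coefficients `a`, `b`, `c` and the
#'   fit `residuals`.
#' @export
fit_tilt_plane <- function(points) {
  stopifnot(all(c("x", "y", "z") %in% names(points)))
  if (nrow(points) < 3) stop("need at least 3 points", call. = FALSE)
  X <- cbind(1, points$x, points$y)
  if (qr(X)$rank < 3) {
    stop("degenerate tilt fit: points are collinear", call. = FALSE)
  }
  fit <- stats::lm.fit(X, points$z)
  cf <- fit$coefficients
  structure(list(a = unname(cf[2]), b = unname(cf[3]), c = unname(cf[1]),
                 residuals = unname(fit$residuals)),
            class = "tilt_plane")
}

#' Predict focal z from a tilt plane
#'
#' @param plane a [fit_tilt_plane()] result.
#' @param x,y stage coordinates (um).
#' @return predicted z (um).
#' @export
predict_tilt <- function(plane, x, y) {
  plane$a * x + plane$b * y + plane$c
}
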