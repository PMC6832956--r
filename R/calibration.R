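#' Raman shift standard band table: 4-acetaminophenol
#'
#' Literature band positions (cm^-1) of solid 4-acetaminophenol
#' (acetaminophen/paracetamol), the wavenumber calibration standard used by
#' the pipeline. Positions follow the ASTM E1840 Raman shift standard list.
#'
#' @return data.frame with column `wavenumber`.
#' @export
acetaminophenol_peak_table <- function() {
  data.frame(wavenumber = c(329.2, 390.9, 465.1, 504.0, 651.6, 710.8,
                            797.2, 834.5, 857.9, 968.7, 1105.5, 1168.5,
                            1236.8, 1278.5, 1323.9, 1371.5, 1515.1,
                            1561.6, 1648.4, 2931.1, 3064.6))
}

# Strict local maxima of y with sub-pixel quadratic refinement.
# Returns data.frame(pixel, height) on the 0-based pixel axis.
detect_peaks <- function(y, min_height = NULL) {
  n <- length(y)
  if (n < 3) return(data.frame(pixel = numeric(0), height = numeric(0)))
  i <- 2:(n - 1)
  is_max <- y[i] > y[i - 1] & y[i] >= y[i + 1]
  idx <- i[is_max]
  if (!is.null(min_height)) idx <- idx[y[idx] >= min_height]
  if (length(idx) == 0) return(data.frame(pixel = numeric(0),
                                          height = numeric(0)))
  # quadratic through the three samples around each maximum
  denom <- y[idx - 1] - 2 * y[idx] + y[idx + 1]
  delta <- ifelse(abs(denom) > .Machine$double.eps,
                  0.5 * (y[idx - 1] - y[idx + 1]) / denom, 0)
  delta <- pmin(pmax(delta, -0.5), 0.5)
  data.frame(pixel = (idx - 1) + delta, height = y[idx])
}

#' Wavenumber calibration against a Raman shift standard
#'
#' Detects local maxima in the standard's spectrum (recorded on the camera
#' pixel axis), refines each to sub-pixel position by quadratic
#' interpolation, matches them to the literature band table, and fits a
#' polynomial pixel-to-wavenumber mapping by least squares. Matching first
#' pairs the most prominent maxima with the table in axis order (both are
#' monotone), then re-matches all detected maxima to the nearest table
#' entry within `tolerance` under the provisional fit and refits.
#'
#' @param standard numeric intensity vector on the pixel axis, or a
#'   `raman_spectrum` with `axis_unit = "pixel"`.
#' @param peak_table data.frame with column `wavenumber` (cm^-1).
#' @param degree polynomial degree of the mapping.
#' @param tolerance match tolerance in cm^-1 for the refinement pass.
#' @return list of class `wavenumber_calibration`: `coefficients`
#'   (ascending powers of the 0-based pixel index), `degree`,
#'   `residual_rms` (cm^-1), `matches` (data.frame `pixel`, `wavenumber`).
#' @export
calibrate_wavenumber <- function(standard, peak_table, degree = 3,
                                 tolerance = 10) {
  y <- if (inherits(standard, "raman_spectrum")) standard$intensity
       else as.numeric(standard)
  wn <- sort(peak_table$wavenumber)
  peaks <- detect_peaks(y, min_height = max(y) * 0.05)
  if (nrow(peaks) < degree + 1) {
    stop(sprintf("too few detected peaks (%d) for a degree-%d fit",
                 nrow(peaks), degree), call. = FALSE)
  }
  # provisional pairing: top-|table| prominent maxima, in axis order
  top <- peaks[order(-peaks$height), , drop = FALSE]
  top <- utils::head(top, length(wn))
  top <- top[order(top$pixel), , drop = FALSE]
  if (nrow(top) < degree + 1) {
    stop("too few matched peaks for the requested degree", call. = FALSE)
  }
  wn_prov <- if (nrow(top) == length(wn)) wn else {
    # fewer maxima than table rows: pair to the most evenly spread subset
    wn[round(seq(1, length(wn), length.out = nrow(top)))]
  }
  fit_poly <- function(px, target, deg) {
    X <- outer(px, 0:deg, `^`)
    stats::lm.fit(X, target)$coefficients
  }
  coef_prov <- fit_poly(top$pixel, wn_prov, degree)
  predict_poly <- function(coefs, px) {
    drop(outer(px, seq_along(coefs) - 1, `^`) %*% coefs)
  }
  # refinement: nearest-table matching under the provisional map
  pred <- predict_poly(coef_prov, peaks$pixel)
  nearest <- vapply(pred, function(w) which.min(abs(wn - w)), integer(1))
  err <- abs(pred - wn[nearest])
  keep <- err <= tolerance & !duplicated(nearest)
  matches <- data.frame(pixel = peaks$pixel[keep],
                        wavenumber = wn[nearest[keep]])
  if (nrow(matches) < degree + 1) {
    stop(sprintf("too few matched peaks (%d) for a degree-%d fit",
                 nrow(matches), degree), call. = FALSE)
  }
  coefs <- fit_poly(matches$pixel, matches$wavenumber, degree)
  resid <- predict_poly(coefs, matches$pixel) - matches$wavenumber
  grid <- seq(0, length(y) - 1, length.out = 512)
  if (any(diff(predict_poly(coefs, grid)) <= 0)) {
    stop("fitted pixel-to-wavenumber mapping is not monotone",
         call. = FALSE)
  }
  structure(list(coefficients = unname(coefs), degree = degree,
                 residual_rms = sqrt(mean(resid^2)), matches = matches),
            class = "wavenumber_calibration")
}

#' Evaluate a wavenumber calibration at pixel positions
#'
#' @param calibration a [calibrate_wavenumber()] result.
#' @param pixels 0-based pixel indices.
#' @return wavenumbers in cm^-1.
#' @export
predict_wavenumber <- function(calibration, pixels) {
  drop(outer(pixels, seq_along(calibration$coefficients) - 1, `^`) %*%
         calibration$coefficients)
}

#' Intensity (spectral response) calibration from a white-light lamp pair
#'
#' Per-channel correction factors are the ratio of the certified lamp
#' emission to the measured lamp spectrum; applying them removes the
#' instrument's spectral response. Channels where the measured lamp is not
#' positive are masked out (factor 1, mask `FALSE`); more than 20% masked
#' channels is a calibration error.
#'
#' @param measured,certified lamp intensity vectors on the target axis.
#' @param smooth_k odd window for median smoothing of the factors, or
#'   `NULL` (default) for the raw ratio.
#' @return list of class `intensity_response`: `factors`, `mask`.
#' @export
calibrate_intensity <- function(measured, certified, smooth_k = NULL) {
  measured <- as.numeric(measured)
  certified <- as.numeric(certified)
  if (length(measured) != length(certified)) {
    stop("lamp spectra must share the target axis", call. = FALSE)
  }
  mask <- measured > 0 & is.finite(measured) & is.finite(certified)
  if (mean(!mask) > 0.2) {
    stop("calibration error: nonpositive measured lamp on >20% of channels",
         call. = FALSE)
  }
  factors <- rep(1, length(measured))
  factors[mask] <- certified[mask] / measured[mask]
  if (!is.null(smooth_k)) {
    factors <- stats::runmed(factors, k = smooth_k, endrule = "median")
  }
  if (any(factors[mask] <= 0)) {
    stop("calibration error: nonpositive response factors", call. = FALSE)
  }
  structure(list(factors = factors, mask = mask),
            class = "intensity_response")
}

#' Apply an intensity response correction
#'
#' @param intensity numeric vector (or matrix, channels in rows) on the
#'   response's axis.
#' @param response a [calibrate_intensity()] result.
#' @return corrected intensities, same shape as the input.
#' @export
apply_response <- function(intensity, response) {
  if (is.matrix(intensity)) {
    intensity * response$factors
  } else {
    as.numeric(intensity) * response$factors
  }
}
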