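#' Build surrogate calibration fixtures with known ground truth
#'
#' Constructs (a) a wavenumber-standard spectrum on the camera pixel axis
#' whose Gaussian bands sit at the pixel positions that map to the given
#' peak-table wavenumbers under the true pixel-to-wavenumber polynomial,
#' and (b) a measured/certified white-lamp pair related by a known
#' response curve. Round-tripping these fixtures through
#' [calibrate_wavenumber()] and [calibrate_intensity()] must recover the
#' generating mappings.
#'
#' @param true_coefficients polynomial coefficients (ascending powers of
#'   the 0-based pixel index) of the true pixel-to-wavenumber mapping;
#'   must be strictly increasing over the pixel range.
#' @param n_pixels number of camera pixels.
#' @param peak_wavenumbers band positions (cm^-1) for the standard; all
#'   must lie inside the mapped range.
#' @param peak_width_px Gaussian sigma of the standard's bands, in pixels.
#' @param response_curve function of wavenumber giving the instrument
#'   response (> 0), or `NULL` for a flat response of 1.
#' @param lamp_axis wavenumber axis for the lamp pair; defaults to the
#'   mapped pixel axis.
#' @return list with `standard` (a `raman_spectrum` on the pixel axis),
#'   `peak_table`, `measured_lamp`, `certified_lamp`, `lamp_axis`, and
#'   `truth` (the generating mapping and response).
#' @export
make_calibration_fixtures <- function(true_coefficients, n_pixels = 1024,
                                      peak_wavenumbers,
                                      peak_width_px = 2.5,
                                      response_curve = NULL,
                                      lamp_axis = NULL) {
  px <- 0:(n_pixels - 1)
  mapped <- drop(outer(px, seq_along(true_coefficients) - 1, `^`) %*%
                   true_coefficients)
  if (any(diff(mapped) <= 0)) {
    stop("true mapping must be strictly increasing over the pixel range",
         call. = FALSE)
  }
  if (any(peak_wavenumbers < min(mapped) | peak_wavenumbers > max(mapped))) {
    stop("peak wavenumbers outside the mapped range", call. = FALSE)
  }
  # invert the monotone mapping to place the bands
  peak_px <- stats::approx(mapped, px, xout = peak_wavenumbers)$y
  amp <- 0.6 + 0.4 * cos(seq_along(peak_wavenumbers))^2
  y <- rep(0, n_pixels)
  for (i in seq_along(peak_px)) {
    y <- y + gaussian_band(px, peak_px[i], amp[i], peak_width_px)
  }
  if (is.null(lamp_axis)) lamp_axis <- mapped
  # smooth, positive, lamp-like certified emission
  certified <- 0.4 + exp(-((lamp_axis - stats::median(lamp_axis))^2) /
                           (2 * (diff(range(lamp_axis)) / 2.5)^2))
  resp <- if (is.null(response_curve)) rep(1, length(lamp_axis)) else {
    response_curve(lamp_axis)
  }
  if (any(resp <= 0)) stop("response curve must be positive", call. = FALSE)
  measured <- certified * resp
  list(standard = raman_spectrum(px, y, axis_unit = "pixel"),
       peak_table = data.frame(wavenumber = peak_wavenumbers,
                               pixel = peak_px),
       measured_lamp = measured, certified_lamp = certified,
       lamp_axis = lamp_axis,
       truth = list(coefficients = true_coefficients,
                    response = resp))
}
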