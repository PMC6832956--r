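#' Build an extended multiplicative signal correction model
#'
#' The EMSC design regresses each spectrum on a reference spectrum, the
#' interferent spectra (a water spectrum by default), and a polynomial
#' baseline up to order 2 evaluated on the axis centered and scaled to
#' `[-1, 1]` for conditioning. The design matrix must have full column
#' rank.
#'
#' @param reference reference spectrum (numeric, on `wavenumber`).
#' @param wavenumber shared axis, cm^-1.
#' @param interferents named list of interferent spectra on the same axis;
#'   default a unit-height water curve from [water_reference()].
#' @param poly_order baseline polynomial order (0, 1 or 2; the pipeline
#'   uses first- and second-order terms, i.e. 2).
#' @return list of class `emsc_model` with the design matrix and basis
#'   bookkeeping.
#' @export
emsc_model <- function(reference, wavenumber,
                       interferents = list(water = water_reference(wavenumber)),
                       poly_order = 2) {
  reference <- as.numeric(reference)
  n <- length(wavenumber)
  if (length(reference) != n) {
    stop("reference must be on the target axis", call. = FALSE)
  }
  for (nm in names(interferents)) {
    if (length(interferents[[nm]]) != n) {
      stop("interferent '", nm, "' must be on the target axis",
           call. = FALSE)
    }
  }
  nu <- 2 * (wavenumber - min(wavenumber)) /
    (max(wavenumber) - min(wavenumber)) - 1
  poly <- outer(nu, 0:poly_order, `^`)
  colnames(poly) <- paste0("p", 0:poly_order)
  X <- cbind(reference = reference,
             do.call(cbind, interferents),
             poly)
  if (qr(X)$rank < ncol(X)) {
    stop("EMSC design matrix is rank deficient", call. = FALSE)
  }
  structure(list(reference = reference, wavenumber = wavenumber, nu = nu,
                 interferents = interferents, poly_order = poly_order,
                 design = X),
            class = "emsc_model")
}

#' Fit EMSC coefficients to one spectrum
#'
#' Ordinary least squares of the intensities on the EMSC design:
#' `y ~ b * reference + sum(c_j * interferent_j) + p0 + p1*nu + p2*nu^2`.
#'
#' @param intensity numeric intensity vector on the model axis.
#' @param model an [emsc_model()].
#' @return list of class `emsc_coefficients`: `b` (multiplicative
#'   coefficient on the reference), `interferents` (named), `poly`
#'   (`p0`, `p1`, ...), `residual_norm`, and the full coefficient vector
#'   `all`.
#' @export
emsc_fit <- function(intensity, model) {
  intensity <- as.numeric(intensity)
  if (length(intensity) != nrow(model$design)) {
    stop("spectrum is not on the model axis", call. = FALSE)
  }
  fit <- stats::lm.fit(model$design, intensity)
  cf <- fit$coefficients
  n_int <- length(model$interferents)
  structure(list(
    b = unname(cf[1]),
    interferents = stats::setNames(unname(cf[seq_len(n_int) + 1]),
                                   names(model$interferents)),
    poly = unname(cf[(n_int + 2):length(cf)]),
    residual_norm = sqrt(sum(fit$residuals^2)),
    all = unname(cf)),
    class = "emsc_coefficients")
}

# Fit a whole channels-x-spectra matrix at once (shared QR).
emsc_fit_matrix <- function(intensities, model) {
  qr_x <- qr(model$design)
  coefs <- qr.coef(qr_x, intensities)           # ncol(design) x n_spectra
  resid <- intensities - model$design %*% coefs
  list(coefficients = coefs,
       b = coefs[1, ],
       residual_norm = sqrt(colSums(resid^2)))
}

#' Apply an EMSC correction
#'
#' Subtracts the fitted interferent and polynomial contributions and
#' divides by the multiplicative coefficient, returning the spectrum on
#' the reference scale:
#' `(y - sum(c_j * interferent_j) - poly) / b`.
#'
#' @param intensity numeric intensity vector on the model axis.
#' @param model an [emsc_model()].
#' @param coefficients an [emsc_fit()] result; fitted on the fly when
#'   `NULL`.
#' @param b_floor smallest admissible `|b|`; below it the fit is
#'   degenerate and correction refuses to divide.
#' @return corrected intensity vector.
#' @export
emsc_correct <- function(intensity, model, coefficients = NULL,
                         b_floor = 1e-6) {
  if (is.null(coefficients)) coefficients <- emsc_fit(intensity, model)
  if (!is.finite(coefficients$b) || abs(coefficients$b) < b_floor) {
    stop("degenerate EMSC fit: |b| below floor", call. = FALSE)
  }
  background <- model$design[, -1, drop = FALSE] %*% coefficients$all[-1]
  (as.numeric(intensity) - drop(background)) / coefficients$b
}

#' Default EMSC reference: detrended median spectrum
#'
#' The pipeline's reference is the per-channel median of the (spike
#' cleaned) dataset with a rough second-order polynomial trend removed and
#' shifted to be nonnegative, a stand-in for a background-corrected pollen
#' spectrum. The shift keeps the reference's integrated area well away
#' from zero so the downstream area normalization stays well conditioned.
#' A user-supplied reference is preferred whenever available.
#'
#' @param intensities channels x spectra matrix.
#' @param wavenumber axis, cm^-1.
#' @return numeric reference spectrum.
#' @export
median_reference <- function(intensities, wavenumber) {
  med <- apply(intensities, 1, stats::median)
  nu <- 2 * (wavenumber - min(wavenumber)) /
    (max(wavenumber) - min(wavenumber)) - 1
  X <- cbind(1, nu, nu^2)
  trend <- drop(X %*% stats::lm.fit(X, med)$coefficients)
  out <- med - trend
  out - min(out)
}
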