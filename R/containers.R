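#' Construct a Raman spectrum
#'
#' A spectrum pairs a strictly increasing wavenumber axis (cm^-1) with one
#' intensity trace (arbitrary units) and carries acquisition/label metadata.
#' Default acquisition fields reflect a 785 nm excitation line at 140 mW and
#' 0.5 s integration, the regime the pipeline was designed around.
#'
#' @param wavenumber numeric vector, cm^-1, strictly increasing (or a pixel
#'   index axis for uncalibrated spectra; see `axis_unit`).
#' @param intensity numeric vector, same length as `wavenumber`.
#' @param meta named list of metadata (id, species, genus, family,
#'   growth_habit, acquisition fields).
#' @param axis_unit `"wavenumber"` or `"pixel"`.
#' @return An object of class `raman_spectrum`: a list with elements
#'   `wavenumber`, `intensity`, `meta`, `axis_unit`.
#' @export
raman_spectrum <- function(wavenumber, intensity, meta = list(),
                           axis_unit = c("wavenumber", "pixel")) {
  axis_unit <- match.arg(axis_unit)
  wavenumber <- as.numeric(wavenumber)
  intensity <- as.numeric(intensity)
  if (length(wavenumber) != length(intensity)) {
    stop("`wavenumber` and `intensity` must have equal length", call. = FALSE)
  }
  if (length(wavenumber) >= 2 && any(diff(wavenumber) <= 0)) {
    stop("spectral axis must be strictly increasing", call. = FALSE)
  }
  defaults <- list(excitation_nm = 785, power_mW = 140, integration_s = 0.5)
  meta <- utils::modifyList(defaults, as.list(meta))
  structure(
    list(wavenumber = wavenumber, intensity = intensity, meta = meta,
         axis_unit = axis_unit),
    class = "raman_spectrum"
  )
}

#' @export
print.raman_spectrum <- function(x, ...) {
  rng <- range(x$wavenumber)
  cat(sprintf("<raman_spectrum> %d channels, axis %.1f-%.1f %s\n",
              length(x$wavenumber), rng[1], rng[2],
              if (x$axis_unit == "pixel") "px" else "cm^-1"))
  if (!is.null(x$meta$id)) cat("  id:", x$meta$id, "\n")
  invisible(x)
}

#' Construct a spectral dataset
#'
#' Bundles a shared wavenumber axis, an intensities matrix (channels in rows,
#' one column per spectrum) and a labels manifest with one row per spectrum.
#' The column layout mirrors the on-disk spectra table (first column
#' wavenumber, remaining columns spectra).
#'
#' @param wavenumber shared axis, cm^-1, strictly increasing.
#' @param intensities numeric matrix, `length(wavenumber)` rows.
#' @param manifest data.frame with columns `id`, `species`, `genus`,
#'   `family`, `growth_habit`; `nrow(manifest) == ncol(intensities)`.
#' @return Object of class `spectral_dataset`.
#' @export
spectral_dataset <- function(wavenumber, intensities, manifest) {
  intensities <- as.matrix(intensities)
  if (nrow(intensities) != length(wavenumber)) {
    stop("intensities must have one row per wavenumber channel", call. = FALSE)
  }
  if (length(wavenumber) >= 2 && any(diff(wavenumber) <= 0)) {
    stop("spectral axis must be strictly increasing", call. = FALSE)
  }
  manifest <- as.data.frame(manifest)
  required <- c("id", "species", "genus", "family", "growth_habit")
  missing_cols <- setdiff(required, names(manifest))
  if (length(missing_cols) > 0) {
    stop("manifest is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(manifest) != ncol(intensities)) {
    stop("manifest must have one row per spectrum", call. = FALSE)
  }
  colnames(intensities) <- manifest$id
  structure(
    list(wavenumber = as.numeric(wavenumber), intensities = intensities,
         manifest = manifest),
    class = "spectral_dataset"
  )
}

#' @export
print.spectral_dataset <- function(x, ...) {
  cat(sprintf("<spectral_dataset> %d spectra x %d channels (%.1f-%.1f cm^-1)\n",
              ncol(x$intensities), nrow(x$intensities),
              min(x$wavenumber), max(x$wavenumber)))
  cat(sprintf("  %d species, %d genera, %d families, habits: %s\n",
              length(unique(x$manifest$species)),
              length(unique(x$manifest$genus)),
              length(unique(x$manifest$family)),
              paste(sort(unique(x$manifest$growth_habit)), collapse = ", ")))
  invisible(x)
}

#' Number of spectra in a dataset
#' @param x a `spectral_dataset`.
#' @return integer count.
#' @export
n_spectra <- function(x) ncol(x$intensities)

#' Subset a spectral dataset by spectrum index
#' @param x a `spectral_dataset`.
#' @param idx integer or logical index over spectra (columns).
#' @return a `spectral_dataset` with the selected spectra.
#' @export
subset_spectra <- function(x, idx) {
  spectral_dataset(x$wavenumber,
                   x$intensities[, idx, drop = FALSE],
                   x$manifest[idx, , drop = FALSE])
}
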