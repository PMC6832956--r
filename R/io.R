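#' Write a spectra table
#'
#' Tabular text layout: first column the wavenumber axis, one column per
#' spectrum, header row of spectrum ids.
#'
#' @param dataset a `spectral_dataset`.
#' @param path output file.
#' @param sep delimiter (default tab).
#' @export
write_spectra_table <- function(dataset, path, sep = "\t") {
  tab <- data.frame(wavenumber = dataset$wavenumber,
                    dataset$intensities, check.names = FALSE)
  utils::write.table(tab, path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

# Guess the delimiter of a tabular text file from its header line.
detect_delimiter <- function(path) {
  header <- readLines(path, n = 1)
  counts <- c("\t" = lengths(regmatches(header, gregexpr("\t", header))),
              "," = lengths(regmatches(header, gregexpr(",", header))),
              ";" = lengths(regmatches(header, gregexpr(";", header))))
  if (max(counts) == 0) stop("could not detect delimiter in ", path,
                             call. = FALSE)
  names(counts)[which.max(counts)]
}

#' Read a spectra table
#'
#' Delimiter is auto-detected among comma, tab and semicolon.
#'
#' @param path spectra table as written by [write_spectra_table()].
#' @param manifest optional manifest data.frame to attach; when `NULL`, a
#'   minimal manifest is built from the column ids.
#' @return a `spectral_dataset`.
#' @export
read_spectra_table <- function(path, manifest = NULL) {
  sep <- detect_delimiter(path)
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           check.names = FALSE)
  wn <- tab[[1]]
  intens <- as.matrix(tab[, -1, drop = FALSE])
  if (is.null(manifest)) {
    manifest <- data.frame(id = colnames(intens), species = NA_character_,
                           genus = NA_character_, family = NA_character_,
                           growth_habit = NA_character_,
                           stringsAsFactors = FALSE)
  }
  spectral_dataset(wn, intens, manifest)
}

#' Write / read a labels manifest
#'
#' Delimited text with columns id, species, genus, family, growth_habit.
#'
#' @param manifest data.frame.
#' @param path file path.
#' @param sep delimiter.
#' @export
write_manifest <- function(manifest, path, sep = "\t") {
  utils::write.table(manifest, path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  sep <- detect_delimiter(path)
  manifest <- utils::read.table(path, header = TRUE, sep = sep,
                                check.names = FALSE,
                                stringsAsFactors = FALSE)
  required <- c("id", "species", "genus", "family", "growth_habit")
  missing_cols <- setdiff(required, names(manifest))
  if (length(missing_cols) > 0) {
    stop("manifest schema error: missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  manifest
}

#' Write a grayscale image to TIFF or PNG
#'
#' Intensities are clipped to `[0, 1]`; the format follows the file
#' extension (16-bit for TIFF, 8-bit for PNG by default).
#'
#' @param image numeric matrix on `[0, 1]` (or a [fov_image()]).
#' @param path output path ending in `.tif`, `.tiff` or `.png`.
#' @export
write_image <- function(image, path) {
  if (inherits(image, "fov_image")) image <- image$image
  image <- pmin(pmax(image, 0), 1)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(image, path, bits.per.sample = 16)
  } else if (ext == "png") {
    png::writePNG(image, path)
  } else {
    stop("unsupported image extension: ", ext, call. = FALSE)
  }
  invisible(path)
}

#' Read a grayscale or RGB image
#'
#' @param path `.tif`/`.tiff`/`.png` file.
#' @return numeric matrix (grayscale) or array (RGB), intensities on
#'   `[0, 1]`.
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- if (ext %in% c("tif", "tiff")) {
    tiff::readTIFF(path)
  } else if (ext == "png") {
    png::readPNG(path)
  } else {
    stop("unsupported image extension: ", ext, call. = FALSE)
  }
  if (length(dim(img)) == 3 && dim(img)[3] == 1) img <- img[, , 1]
  img
}
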