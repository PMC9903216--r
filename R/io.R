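#' Read a grayscale enface image from PNG or TIFF
#'
#' Multi-channel images are averaged to grayscale; intensities are
#' returned in \[0, 1\]. Subject and eye identifiers default to values
#' parsed from the file name pattern `<subject>_<eye>.<ext>` when present.
#'
#' @param path image path (.png, .tif or .tiff).
#' @param pixel_um physical pixel size to attach (default 6).
#' @param subject_id,eye optional identifiers overriding the file name.
#' @return an `octa_enface` object.
#' @export
read_enface <- function(path, pixel_um = 6, subject_id = NULL, eye = NULL) {
  if (!file.exists(path)) stop("cannot read image: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  a <- switch(ext,
              png = png::readPNG(path),
              tif = , tiff = tiff::readTIFF(path),
              stop("unsupported image format: .", ext, call. = FALSE))
  if (length(dim(a)) == 3L) a <- apply(a, c(1L, 2L), mean)
  base <- tools::file_path_sans_ext(basename(path))
  parts <- strsplit(base, "_", fixed = TRUE)[[1L]]
  if (is.null(subject_id))
    subject_id <- if (length(parts) >= 2L) paste(utils::head(parts, -1L), collapse = "_") else base
  if (is.null(eye)) {
    last <- utils::tail(parts, 1L)
    eye <- if (last %in% c("right", "left")) last else "right"
  }
  structure(list(pixels = a, pixel_um = pixel_um,
                 subject_id = subject_id, eye = eye),
            class = "octa_enface")
}

#' Write an enface image to PNG or 16-bit TIFF
#'
#' @param img `octa_enface` or numeric matrix in \[0,1\].
#' @param path output path; format chosen by extension.
#' @return the path, invisibly.
#' @export
write_enface <- function(img, path) {
  x <- if (inherits(img, "octa_enface")) img$pixels else img
  x <- clamp(x)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         png = png::writePNG(x, path),
         tif = , tiff = tiff::writeTIFF(x, path, bits.per.sample = 16L),
         stop("unsupported image format: .", ext, call. = FALSE))
  invisible(path)
}

#' Write a binary map as a 0/255 PNG with a JSON parameter sidecar
#'
#' @param map `binary_vessel_map`, `skeleton_map` or logical matrix.
#' @param path output PNG path; the sidecar is written to
#'   `<path>.json` when the map carries provenance.
#' @return the path, invisibly.
#' @export
write_mask <- function(map, path) {
  mask <- if (is.logical(map)) map else map$mask
  png::writePNG(mask * 1.0, path)
  prov <- if (!is.logical(map) && !is.null(map$provenance)) map$provenance else NULL
  if (!is.null(prov))
    jsonlite::write_json(prov, paste0(path, ".json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a binary mask PNG
#'
#' @param path PNG path written by [write_mask()] (or any grayscale PNG;
#'   pixels > 0.5 are foreground).
#' @return logical matrix.
#' @export
read_mask <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3L) a <- a[, , 1L]
  a > 0.5
}
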