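# Image and sidecar IO: 16-bit TIFF/PNG radiometric frames, 8-bit PNG
# grayscale images and masks, JSON sidecars for black-body geometry.

#' Read / write a 16-bit radiometric frame
#'
#' Frames are stored as single-channel 16-bit grayscale TIFF or PNG holding
#' the raw sensor counts.
#'
#' @param path file path (`.tif`, `.tiff` or `.png`).
#' @param frame a [radiometric_frame()].
#' @return `read_thermal_frame()` returns a [radiometric_frame()].
#' @export
read_thermal_frame <- function(path) {
  ext <- tolower(tools::file_ext(path))
  counts <- if (ext %in% c("tif", "tiff")) {
    m <- tiff::readTIFF(path, as.is = TRUE)
    if (length(dim(m)) == 3L) m <- m[, , 1L]
    m
  } else {
    round(png::readPNG(path)[, , drop = TRUE] * 65535)
  }
  radiometric_frame(counts, bit_depth = 16L)
}

#' @rdname read_thermal_frame
#' @export
write_thermal_frame <- function(frame, path) {
  stopifnot(inherits(frame, "radiometric_frame"))
  ext <- tolower(tools::file_ext(path))
  if (!ext %in% c("tif", "tiff"))
    stop("frames are written as 16-bit TIFF; 16-bit PNG output is not ",
         "supported by the available PNG codec")
  tiff::writeTIFF(frame$counts / 65535, path, bits.per.sample = 16L,
                  compression = "none")
  invisible(path)
}

#' Read / write an 8-bit grayscale PNG in `[0, 1]`
#' @param path file path.
#' @param img numeric matrix in `[0, 1]`.
#' @export
read_gray_png <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3L) m <- m[, , 1L]
  m
}

#' @rdname read_gray_png
#' @export
write_gray_png <- function(img, path) {
  png::writePNG(pmin(pmax(unclass(img), 0), 1), path)
  invisible(path)
}

#' Read / write a binary mask PNG
#' @param path file path.
#' @param mask logical or 0/1 matrix.
#' @export
read_mask_png <- function(path) {
  read_gray_png(path) > 0.5
}

#' @rdname read_mask_png
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(matrix(as.numeric(mask != 0), nrow(mask), ncol(mask)), path)
  invisible(path)
}

#' Read / write the black-body geometry sidecar
#'
#' JSON sidecar holding the two reference regions (0-based half-open
#' extents) and their setpoints.
#'
#' @param path file path.
#' @param bb_low,bb_high [blackbody_reference()]s.
#' @return `read_blackbody_sidecar()` returns a list with `bb_low` and
#'   `bb_high`.
#' @export
write_blackbody_sidecar <- function(bb_low, bb_high, path) {
  jsonlite::write_json(
    list(bb_low = list(region = bb_low$region,
                       setpoint_c = bb_low$setpoint_c),
         bb_high = list(region = bb_high$region,
                        setpoint_c = bb_high$setpoint_c)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_blackbody_sidecar
#' @export
read_blackbody_sidecar <- function(path) {
  x <- jsonlite::fromJSON(path)
  list(bb_low = blackbody_reference(x$bb_low$region, x$bb_low$setpoint_c),
       bb_high = blackbody_reference(x$bb_high$region, x$bb_high$setpoint_c))
}
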