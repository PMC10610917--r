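# Radiometric calibration: raw sensor counts -> temperature via two-point
# black-body references, and temperature -> grayscale via a fixed
# temperature window. All pixel regions are 0-based, half-open
# c(row0, row1, col0, col1) intervals.

#' Radiometric frame
#'
#' Raw sensor counts from a thermal camera (unitless ADC values).
#'
#' @param counts integer-valued matrix of sensor counts.
#' @param bit_depth ADC bit depth; counts must lie in `[0, 2^bit_depth)`.
#' @return An object of class `radiometric_frame`.
#' @export
radiometric_frame <- function(counts, bit_depth = 16L) {
  stopifnot(is.matrix(counts), nrow(counts) > 0, ncol(counts) > 0)
  counts <- round(counts)
  if (any(counts < 0) || any(counts >= 2^bit_depth))
    stop(sprintf("counts must lie in [0, 2^%d)", bit_depth))
  structure(list(counts = counts, height = nrow(counts),
                 width = ncol(counts), bit_depth = as.integer(bit_depth)),
            class = "radiometric_frame")
}

#' Black-body reference region
#'
#' A rectangular patch of the frame held at a known set temperature,
#' used as a calibration anchor.
#'
#' @param region integer vector `c(row0, row1, col0, col1)`, 0-based,
#'   half-open.
#' @param setpoint_c set temperature in degrees Celsius, within `[0, 60]`.
#' @return An object of class `blackbody_reference`.
#' @export
blackbody_reference <- function(region, setpoint_c) {
  region <- as.integer(region)
  stopifnot(length(region) == 4L, region[2L] > region[1L],
            region[4L] > region[3L], region[1L] >= 0L, region[3L] >= 0L)
  if (setpoint_c < 0 || setpoint_c > 60)
    stop("setpoint_c outside the plausible [0, 60] degC band")
  structure(list(region = region, setpoint_c = setpoint_c),
            class = "blackbody_reference")
}

region_values <- function(mat, region) {
  if (region[2L] > nrow(mat) || region[4L] > ncol(mat))
    stop("region extends outside the frame")
  mat[(region[1L] + 1L):region[2L], (region[3L] + 1L):region[4L]]
}

#' Two-point black-body calibration
#'
#' Fits the affine count-to-temperature map through the two black-body
#' anchors (region statistic of counts -> setpoint temperature) and applies
#' it pixelwise. Two points determine the affine law uniquely; the paperless
#' choice of region statistic defaults to the mean and may be switched to
#' the median.
#'
#' @param frame a [radiometric_frame()].
#' @param bb_low,bb_high [blackbody_reference()]s; `bb_low` must have the
#'   lower setpoint.
#' @param statistic region summary used as the anchor count.
#' @return Temperature map: numeric matrix in degrees Celsius, same shape
#'   as the frame.
#' @export
calibrate_two_point <- function(frame, bb_low, bb_high,
                                statistic = c("mean", "median")) {
  stopifnot(inherits(frame, "radiometric_frame"),
            inherits(bb_low, "blackbody_reference"),
            inherits(bb_high, "blackbody_reference"))
  statistic <- match.arg(statistic)
  if (bb_low$setpoint_c >= bb_high$setpoint_c)
    stop("bb_low setpoint must be below bb_high setpoint")
  stat_fn <- if (statistic == "mean") mean else stats::median
  m_lo <- stat_fn(region_values(frame$counts, bb_low$region))
  m_hi <- stat_fn(region_values(frame$counts, bb_high$region))
  if (m_lo == m_hi)
    stop("degenerate calibration: identical black-body region counts")
  slope <- (bb_high$setpoint_c - bb_low$setpoint_c) / (m_hi - m_lo)
  tmap <- bb_low$setpoint_c + slope * (frame$counts - m_lo)
  if (!all(is.finite(tmap))) stop("non-finite temperatures after calibration")
  tmap
}

#' Temperature window
#'
#' A fixed temperature interval mapped linearly onto grayscale `[0, 1]`;
#' temperatures outside the window are clipped. The default window is 10
#' degC wide and centred midway between the two black-body setpoints
#' (32 degC).
#'
#' @param center_c window centre in degC.
#' @param width_c window width in degC (> 0).
#' @return An object of class `window_spec`.
#' @export
window_spec <- function(center_c = 32, width_c = 10) {
  stopifnot(width_c > 0)
  structure(list(center_c = center_c, width_c = width_c),
            class = "window_spec")
}

#' Grayscale image container
#'
#' @param values numeric matrix with all values in `[0, 1]`.
#' @param provenance `"raw-windowed"` or `"enhanced"`.
#' @return The matrix with class `grayscale_image` and a provenance
#'   attribute.
#' @export
grayscale_image <- function(values, provenance = c("raw-windowed",
                                                   "enhanced")) {
  provenance <- match.arg(provenance)
  stopifnot(is.matrix(values), all(is.finite(values)),
            all(values >= 0), all(values <= 1))
  structure(values, provenance = provenance,
            class = c("grayscale_image", class(values)))
}

#' Convert a temperature map to grayscale through a temperature window
#'
#' `v = (T - (center - width/2)) / width`, clipped to `[0, 1]`.
#'
#' @param tmap numeric temperature matrix in degC.
#' @param window a [window_spec()].
#' @return A [grayscale_image()] with provenance `"raw-windowed"`.
#' @export
temperature_to_grayscale <- function(tmap, window = window_spec()) {
  stopifnot(inherits(window, "window_spec"), is.matrix(tmap),
            all(is.finite(tmap)))
  lo <- window$center_c - window$width_c / 2
  v <- (tmap - lo) / window$width_c
  grayscale_image(pmin(pmax(v, 0), 1), "raw-windowed")
}

#' Crop away calibration targets
#'
#' Returns the largest axis-aligned sub-image containing none of the given
#' calibration regions (deterministic: ties broken by area, then top row,
#' then left column).
#'
#' @param img a matrix (typically a [grayscale_image()]).
#' @param regions list of 0-based half-open `c(row0, row1, col0, col1)`
#'   extents to exclude. An empty list returns the input unchanged.
#' @return The cropped matrix with attribute `crop_region` (0-based
#'   half-open extent in the original image).
#' @export
crop_calibration_targets <- function(img, regions = list()) {
  if (length(regions) == 0L) {
    attr(img, "crop_region") <- c(0L, nrow(img), 0L, ncol(img))
    return(img)
  }
  blocked <- matrix(FALSE, nrow(img), ncol(img))
  for (rg in regions) {
    rg <- as.integer(rg)
    if (rg[2L] > nrow(img) || rg[4L] > ncol(img) || rg[1L] < 0L || rg[3L] < 0L)
      stop("calibration region extends outside the image")
    blocked[(rg[1L] + 1L):rg[2L], (rg[3L] + 1L):rg[4L]] <- TRUE
  }
  if (all(blocked)) stop("crop failure: regions cover the whole image")
  r <- cpp_largest_free_rect(blocked)
  if (r[1L] < 0L) stop("crop failure: no free rectangle found")
  out <- img[(r[1L] + 1L):r[2L], (r[3L] + 1L):r[4L], drop = FALSE]
  attributes(out) <- c(attributes(out),
                       attributes(img)[setdiff(names(attributes(img)),
                                               c("dim", "crop_region"))])
  attr(out, "crop_region") <- as.integer(r)
  out
}
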