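# Segmentation metrics (Dice, IoU, Hausdorff distance) and image-quality
# metrics (Shannon entropy, MSE, PSNR on the 8-bit scale).

as_mask <- function(m) {
  if (is.logical(m)) return(m)
  stopifnot(all(m %in% c(0, 1)))
  m != 0
}

#' Dice similarity coefficient
#'
#' `DSC = 2|A intersect B| / (|A| + |B|)`; two empty masks score 1.
#'
#' @param a,b binary masks (logical or 0/1 matrices of equal shape).
#' @return DSC in `[0, 1]`.
#' @export
dsc <- function(a, b) {
  a <- as_mask(a); b <- as_mask(b)
  stopifnot(identical(dim(a), dim(b)))
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1)
  2 * sum(a & b) / denom
}

#' Intersection over union
#'
#' `IOU = |A intersect B| / |A union B|`; two empty masks score 1.
#'
#' @inheritParams dsc
#' @return IoU in `[0, 1]`.
#' @export
iou <- function(a, b) {
  a <- as_mask(a); b <- as_mask(b)
  stopifnot(identical(dim(a), dim(b)))
  u <- sum(a | b)
  if (u == 0) return(1)
  sum(a & b) / u
}

# Boundary pixels: mask pixels with a 4-neighbour outside the mask (image
# borders count as outside).
mask_boundary <- function(m) {
  m <- as_mask(m)
  H <- nrow(m); W <- ncol(m)
  pad <- matrix(FALSE, H + 2L, W + 2L)
  pad[2:(H + 1L), 2:(W + 1L)] <- m
  interior <- pad[1:H, 2:(W + 1L)] & pad[3:(H + 2L), 2:(W + 1L)] &
    pad[2:(H + 1L), 1:W] & pad[2:(H + 1L), 3:(W + 2L)]
  m & !interior
}

#' Hausdorff distance between mask boundaries
#'
#' Raw mode: the maximum over both directions of the largest
#' nearest-neighbour Euclidean distance (in pixels) between the two masks'
#' boundary point sets. Normalized mode: `1 - HD / diag`, clipped to
#' `[0, 1]`, where `diag` is the image diagonal — a similarity score in
#' `[0, 1]` with higher values better, used for reporting alongside DSC and
#' IoU. The normalization convention is this package's own, documented
#' stand-in for tabulated HD similarity values.
#'
#' @inheritParams dsc
#' @param normalized return the `[0, 1]` similarity form.
#' @return Distance in pixels (raw) or similarity in `[0, 1]` (normalized).
#' @export
hd <- function(a, b, normalized = FALSE) {
  a <- as_mask(a); b <- as_mask(b)
  stopifnot(identical(dim(a), dim(b)))
  if (sum(a) == 0 || sum(b) == 0)
    stop("Hausdorff distance undefined for an empty mask")
  pa <- which(mask_boundary(a), arr.ind = TRUE)
  pb <- which(mask_boundary(b), arr.ind = TRUE)
  d2 <- outer(pa[, 1L], pb[, 1L], "-")^2 + outer(pa[, 2L], pb[, 2L], "-")^2
  raw <- sqrt(max(apply(d2, 1L, min), apply(d2, 2L, min)))
  if (!normalized) return(raw)
  diag_len <- sqrt((nrow(a) - 1)^2 + (ncol(a) - 1)^2)
  min(max(1 - raw / diag_len, 0), 1)
}

#' Shannon entropy of the intensity histogram
#'
#' Entropy in bits of the `n_bins`-bin intensity histogram of an image in
#' `[0, 1]`. Lower entropy after enhancement indicates mass concentrated in
#' fewer gray levels.
#'
#' @param img numeric matrix in `[0, 1]`.
#' @param n_bins histogram bin count.
#' @return Entropy in bits.
#' @export
entropy <- function(img, n_bins = 256L) {
  v <- as.numeric(img)
  stopifnot(all(v >= 0), all(v <= 1))
  bin <- pmin(floor(v * n_bins), n_bins - 1L)
  p <- tabulate(bin + 1L, nbins = n_bins) / length(v)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Mean squared error on the 8-bit scale
#'
#' MSE between two `[0, 1]` images after scaling to `0..255`, matching the
#' magnitudes conventionally reported for 8-bit imagery.
#'
#' @param img,ref numeric matrices in `[0, 1]` of equal shape.
#' @return MSE in squared 8-bit intensity units.
#' @export
mse <- function(img, ref) {
  stopifnot(identical(dim(img), dim(ref)))
  mean((255 * (as.numeric(img) - as.numeric(ref)))^2)
}

#' Peak signal-to-noise ratio
#'
#' `PSNR = 10 log10(255^2 / MSE)` in dB; `Inf` for identical images.
#'
#' @inheritParams mse
#' @return PSNR in dB.
#' @export
psnr <- function(img, ref) {
  m <- mse(img, ref)
  if (m == 0) return(Inf)
  10 * log10(255^2 / m)
}

#' Segmentation metric report for sets of masks
#'
#' Per-image DSC, IoU and normalized Hausdorff similarity plus their mean
#' and standard deviation.
#'
#' @param preds,gts lists of binary masks of equal length.
#' @return List with `per_image` (data frame) and `summary` (mean/sd rows).
#' @export
evaluate_masks <- function(preds, gts) {
  stopifnot(length(preds) == length(gts), length(preds) >= 1)
  rows <- lapply(seq_along(preds), function(i) {
    hval <- tryCatch(hd(preds[[i]], gts[[i]], normalized = TRUE),
                     error = function(e) NA_real_)
    data.frame(image = i, dsc = dsc(preds[[i]], gts[[i]]),
               iou = iou(preds[[i]], gts[[i]]), hd = hval)
  })
  per_image <- do.call(rbind, rows)
  summary <- data.frame(
    statistic = c("mean", "sd"),
    dsc = c(mean(per_image$dsc), stats::sd(per_image$dsc)),
    iou = c(mean(per_image$iou), stats::sd(per_image$iou)),
    hd = c(mean(per_image$hd, na.rm = TRUE),
           stats::sd(per_image$hd, na.rm = TRUE)))
  list(per_image = per_image, summary = summary)
}
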