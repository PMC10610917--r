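# Two-stage adaptive gamma contrast transform. The gamma exponent is driven
# by two cumulative-distribution statistics of the image: x0 (intensity at
# CDF 0.5) and x1 (intensity at CDF 0.75). Their relative ratio
# beta = (x1 - x0) / x0 selects between two exponent regimes ("stages"):
# dark early-recovery frames (beta <= 1) are brightened, high-contrast
# late-recovery frames (beta > 1) are compressed.

#' Empirical cumulative distribution of a grayscale image
#'
#' CDF over `n_bins` uniform intensity bins on `[0, 1]`: at each bin upper
#' edge `t`, the fraction of pixels with value `<= t`.
#'
#' @param img numeric matrix with values in `[0, 1]`.
#' @param n_bins number of uniform bins.
#' @return An object of class `cdf_profile`: list with `support` (bin edges
#'   `0, 1/n, ..., 1`) and `cdf` (non-decreasing, ending at 1).
#' @export
compute_cdf <- function(img, n_bins = 256L) {
  v <- as.numeric(img)
  stopifnot(length(v) > 0, all(is.finite(v)), all(v >= 0), all(v <= 1),
            n_bins >= 1L)
  n_bins <- as.integer(n_bins)
  # bin 0 holds v == 0; bin k (k >= 1) holds v in ((k-1)/n, k/n]
  bin <- pmin(ceiling(v * n_bins), n_bins)
  counts <- tabulate(bin + 1L, nbins = n_bins + 1L)
  structure(list(support = seq(0, 1, length.out = n_bins + 1L),
                 cdf = cumsum(counts) / length(v),
                 n_bins = n_bins),
            class = "cdf_profile")
}

#' CDF quantile statistics x0 and x1
#'
#' The smallest support values at which the CDF reaches 0.5 (the median,
#' `x0`) and 0.75 (the upper quartile, `x1`), with linear interpolation
#' between bin edges.
#'
#' @param cdf a [compute_cdf()] profile.
#' @return Named numeric vector `c(x0 = , x1 = )` with `x0 <= x1`.
#' @export
quantile_points <- function(cdf) {
  stopifnot(inherits(cdf, "cdf_profile"))
  qp <- function(q) {
    i <- which(cdf$cdf >= q)[1L]
    if (i == 1L) return(cdf$support[1L])
    c0 <- cdf$cdf[i - 1L]; c1 <- cdf$cdf[i]
    s0 <- cdf$support[i - 1L]; s1 <- cdf$support[i]
    s0 + (q - c0) / (c1 - c0) * (s1 - s0)
  }
  x0 <- qp(0.5); x1 <- qp(0.75)
  c(x0 = x0, x1 = max(x0, x1))
}

#' Relative ratio of temperature difference
#'
#' `beta = (x1 - x0) / x0`, with a small floor on the denominator to keep
#' all-black frames from dividing by zero.
#'
#' @param x0,x1 CDF statistics from [quantile_points()].
#' @param eps denominator floor.
#' @return beta (dimensionless, >= 0).
#' @export
compute_beta <- function(x0, x1, eps = 1e-6) {
  stopifnot(x0 >= 0, x1 >= x0)
  (x1 - x0) / max(x0, eps)
}

#' Regime-dependent adaptive gamma exponent
#'
#' For `beta <= 1` (dark, low-contrast regime):
#' `gamma = 0.5 + x0` if `x0 <= 0.5`, else `1 / (1.5 - x0)`.
#' For `beta > 1` (high-contrast regime) the pointwise reciprocal:
#' `gamma = 1 / (0.5 + x0)` if `x0 <= 0.5`, else `1.5 - x0`.
#' Both regimes meet continuously at `x0 = 0.5` with `gamma = 1` and stay
#' strictly positive on `x0` in `[0, 1]`.
#'
#' @param x0 CDF median statistic in `[0, 1]` (vectorized).
#' @param beta regime selector from [compute_beta()].
#' @return gamma exponent(s) > 0.
#' @export
compute_gamma <- function(x0, beta) {
  stopifnot(all(x0 >= 0), all(x0 <= 1))
  low <- ifelse(x0 <= 0.5, 0.5 + x0, 1 / (1.5 - x0))
  if (beta <= 1) low else 1 / low
}

#' Pixelwise gamma (power-law) transform
#'
#' `V_out = V_in ^ gamma`; preserves `[0, 1]` and is strictly increasing.
#'
#' @param img numeric matrix in `[0, 1]`.
#' @param gamma exponent > 0.
#' @return Transformed matrix (a [grayscale_image()] with provenance
#'   `"enhanced"` when the input is a matrix).
#' @export
apply_gamma <- function(img, gamma) {
  stopifnot(gamma > 0)
  grayscale_image(unclass(img)^gamma, "enhanced")
}

#' Gamma-transform parameters
#' @param x0,x1,beta,gamma per-image statistics driving the transform.
#' @return An object of class `gamma_params`.
#' @export
gamma_params <- function(x0, x1, beta, gamma) {
  stopifnot(x0 >= 0, x1 >= x0, x1 <= 1, gamma > 0)
  structure(list(x0 = x0, x1 = x1, beta = beta, gamma = gamma),
            class = "gamma_params")
}

#' Two-stage adaptive gamma enhancement
#'
#' The full pipeline: empirical CDF, quantile statistics, regime ratio
#' beta, regime-dependent exponent, power-law transform. Deterministic.
#'
#' @param img numeric matrix in `[0, 1]` (black bodies should already be
#'   cropped away so calibration patches do not bias the statistics).
#' @param n_bins CDF bin count.
#' @return List with `image` (enhanced [grayscale_image()]) and `params`
#'   (a [gamma_params()]).
#' @export
enhance_two_stage <- function(img, n_bins = 256L) {
  qs <- quantile_points(compute_cdf(img, n_bins))
  beta <- compute_beta(qs[["x0"]], qs[["x1"]])
  g <- compute_gamma(qs[["x0"]], beta)
  list(image = apply_gamma(img, g),
       params = gamma_params(qs[["x0"]], qs[["x1"]], beta, g))
}

#' Single-regime adaptive gamma baseline
#'
#' Applies the dark-regime exponent rule to every image regardless of beta
#' (comparison baseline).
#' @inheritParams enhance_two_stage
#' @return Same structure as [enhance_two_stage()].
#' @export
enhance_adaptive <- function(img, n_bins = 256L) {
  qs <- quantile_points(compute_cdf(img, n_bins))
  beta <- compute_beta(qs[["x0"]], qs[["x1"]])
  g <- compute_gamma(qs[["x0"]], beta = 0)      # always the beta <= 1 rule
  list(image = apply_gamma(img, g),
       params = gamma_params(qs[["x0"]], qs[["x1"]], beta, g))
}

#' Fixed gamma transform baseline
#' @param img numeric matrix in `[0, 1]`.
#' @param gamma constant exponent.
#' @export
fixed_gamma <- function(img, gamma = 0.7) apply_gamma(img, gamma)

#' Histogram equalization baseline
#'
#' Maps each pixel to its empirical CDF value over `n_bins` bins, so the
#' output histogram is approximately uniform.
#' @inheritParams enhance_two_stage
#' @return An enhanced [grayscale_image()].
#' @export
histogram_equalization <- function(img, n_bins = 256L) {
  cdf <- compute_cdf(img, n_bins)
  v <- as.numeric(unclass(img))
  bin <- pmin(ceiling(v * cdf$n_bins), cdf$n_bins)
  out <- cdf$cdf[bin + 1L]
  grayscale_image(matrix(out, nrow(img), ncol(img)), "enhanced")
}

#' Enhancement dispatcher
#'
#' @param img numeric matrix in `[0, 1]`.
#' @param method enhancement method.
#' @param gamma exponent for `method = "fixed"`.
#' @param n_bins CDF bin count.
#' @return List with `image` and (where defined) `params`.
#' @export
enhance_image <- function(img, method = c("two-stage", "adaptive", "fixed",
                                          "hist-eq", "none"),
                          gamma = 0.7, n_bins = 256L) {
  method <- match.arg(method)
  switch(method,
         "two-stage" = enhance_two_stage(img, n_bins),
         "adaptive" = enhance_adaptive(img, n_bins),
         "fixed" = list(image = fixed_gamma(img, gamma), params = NULL),
         "hist-eq" = list(image = histogram_equalization(img, n_bins),
                          params = NULL),
         "none" = list(image = grayscale_image(unclass(img)), params = NULL))
}
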