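test_that("empirical CDF matches the counting oracle at every bin edge", {
  set.seed(11)
  for (rep in 1:5) {
    img <- matrix(runif(32 * 32), 32, 32)
    prof <- compute_cdf(img, 256)
    at <- sapply(prof$support, function(t) oracle_cdf_at(img, t))
    expect_equal(prof$cdf, at, tolerance = 1e-12)
    expect_true(all(diff(prof$cdf) >= 0))
    expect_equal(prof$cdf[length(prof$cdf)], 1)
  }
})

test_that("CDF of a constant image is a unit step", {
  prof <- compute_cdf(matrix(0.5, 8, 8), 256)
  expect_equal(prof$cdf[prof$support < 0.49], rep(0, sum(prof$support < 0.49)))
  expect_equal(prof$cdf[prof$support >= 0.5], rep(1, sum(prof$support >= 0.5)))
})

test_that("four-pixel CDF example: CDF(0.25) = 0.5", {
  img <- matrix(c(0.1, 0.2, 0.3, 0.4), 2, 2)
  prof <- compute_cdf(img, 256)
  expect_equal(prof$cdf[which(prof$support == 0.25)], 0.5)
})

test_that("quantile points agree with the sorting oracle within one bin", {
  set.seed(12)
  bin <- 1 / 256
  for (rep in 1:10) {
    img <- matrix(runif(32 * 32), 32, 32)
    qp <- quantile_points(compute_cdf(img, 256))
    expect_lt(abs(qp[["x0"]] - oracle_quantile(img, 0.5)), bin + 1e-12)
    expect_lt(abs(qp[["x1"]] - oracle_quantile(img, 0.75)), bin + 1e-12)
    expect_lte(qp[["x0"]], qp[["x1"]])
  }
  # uniform law: x0 near 0.5, x1 near 0.75
  big <- matrix(runif(128 * 128), 128, 128)
  qp <- quantile_points(compute_cdf(big, 256))
  expect_lt(abs(qp[["x0"]] - 0.5), 0.05)
  expect_lt(abs(qp[["x1"]] - 0.75), 0.05)
  # degenerate constant image
  qp2 <- quantile_points(compute_cdf(matrix(0.2, 6, 6), 256))
  expect_lt(abs(qp2[["x0"]] - 0.2), 1 / 256)
  expect_lt(abs(qp2[["x1"]] - 0.2), 1 / 256)
  # four-pixel rank rule
  qp3 <- quantile_points(compute_cdf(matrix(c(0.1, 0.2, 0.3, 0.4), 2, 2),
                                     256))
  expect_lt(abs(qp3[["x0"]] - 0.2), 1 / 256 + 1e-12)
  expect_lt(abs(qp3[["x1"]] - 0.3), 1 / 256 + 1e-12)
})

test_that("beta substitutions and the epsilon guard", {
  expect_equal(compute_beta(0.4, 0.6), 0.5)
  expect_equal(compute_beta(0.3, 0.3), 0)
  expect_equal(compute_beta(0.2, 0.5), 1.5)
  expect_true(is.finite(compute_beta(0, 0.5)))      # all-black guard
  expect_gt(compute_beta(0, 0.5), 1)                # routes to beta > 1
})

test_that("gamma regimes: substitutions, unity at the median, reciprocity", {
  expect_equal(compute_gamma(0.5, beta = 0.5), 1)
  expect_equal(compute_gamma(0.5, beta = 2), 1)
  expect_equal(compute_gamma(0.3, beta = 0.5), 0.8)
  expect_equal(compute_gamma(0.3, beta = 2), 1.25)
  expect_equal(compute_gamma(0.8, beta = 0.5), 1 / 0.7)
  x0 <- seq(0, 1, by = 0.01)
  g_low <- compute_gamma(x0, beta = 0.5)
  g_high <- compute_gamma(x0, beta = 2)
  expect_true(all(g_low > 0) && all(g_high > 0))
  expect_lt(max(abs(g_high - 1 / g_low)), 1e-12)
  # continuity at the regime boundary x0 = 0.5
  expect_lt(abs(compute_gamma(0.5 - 1e-9, 0.5) -
                compute_gamma(0.5 + 1e-9, 0.5)), 1e-8)
})

test_that("power-law transform: identity, fixed points, monotonicity", {
  img <- matrix(runif(64), 8, 8)
  expect_equal(unclass(apply_gamma(img, 1)), img, ignore_attr = TRUE)
  expect_equal(unclass(apply_gamma(matrix(0.25, 1, 1), 0.5))[1], 0.5)
  ends <- matrix(c(0, 1), 1, 2)
  for (g in c(0.3, 1, 2.7))
    expect_equal(as.numeric(unclass(apply_gamma(ends, g))), c(0, 1))
  v <- matrix(seq(0.01, 0.99, length.out = 50), 1)
  for (g in c(0.5, 2))
    expect_true(all(diff(as.numeric(unclass(apply_gamma(v, g)))) > 0))
})

test_that("two-stage enhancement leaves a mid-gray constant image alone", {
  img <- matrix(0.5, 16, 16)
  out <- enhance_two_stage(img)
  expect_equal(out$params$gamma, 1, tolerance = 5e-3)
  expect_equal(unclass(out$image), img, tolerance = 1e-2, ignore_attr = TRUE)
})

test_that("dark images are brightened by the beta <= 1 regime", {
  set.seed(13)
  img <- matrix(runif(64 * 64, 0, 0.4), 64, 64)
  out <- enhance_two_stage(img)
  expect_lte(out$params$beta, 1)
  expect_lt(out$params$gamma, 1)
  expect_gt(mean(unclass(out$image)), mean(img))
  expect_gte(median(unclass(out$image)), median(img))
})

test_that("high-contrast late-stage frames select the beta > 1 regime", {
  cfg <- phantom_config(width = 96L, height = 80L, frames = 600L, seed = 5)
  late <- simulate_recovery(cfg, 600L)
  gray <- crop_calibration_targets(
    temperature_to_grayscale(late$frames[[1]], phantom_window(cfg)),
    cfg$bb_regions)
  out <- enhance_two_stage(gray)
  # recompute beta via the sorting oracle
  x0 <- oracle_quantile(unclass(gray), 0.5)
  x1 <- oracle_quantile(unclass(gray), 0.75)
  expect_gt((x1 - x0) / x0, 1)
  expect_gt(out$params$beta, 1)
  expect_gt(out$params$gamma, 1)
})

test_that("histogram equalization flattens the CDF; fixed gamma 1 is identity", {
  set.seed(14)
  img <- matrix(runif(64 * 64), 64, 64)
  eq <- histogram_equalization(img)
  prof <- compute_cdf(unclass(eq), 256)
  # equalized CDF within one bin of the diagonal where support is reachable
  mid <- prof$support >= 1 / 256
  expect_lt(max(abs(prof$cdf[mid] - prof$support[mid])), 2 / 256 + 1 / 4096)
  # already-uniform histogram image is nearly unchanged
  grid <- matrix((rep(1:256, length.out = 1024) - 0.5) / 256, 32, 32)
  eq2 <- histogram_equalization(grid)
  expect_lt(max(abs(unclass(eq2) - grid)), 1 / 256 + 1e-9)
  expect_equal(unclass(fixed_gamma(img, 1)), img, ignore_attr = TRUE)
})
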