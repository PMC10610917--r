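test_that("two-point calibration recovers an arbitrary affine count law", {
  set.seed(101)
  for (rep in 1:5) {
    alpha <- runif(1, 2e-4, 7e-4)         # degC per count
    delta <- runif(1, 0, 10)              # degC at count 0
    counts <- matrix(sample(0:65535, 40 * 50, replace = TRUE), 40, 50)
    k1 <- sample(5000:20000, 1)
    k2 <- sample(30000:60000, 1)
    counts[3:8, 2:7] <- k1
    counts[3:8, 40:45] <- k2
    frame <- radiometric_frame(counts)
    bb_lo <- blackbody_reference(c(2, 8, 1, 7), alpha * k1 + delta)
    bb_hi <- blackbody_reference(c(2, 8, 39, 45), alpha * k2 + delta)
    tmap <- calibrate_two_point(frame, bb_lo, bb_hi)
    expect_lt(max(abs(tmap - (alpha * counts + delta))), 1e-9)
  }
})

test_that("calibration is exact at the anchors and their midpoint", {
  counts <- matrix(1000, 20, 30)
  counts[5:10, 2:6] <- 2000
  counts[5:10, 24:28] <- 6000
  frame <- radiometric_frame(counts)
  bb_lo <- blackbody_reference(c(4, 10, 1, 6), 28)
  bb_hi <- blackbody_reference(c(4, 10, 23, 28), 36)
  tmap <- calibrate_two_point(frame, bb_lo, bb_hi)
  expect_equal(tmap[6, 3], 28)                       # at the low anchor mean
  expect_equal(tmap[6, 25], 36)                      # at the high anchor
  # a pixel exactly midway between the region means maps to 32 degC
  counts2 <- counts
  counts2[1, 1] <- 4000
  tmap2 <- calibrate_two_point(radiometric_frame(counts2), bb_lo, bb_hi)
  expect_equal(tmap2[1, 1], 32)
})

test_that("calibration rejects degenerate and out-of-bounds references", {
  counts <- matrix(3000, 20, 20)
  frame <- radiometric_frame(counts)
  b1 <- blackbody_reference(c(0, 4, 0, 4), 28)
  b2 <- blackbody_reference(c(10, 14, 10, 14), 36)
  expect_error(calibrate_two_point(frame, b1, b2), "degenerate")
  b3 <- blackbody_reference(c(0, 40, 0, 4), 36)
  expect_error(calibrate_two_point(frame, b1, b3), "outside")
  expect_error(calibrate_two_point(frame, b2, b1), "setpoint")
  expect_error(blackbody_reference(c(0, 4, 0, 4), 80), "band")
})

test_that("temperature windowing maps centre to 0.5, clips, preserves order", {
  w <- window_spec(center_c = 30, width_c = 10)
  tm <- matrix(c(30, 28, 24.9, 35.1, 25, 35), 2, 3)
  v <- temperature_to_grayscale(tm, w)
  expect_equal(v[1, 1], 0.5)
  expect_equal(v[2, 1], 0.3)     # 28 degC in a [25, 35] window
  expect_equal(v[1, 2], 0)       # below the window floor
  expect_equal(v[2, 2], 1)       # above the window ceiling
  # monotone in temperature
  tt <- matrix(seq(20, 40, length.out = 50), 1)
  vv <- temperature_to_grayscale(tt, w)
  expect_true(all(diff(as.numeric(vv)) >= 0))
})

test_that("window round trip is the identity inside the window", {
  w <- window_spec(center_c = 32, width_c = 10)
  temps <- matrix(runif(100, 27.01, 36.99), 10, 10)
  v <- temperature_to_grayscale(temps, w)
  back <- (unclass(v) * w$width_c) + (w$center_c - w$width_c / 2)
  expect_equal(back, temps, tolerance = 1e-12, ignore_attr = TRUE)
  v2 <- temperature_to_grayscale(back, w)
  expect_lt(max(abs(unclass(v2) - unclass(v))), 1e-12)
})

test_that("cropping removes margin calibration strips, keeps the centre", {
  img <- matrix(runif(100 * 100), 100, 100)
  # strips on the left and right margins, as in the camera's layout
  regions <- list(c(40, 60, 0, 10), c(40, 60, 90, 100))
  out <- crop_calibration_targets(img, regions)
  rg <- attr(out, "crop_region")
  expect_equal(rg[3:4], c(10L, 90L))
  expect_equal(rg[1:2], c(0L, 100L))
  expect_equal(dim(out), c(100L, 80L))
})

test_that("cropping with no regions is the identity", {
  img <- matrix(runif(30 * 20), 30, 20)
  out <- crop_calibration_targets(img, list())
  expect_equal(unclass(out)[, ], img, ignore_attr = TRUE)
})

test_that("one 10-px margin strip on a 100-px-wide image leaves 90 px", {
  img <- matrix(0, 40, 100)
  out <- crop_calibration_targets(img, list(c(0, 40, 0, 10)))
  expect_equal(dim(out), c(40L, 90L))
  expect_equal(attr(out, "crop_region"), c(0L, 40L, 10L, 100L))
})

test_that("crop matches an exhaustive largest-free-rectangle search", {
  set.seed(77)
  oracle_area <- function(blocked) {
    H <- nrow(blocked); W <- ncol(blocked); best <- 0
    for (r0 in 1:H) for (r1 in r0:H) for (c0 in 1:W) for (c1 in c0:W)
      if (!any(blocked[r0:r1, c0:c1]))
        best <- max(best, (r1 - r0 + 1) * (c1 - c0 + 1))
    best
  }
  for (rep in 1:5) {
    H <- 8; W <- 10
    img <- matrix(0, H, W)
    blocked <- matrix(runif(H * W) < 0.2, H, W)
    if (all(blocked)) next
    regions <- lapply(which(blocked), function(i) {
      r <- (i - 1) %% H; c <- (i - 1) %/% H
      c(r, r + 1, c, c + 1)
    })
    out <- crop_calibration_targets(img, regions)
    expect_equal(prod(dim(out)), oracle_area(blocked))
  }
})

test_that("crop fails when regions cover everything", {
  img <- matrix(0, 5, 5)
  expect_error(crop_calibration_targets(img, list(c(0, 5, 0, 5))),
               "crop failure")
})
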