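test_that("input stem reduces a 64x64 image to 16x16 deterministically", {
  net <- new_pfsnet(pfs_config(64, 1 / 8), seed = 3)
  x <- pfseg:::ag_const(array(runif(64 * 64), c(64, 64, 1, 1)))
  out <- net$stem(x)
  d <- dim(pfseg:::ag_value(out))
  expect_equal(d[1:2], c(16L, 16L))
  expect_equal(d[3], net$config$stem_ch)
  zero <- pfseg:::ag_const(array(0, c(64, 64, 1, 1)))
  expect_true(all(is.finite(pfseg:::ag_value(net$stem(zero)))))
  out2 <- net$stem(x)
  expect_identical(pfseg:::ag_value(out), pfseg:::ag_value(out2))
})

test_that("RSU blocks preserve spatial shape across depths", {
  for (L in 4:7) {
    blk <- new_rsu(rsu_spec(L, 3, 4, 5), seed = L)
    x <- array(rnorm(64 * 64 * 3 * 1), c(64, 64, 3, 1))
    out <- blk$forward(x)
    expect_equal(dim(out), c(64L, 64L, 5L, 1L))
  }
})

test_that("RSU with a zeroed U-path equals its local F1 transform", {
  spec <- rsu_spec(4, 1, 2, 3)
  blk <- new_rsu(spec, seed = 9)
  rsu_zero_upath(blk)
  set.seed(10)
  x <- array(rnorm(12 * 12), c(12, 12, 1, 1))
  # independent F1 oracle: scalar-loop 3x3 same-pad convolution plus the
  # eval-mode normalization (running mean 0, var 1) and ReLU
  expect_equal(blk$forward(x), oracle_rsu_f1(blk, x), tolerance = 1e-12)
})

test_that("dilated RSU-4F keeps input resolution, even at tiny sizes", {
  blk <- new_rsu(rsu_spec(4, 2, 3, 4, dilated = TRUE), seed = 4)
  for (s in c(1L, 3L, 8L)) {
    x <- array(rnorm(s * s * 2), c(s, s, 2, 1))
    expect_equal(dim(blk$forward(x)), c(s, s, 4L, 1L))
  }
})

test_that("non-dilated RSU rejects inputs too small for its pooling depth", {
  blk <- new_rsu(rsu_spec(6, 1, 2, 2), seed = 5)
  x <- array(rnorm(8 * 8), c(8, 8, 1, 1))
  expect_error(blk$forward(x), "spatial size")
})

test_that("CBAM gates stay in (0,1), bound the output, and can be opened", {
  cb <- new_cbam(8, reduction = 4, seed = 6)
  x <- array(rnorm(10 * 10 * 8 * 2), c(10, 10, 8, 2))
  out <- cb$forward(x)
  expect_equal(dim(out), dim(x))
  expect_true(all(abs(out) <= abs(x) + 1e-12))
  # force both attention gates fully open: identity
  cb$params[["cbam.mlp.W2"]]$value[] <- 0
  cb$params[["cbam.mlp.b2"]]$value[] <- 60
  cb$params[["cbam.sp.W"]]$value[] <- 0
  cb$params[["cbam.sp.b"]]$value[] <- 60
  expect_equal(cb$forward(x), x, tolerance = 1e-12)
})

test_that("nested grid wiring has the expected nodes and input arities", {
  net <- new_pfsnet(pfs_config(64, 1 / 8), seed = 2)
  want <- c()
  for (i in 0:3) for (j in 1:(4 - i)) want <- c(want, sprintf("x%d%d", i, j))
  expect_setequal(names(net$nested), want)
  # node (i, j) concatenates j same-row maps plus one up-sampled map
  oc <- net$config$out_ch
  for (i in 0:3) for (j in 1:(4 - i)) {
    cin_declared <- dim(net$params[[sprintf("x%d%d.rsu.in.W", i, j)]]$value)[3]
    expect_equal(cin_declared, j * oc[i + 1] + oc[i + 2])
  }
})

test_that("forward output has no accidental mirror symmetry", {
  net <- new_pfsnet(pfs_config(64, 1 / 8), seed = 8)
  set.seed(9)
  x <- matrix(runif(64 * 64), 64, 64)
  a <- pfs_forward(net, x)$fused[, , 1]
  b <- pfs_forward(net, x[, 64:1])$fused[, , 1]
  expect_equal(dim(b), dim(a))
  expect_gt(max(abs(b[, 64:1] - a)), 1e-6)
})

test_that("parameter count scales ~4x with a 2x width multiplier", {
  p1 <- param_count(new_pfsnet(pfs_config(64, 1 / 8), seed = 1))
  p2 <- param_count(new_pfsnet(pfs_config(64, 1 / 4), seed = 1))
  expect_gt(p2 / p1, 3.4)
  expect_lt(p2 / p1, 4.4)
})

test_that("checkpoints round-trip bit-for-bit and guard the architecture", {
  net <- new_pfsnet(pfs_config(64, 1 / 8), seed = 12)
  x <- matrix(runif(64 * 64), 64, 64)
  before <- pfs_forward(net, x)
  path <- tempfile(fileext = ".rds")
  save_checkpoint(net, path)
  net2 <- load_checkpoint(path)
  expect_identical(pfs_forward(net2, x), before)
  # tampered architecture hash is refused
  obj <- readRDS(path)
  obj$hash <- "00000000"
  saveRDS(obj, path)
  expect_error(load_checkpoint(path), "hash mismatch")
})

test_that("forward pass rejects inputs of the wrong size", {
  net <- new_pfsnet(pfs_config(64, 1 / 8), seed = 1)
  expect_error(pfs_forward(net, matrix(0, 32, 32)), "input must be")
})
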