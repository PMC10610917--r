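count_components <- function(mask) {
  # 4-connected flood fill
  lab <- matrix(0L, nrow(mask), ncol(mask))
  n <- 0L
  for (r in seq_len(nrow(mask))) for (c in seq_len(ncol(mask))) {
    if (!mask[r, c] || lab[r, c] > 0L) next
    n <- n + 1L
    queue <- list(c(r, c)); lab[r, c] <- n
    while (length(queue) > 0L) {
      p <- queue[[length(queue)]]; queue[[length(queue)]] <- NULL
      for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        q <- p + d
        if (q[1] < 1 || q[1] > nrow(mask) || q[2] < 1 || q[2] > ncol(mask))
          next
        if (mask[q[1], q[2]] && lab[q[1], q[2]] == 0L) {
          lab[q[1], q[2]] <- n
          queue[[length(queue) + 1L]] <- q
        }
      }
    }
  }
  n
}

test_that("foot masks: two mirror-symmetric components of sensible area", {
  for (sd in c(1, 5, 42)) {
    cfg <- phantom_config(width = 96L, height = 80L, seed = sd)
    m <- make_foot_masks(cfg)
    expect_equal(count_components(m), 2L)
    expect_identical(m, m[, ncol(m):1])           # left = flipped right
    frac <- mean(m)
    expect_gt(frac, 0.10)
    expect_lt(frac, 0.45)
    # deterministic per seed
    expect_identical(m, make_foot_masks(cfg))
  }
})

test_that("noise-free recovery follows the exponential rewarming law", {
  cfg <- phantom_config(width = 64L, height = 48L, frames = 900L,
                        noise_sd_c = 0, nonuniform_cooling = FALSE,
                        seed = 3)
  seqn <- simulate_recovery(cfg, c(1L, 100L, 300L, 900L))
  m <- seqn$mask
  # t = 0: feet exactly at the start temperature
  expect_true(all(seqn$frames[[1]][m] == cfg$foot_start_temp_c))
  # background constant everywhere outside feet and black bodies
  bb <- matrix(FALSE, cfg$height, cfg$width)
  for (rg in cfg$bb_regions) bb[(rg[1] + 1):rg[2], (rg[3] + 1):rg[4]] <- TRUE
  bg <- !m & !bb
  for (fr in seqn$frames)
    expect_true(all(fr[bg] == cfg$background_temp_c))
  # foot mean strictly increasing, bounded by (start, end)
  mu <- sapply(seqn$frames, function(fr) mean(fr[m]))
  expect_true(all(diff(mu) > 0))
  expect_true(all(mu >= cfg$foot_start_temp_c & mu < cfg$foot_end_temp_c))
  # asymptote: late frame close to body temperature
  expect_lt(cfg$foot_end_temp_c - mu[4], 0.2)
  # closed-form minimum-contrast crossing time
  t_star <- cfg$recovery_time_constant_s *
    log((cfg$foot_end_temp_c - cfg$foot_start_temp_c) /
        (cfg$foot_end_temp_c - cfg$background_temp_c))
  cross <- simulate_recovery(cfg, round(t_star) + 1L)
  contrast <- abs(mean(cross$frames[[1]][m]) - cfg$background_temp_c)
  expect_lt(contrast, 0.04)      # below the NETD noise scale
})

test_that("same seed reproduces frames bit-for-bit, different seeds differ", {
  cfg <- phantom_config(width = 48L, height = 40L, frames = 30L, seed = 9)
  a <- simulate_recovery(cfg, c(5L, 20L))
  b <- simulate_recovery(cfg, c(5L, 20L))
  expect_identical(a$frames, b$frames)
  cfg2 <- cfg; cfg2$seed <- 10L
  c_ <- simulate_recovery(cfg2, c(5L, 20L))
  expect_false(identical(a$frames[[1]], c_$frames[[1]]))
  # lazily generated subsets agree with the full sequence
  full <- simulate_recovery(cfg)
  expect_identical(full$frames[[20]], a$frames[[2]])
})

test_that("counts conversion is the stated affine law, 16-bit bounded", {
  cfg <- phantom_config(width = 48L, height = 40L, seed = 2)
  fr <- simulate_recovery(cfg, 1L)$frames[[1]]
  cts <- phantom_counts(cfg, fr)
  expect_s3_class(cts, "radiometric_frame")
  expect_equal(cts$counts,
               round(cfg$count_offset + cfg$count_gain * fr))
  expect_true(all(cts$counts >= 0 & cts$counts < 65536))
})

test_that("dataset plumbing: stride sampling, flip doubling, determinism", {
  cfg <- phantom_config(width = 48L, height = 40L, frames = 60L, seed = 4)
  d1 <- file.path(tempdir(), "ds1"); d2 <- file.path(tempdir(), "ds2")
  on.exit(unlink(c(d1, d2), recursive = TRUE), add = TRUE)
  man <- build_dataset(cfg, n_subjects = 3, sampling_stride = 10L,
                       out_dir = d1, flip = TRUE, enhance = TRUE,
                       split = c(1 / 3, 1 / 3, 1 / 3))
  # 60 frames, stride 10 -> 6 samples per subject; flip doubles train only
  expect_equal(sum(!man$flipped), 3 * 6)
  expect_equal(sum(man$flipped), sum(man$split == "train" & !man$flipped))
  # split is by sequence
  expect_equal(length(unique(man$subject[man$split == "train"])), 1)
  tab <- table(unique(man[, c("subject", "split")])$split)
  expect_equal(sort(as.integer(tab)), c(1L, 1L, 1L))
  # flipped pairs are consistent
  fl <- man[man$flipped, ][1, ]
  orig <- man[man$subject == fl$subject & man$frame == fl$frame &
              !man$flipped, ]
  im_f <- read_gray_png(file.path(d1, fl$image))
  im_o <- read_gray_png(file.path(d1, orig$image))
  expect_equal(im_f, im_o[, ncol(im_o):1])
  mk_f <- read_mask_png(file.path(d1, fl$mask))
  mk_o <- read_mask_png(file.path(d1, orig$mask))
  expect_identical(mk_f, mk_o[, ncol(mk_o):1])
  # identical seed => bit-identical dataset
  build_dataset(cfg, n_subjects = 3, sampling_stride = 10L,
                out_dir = d2, flip = TRUE, enhance = TRUE,
                split = c(1 / 3, 1 / 3, 1 / 3))
  f1 <- list.files(d1, recursive = TRUE)
  f2 <- list.files(d2, recursive = TRUE)
  expect_identical(f1, f2)
  h1 <- tools::md5sum(file.path(d1, f1))
  h2 <- tools::md5sum(file.path(d2, f2))
  expect_identical(unname(h1), unname(h2))
})

test_that("loading a dataset returns aligned image/mask pairs", {
  cfg <- phantom_config(width = 48L, height = 40L, frames = 20L, seed = 6)
  d <- file.path(tempdir(), "ds3")
  on.exit(unlink(d, recursive = TRUE), add = TRUE)
  build_dataset(cfg, n_subjects = 2, sampling_stride = 10L, out_dir = d,
                flip = FALSE, enhance = FALSE, split = c(0.5, 0, 0.5))
  tr <- load_dataset(d, "train", size = 32L)
  expect_equal(length(tr$images), 2)
  expect_equal(dim(tr$images[[1]]), c(32L, 32L))
  expect_type(tr$masks[[1]][1, 1], "logical")
})

test_that("phantom regime coverage: early frames beta <= 1, late beta > 1", {
  cfg <- phantom_config(width = 96L, height = 80L, frames = 600L, seed = 8)
  win <- phantom_window(cfg)
  seqn <- simulate_recovery(cfg, c(1L, 600L))
  grays <- lapply(seqn$frames, function(fr)
    crop_calibration_targets(temperature_to_grayscale(fr, win),
                             cfg$bb_regions))
  expect_lte(enhance_two_stage(grays[[1]])$params$beta, 1)
  expect_gt(enhance_two_stage(grays[[2]])$params$beta, 1)
})
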