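# Seeded synthetic thermogram phantoms: two foot-shaped regions rewarming
# exponentially from below ambient towards body temperature in front of a
# constant-temperature background, with black-body calibration patches,
# NETD-scale sensor noise and optional non-uniform cooling patches. The
# generator emulates the cold-stressed acquisition protocol (ambient about
# 22 degC, 10-15 min sequences at 1 Hz, 16-bit radiometric frames) so the
# whole pipeline can be exercised without clinical data.

with_preserved_rng <- function(seed, thunk) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
  })
  set.seed(seed)
  thunk()
}

derived_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + 104729 * as.numeric(k)) %%
               2147483647)
}

#' Phantom sequence configuration
#'
#' Defines one synthetic cold-recovery acquisition. Defaults follow the
#' acquisition conditions of the emulated protocol: 640x512 16-bit frames
#' at 1 Hz, ambient background about 22 degC, feet cooled to 18 degC
#' rewarming towards 36 degC, sensor noise at the camera's NETD scale
#' (0.04 degC), and black-body patches at 28 and 36 degC on the left and
#' right image margins.
#'
#' @param width,height frame size in pixels.
#' @param background_temp_c constant ambient background temperature (degC).
#' @param foot_start_temp_c foot temperature at the start of recovery.
#' @param foot_end_temp_c asymptotic foot temperature (body temperature).
#' @param recovery_time_constant_s exponential rewarming time constant tau;
#'   the foot-background contrast vanishes at
#'   `t* = tau * log((T_end - T_start) / (T_end - T_bg))`.
#' @param frames number of frames in the sequence.
#' @param frame_interval_s seconds between frames.
#' @param noise_sd_c additive zero-mean Gaussian sensor noise (degC).
#' @param bb_setpoints_c the two black-body set temperatures (low, high).
#' @param window_center_c centre of the fixed temperature window used when
#'   converting phantom frames to grayscale. Defaults to 1 degC above the
#'   ambient background, which places the constant background at gray level
#'   0.4: the background stays visible (as in real cold-stressed scenes),
#'   cooled feet start at the display floor and rewarmed feet saturate at
#'   the top of the window.
#' @param window_width_c width of the temperature window (degC).
#' @param nonuniform_cooling add 1-3 Gaussian warm/cold patches inside each
#'   foot (amplitude up to `patch_amp_c`), decaying with the same time
#'   constant as the rewarming, to emulate irregular cooling.
#' @param patch_amp_c maximum absolute patch amplitude in degC.
#' @param count_gain,count_offset affine temperature-to-counts law of the
#'   synthetic camera (`counts = offset + gain * T`, rounded).
#' @param seed integer seed; the whole sequence is a pure function of the
#'   configuration.
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(width = 640L, height = 512L,
                           background_temp_c = 22,
                           foot_start_temp_c = 18,
                           foot_end_temp_c = 36,
                           recovery_time_constant_s = 180,
                           frames = 600L, frame_interval_s = 1,
                           noise_sd_c = 0.04,
                           bb_setpoints_c = c(28, 36),
                           window_center_c = NULL,
                           window_width_c = 10,
                           nonuniform_cooling = TRUE,
                           patch_amp_c = 1.5,
                           count_gain = 400, count_offset = 4000,
                           seed = 1L) {
  stopifnot(foot_start_temp_c < background_temp_c,
            background_temp_c < foot_end_temp_c,
            noise_sd_c >= 0, frames >= 1, width >= 32, height >= 32,
            recovery_time_constant_s > 0,
            bb_setpoints_c[1L] < bb_setpoints_c[2L], window_width_c > 0)
  if (is.null(window_center_c)) window_center_c <- background_temp_c + 1
  width <- as.integer(width); height <- as.integer(height)
  # black-body patches: square-ish strips on the left and right margins
  side <- max(4L, height %/% 8L)
  r0 <- (height - side) %/% 2L
  margin <- max(2L, width %/% 40L)
  bb_regions <- list(c(r0, r0 + side, margin, margin + side),
                     c(r0, r0 + side, width - margin - side, width - margin))
  structure(list(width = width, height = height,
                 background_temp_c = background_temp_c,
                 foot_start_temp_c = foot_start_temp_c,
                 foot_end_temp_c = foot_end_temp_c,
                 recovery_time_constant_s = recovery_time_constant_s,
                 frames = as.integer(frames),
                 frame_interval_s = frame_interval_s,
                 noise_sd_c = noise_sd_c,
                 bb_setpoints_c = bb_setpoints_c,
                 window_center_c = window_center_c,
                 window_width_c = window_width_c,
                 bb_regions = bb_regions,
                 nonuniform_cooling = isTRUE(nonuniform_cooling),
                 patch_amp_c = patch_amp_c,
                 count_gain = count_gain, count_offset = count_offset,
                 seed = as.integer(seed)),
            class = "phantom_config")
}

# Deterministic foot geometry for a config (list: left, right, combined).
phantom_geometry <- function(cfg) {
  with_preserved_rng(derived_seed(cfg$seed, 1L), function() {
    H <- cfg$height; W <- cfg$width
    scale <- stats::runif(1, 0.9, 1.1)
    cy <- H * (0.55 + stats::runif(1, -0.02, 0.02))
    cx <- W * (0.5 - 0.17 + stats::runif(1, -0.01, 0.01))
    a <- W * 0.12 * scale           # ellipse semi-axis, columns
    b <- H * 0.28 * scale           # ellipse semi-axis, rows
    rr <- matrix(seq_len(H), H, W)
    cc <- matrix(seq_len(W), H, W, byrow = TRUE)
    left <- ((rr - cy) / b)^2 + ((cc - cx) / a)^2 <= 1
    # five toe disks centred just inside the upper ellipse boundary so each
    # bulges outward while staying connected to the body
    toe_r <- 0.030 * H * scale
    for (k in 1:5) {
      phi <- (k - 3) * 0.45            # angle from vertical
      tx <- cx + 0.92 * a * sin(phi)
      ty <- cy - 0.95 * b * cos(phi)
      left <- left | ((rr - ty)^2 + (cc - tx)^2 <= toe_r^2)
    }
    right <- left[, W:1]
    if (any(left & right))
      stop("phantom geometry collision: feet overlap")
    for (rg in cfg$bb_regions) {
      patch <- matrix(FALSE, H, W)
      patch[(rg[1L] + 1L):rg[2L], (rg[3L] + 1L):rg[4L]] <- TRUE
      if (any(patch & (left | right)))
        stop("phantom geometry collision: foot touches a black body")
    }
    list(left = left, right = right, mask = left | right)
  })
}

#' Ground-truth foot masks for a phantom configuration
#'
#' Two mirror-symmetric foot-like blobs (an ellipse body plus five toe
#' disks), placed away from the black-body patches; deterministic per seed.
#'
#' @param cfg a [phantom_config()].
#' @return Logical `height x width` matrix (TRUE = foot).
#' @export
make_foot_masks <- function(cfg) {
  stopifnot(inherits(cfg, "phantom_config"))
  phantom_geometry(cfg)$mask
}

# Non-uniform cooling offsets: a temperature offset field (degC at t = 0)
# supported inside the feet, decaying through recovery.
phantom_patches <- function(cfg, geom) {
  if (!cfg$nonuniform_cooling)
    return(matrix(0, cfg$height, cfg$width))
  with_preserved_rng(derived_seed(cfg$seed, 2L), function() {
    H <- cfg$height; W <- cfg$width
    rr <- matrix(seq_len(H), H, W)
    cc <- matrix(seq_len(W), H, W, byrow = TRUE)
    off <- matrix(0, H, W)
    for (side in list(geom$left, geom$right)) {
      idx <- which(side, arr.ind = TRUE)
      n_p <- sample(1:3, 1)
      for (k in seq_len(n_p)) {
        ctr <- idx[sample(nrow(idx), 1), ]
        amp <- stats::runif(1, -cfg$patch_amp_c, cfg$patch_amp_c)
        sig <- stats::runif(1, 0.03, 0.06) * H
        off <- off + amp * exp(-((rr - ctr[1L])^2 + (cc - ctr[2L])^2) /
                                 (2 * sig^2)) * side
      }
    }
    off
  })
}

# Noise-free temperature field at time t (seconds).
phantom_temperature <- function(cfg, geom, patches, t) {
  decay <- exp(-t / cfg$recovery_time_constant_s)
  foot_t <- cfg$foot_end_temp_c -
    (cfg$foot_end_temp_c - cfg$foot_start_temp_c) * decay
  tmap <- matrix(cfg$background_temp_c, cfg$height, cfg$width)
  tmap[geom$mask] <- foot_t
  tmap <- tmap + patches * decay
  for (i in 1:2) {
    rg <- cfg$bb_regions[[i]]
    tmap[(rg[1L] + 1L):rg[2L], (rg[3L] + 1L):rg[4L]] <- cfg$bb_setpoints_c[i]
  }
  tmap
}

#' Simulate a cold-recovery phantom sequence
#'
#' Foot pixels follow `T(t) = T_end - (T_end - T_start) exp(-t / tau)`;
#' the background stays constant; black-body patches are held at their
#' setpoints; zero-mean Gaussian noise of sd `noise_sd_c` is added to every
#' pixel of every frame (seeded per frame, so any subset of frames is
#' reproducible without generating the rest).
#'
#' @param cfg a [phantom_config()].
#' @param frame_indices 1-based frame indices to generate (default: all).
#' @return An object of class `phantom_sequence`: list with `frames`
#'   (temperature matrices, degC), `mask` (static ground truth),
#'   `timestamps` (seconds), `frame_indices` and `config`.
#' @export
simulate_recovery <- function(cfg, frame_indices = NULL) {
  stopifnot(inherits(cfg, "phantom_config"))
  if (is.null(frame_indices)) frame_indices <- seq_len(cfg$frames)
  stopifnot(all(frame_indices >= 1), all(frame_indices <= cfg$frames))
  geom <- phantom_geometry(cfg)
  patches <- phantom_patches(cfg, geom)
  frames <- lapply(frame_indices, function(i) {
    t <- (i - 1) * cfg$frame_interval_s
    tmap <- phantom_temperature(cfg, geom, patches, t)
    if (cfg$noise_sd_c > 0) {
      tmap <- tmap + with_preserved_rng(derived_seed(cfg$seed, 100L + i),
                                        function()
        matrix(stats::rnorm(length(tmap), 0, cfg$noise_sd_c),
               nrow(tmap), ncol(tmap)))
    }
    tmap
  })
  structure(list(frames = frames, mask = geom$mask,
                 timestamps = (frame_indices - 1) * cfg$frame_interval_s,
                 frame_indices = frame_indices, config = cfg),
            class = "phantom_sequence")
}

#' Convert a phantom temperature frame to raw sensor counts
#'
#' Applies the synthetic camera's affine temperature-to-counts law and
#' quantizes to the 16-bit ADC range.
#'
#' @param cfg a [phantom_config()].
#' @param tmap a temperature matrix from [simulate_recovery()].
#' @return A [radiometric_frame()].
#' @export
phantom_counts <- function(cfg, tmap) {
  counts <- round(cfg$count_offset + cfg$count_gain * tmap)
  radiometric_frame(pmin(pmax(counts, 0), 2^16 - 1), bit_depth = 16L)
}

#' Build an image/mask dataset from phantom sequences
#'
#' Generates `n_subjects` independent sequences (per-subject seeds derived
#' from the base seed), samples every `sampling_stride`-th frame, windows
#' each sampled temperature frame to grayscale, crops away the black-body
#' patches, optionally applies the two-stage adaptive gamma transform and
#' horizontal-flip augmentation (training split only), writes image/mask
#' PNG pairs plus a JSON manifest, and splits by sequence into
#' train/validation/test buckets (floor(0.85 n) / floor(0.05 n) /
#' remainder) so that no sequence contributes frames to two buckets.
#'
#' @param cfg base [phantom_config()] (per-subject seed is `seed + subject`).
#' @param n_subjects number of sequences.
#' @param sampling_stride keep one frame in every `sampling_stride`.
#' @param out_dir output directory (created).
#' @param flip horizontally flip training images (doubles the training
#'   count, with masks flipped consistently).
#' @param enhance apply [enhance_two_stage()] to every image.
#' @param split train/validation/test fractions.
#' @return Invisibly, the manifest data frame (columns: subject, frame,
#'   split, flipped, image, mask).
#' @export
build_dataset <- function(cfg, n_subjects, sampling_stride = 10L,
                          out_dir, flip = TRUE, enhance = TRUE,
                          split = c(0.85, 0.05, 0.10)) {
  stopifnot(inherits(cfg, "phantom_config"), n_subjects >= 1,
            sampling_stride >= 1, abs(sum(split) - 1) < 1e-9)
  n_tr <- floor(split[1L] * n_subjects)
  n_va <- floor(split[2L] * n_subjects)
  n_te <- n_subjects - n_tr - n_va
  if (n_subjects > 1 && (n_tr < 1 || n_te < 1))
    stop("split smaller than one sequence per bucket")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (d in c("images", "masks"))
    dir.create(file.path(out_dir, d), showWarnings = FALSE)
  order_ <- with_preserved_rng(derived_seed(cfg$seed, 3L),
                               function() sample(n_subjects))
  bucket <- rep(c("train", "val", "test"), times = c(n_tr, n_va, n_te))
  subject_split <- stats::setNames(bucket, order_)

  window <- phantom_window(cfg)
  rows <- list()
  for (s in seq_len(n_subjects)) {
    cfg_s <- cfg
    cfg_s$seed <- derived_seed(cfg$seed, 1000L + s)
    idx <- seq(1L, cfg$frames, by = sampling_stride)
    seqn <- simulate_recovery(cfg_s, idx)
    mask_crop <- NULL
    this_split <- subject_split[[as.character(s)]]
    for (k in seq_along(idx)) {
      gray <- temperature_to_grayscale(seqn$frames[[k]], window)
      gray <- crop_calibration_targets(gray, cfg$bb_regions)
      if (is.null(mask_crop)) {
        rg <- attr(gray, "crop_region")
        mask_crop <- seqn$mask[(rg[1L] + 1L):rg[2L], (rg[3L] + 1L):rg[4L]]
      }
      img <- if (enhance) enhance_two_stage(gray)$image else gray
      variants <- list(list(tag = "", im = unclass(img), mk = mask_crop))
      if (flip && this_split == "train")
        variants <- c(variants, list(list(tag = "_flip",
                                          im = unclass(img)[, ncol(img):1],
                                          mk = mask_crop[, ncol(mask_crop):1])))
      for (v in variants) {
        base <- sprintf("s%03d_f%05d%s", s, idx[k], v$tag)
        img_path <- file.path("images", paste0(base, ".png"))
        mask_path <- file.path("masks", paste0(base, ".png"))
        write_gray_png(v$im, file.path(out_dir, img_path))
        write_mask_png(v$mk, file.path(out_dir, mask_path))
        rows[[length(rows) + 1L]] <-
          data.frame(subject = s, frame = idx[k], split = this_split,
                     flipped = v$tag == "_flip",
                     image = img_path, mask = mask_path)
      }
    }
  }
  manifest <- do.call(rbind, rows)
  jsonlite::write_json(
    list(seed = cfg$seed, config_hash = config_hash(cfg),
         n_subjects = n_subjects, sampling_stride = sampling_stride,
         flip = flip, enhance = enhance,
         split = as.list(table(subject_split)),
         entries = manifest),
    file.path(out_dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Temperature window of a phantom configuration
#' @param cfg a [phantom_config()].
#' @return The [window_spec()] the phantom pipeline uses for grayscale
#'   conversion.
#' @export
phantom_window <- function(cfg) {
  window_spec(center_c = cfg$window_center_c, width_c = cfg$window_width_c)
}

#' Load a dataset written by [build_dataset()]
#'
#' Reads the manifest and the image/mask pairs of one split, optionally
#' resizing to a square network input size (bilinear for images, threshold
#' 0.5 for masks).
#'
#' @param dir dataset directory.
#' @param split one of `"train"`, `"val"`, `"test"`.
#' @param size optional square output size.
#' @return List with `images` and `masks` (lists of matrices) and
#'   `manifest` rows used.
#' @export
load_dataset <- function(dir, split = "train", size = NULL) {
  man <- jsonlite::fromJSON(file.path(dir, "manifest.json"))$entries
  man <- man[man$split == split, , drop = FALSE]
  images <- lapply(man$image, function(p) read_gray_png(file.path(dir, p)))
  masks <- lapply(man$mask, function(p) read_mask_png(file.path(dir, p)))
  if (!is.null(size)) {
    images <- lapply(images, resize_matrix, size, size)
    masks <- lapply(masks, function(m)
      resize_matrix(m * 1.0, size, size) > 0.5)
  }
  list(images = images, masks = masks, manifest = man)
}

#' Bilinear matrix resize
#' @param m numeric matrix.
#' @param out_h,out_w output size.
#' @return Resized matrix.
#' @export
resize_matrix <- function(m, out_h, out_w) {
  matrix(cpp_resize_bilinear(as.numeric(m), nrow(m), ncol(m), 1L, 1L,
                             as.integer(out_h), as.integer(out_w)),
         out_h, out_w)
}
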