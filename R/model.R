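# PFSNet: input stem, residual U-blocks (RSU-L and the dilated RSU-4F),
# UNet++-style nested dense skip nodes, CBAM attention at the fusion
# junctions, and multi-side-output fusion (MSOF).

he_init <- function(kh, kw, cin, cout) {
  array(stats::rnorm(kh * kw * cin * cout, sd = sqrt(2 / (kh * kw * cin))),
        dim = c(kh, kw, cin, cout))
}

new_module <- function() {
  net <- new.env(parent = emptyenv())
  net$params <- list()
  net$states <- list()
  net$training <- FALSE
  net
}

new_param_in <- function(net, name, value) {
  p <- ag_param(value)
  net$params[[name]] <- p
  p
}

new_bn_state <- function(net, name, C) {
  st <- new.env(parent = emptyenv())
  st$running_mean <- rep(0, C)
  st$running_var <- rep(1, C)
  net$states[[name]] <- st
  st
}

# conv(3x3, dilated) + batch norm + ReLU, the basic unit inside RSU blocks.
layer_rebnconv <- function(net, name, cin, cout, dilation = 1L) {
  W <- new_param_in(net, paste0(name, ".W"), he_init(3L, 3L, cin, cout))
  b <- new_param_in(net, paste0(name, ".b"), rep(0, cout))
  gm <- new_param_in(net, paste0(name, ".bn.g"), rep(1, cout))
  bt <- new_param_in(net, paste0(name, ".bn.b"), rep(0, cout))
  st <- new_bn_state(net, paste0(name, ".bn"), cout)
  function(x) {
    op_relu(op_batchnorm(op_conv2d(x, W, b, dilation = dilation),
                         gm, bt, st, net$training))
  }
}

#' Residual U-block specification
#'
#' Describes one RSU-L block: a local 3x3 transform (`F1`) whose output is
#' refined by an internal L-level U-shaped sub-network `U`, fused residually
#' as `F1(x) + U(F1(x))`. The dilated variant (`dilated = TRUE`, "RSU-4F")
#' replaces internal down/up-sampling with growing dilation rates so all
#' intermediate maps keep the input resolution.
#'
#' @param L encoder depth of the block (integer >= 2).
#' @param c_in,m,c_out input, internal and output channel counts.
#' @param dilated use the dilated full-resolution variant.
#' @return An object of class `rsu_spec`.
#' @export
rsu_spec <- function(L, c_in, m, c_out, dilated = FALSE) {
  stopifnot(L >= 2, c_in >= 1, m >= 1, c_out >= 1)
  structure(list(L = as.integer(L), c_in = as.integer(c_in),
                 m = as.integer(m), c_out = as.integer(c_out),
                 dilated = isTRUE(dilated)),
            class = "rsu_spec")
}

# Build an RSU block's layers under `name` and return its forward closure.
layer_rsu <- function(net, name, spec) {
  L <- spec$L; m <- spec$m
  conv_in <- layer_rebnconv(net, paste0(name, ".in"), spec$c_in, spec$c_out)
  if (spec$dilated) {
    enc <- vector("list", L)
    enc[[1L]] <- layer_rebnconv(net, paste0(name, ".u.enc1"), spec$c_out, m)
    for (k in 2:L)
      enc[[k]] <- layer_rebnconv(net, paste0(name, ".u.enc", k), m, m,
                                 dilation = 2L^(k - 1L))
    dec <- vector("list", L - 1L)
    for (k in seq_len(L - 1L))
      dec[[k]] <- layer_rebnconv(net, paste0(name, ".u.dec", k), 2L * m,
                                 if (k == 1L) spec$c_out else m,
                                 dilation = 2L^(k - 1L))
    forward <- function(x) {
      xin <- conv_in(x)
      e <- vector("list", L)
      e[[1L]] <- enc[[1L]](xin)
      for (k in 2:L) e[[k]] <- enc[[k]](e[[k - 1L]])
      d <- e[[L]]
      for (k in (L - 1L):1L) d <- dec[[k]](op_concat(list(d, e[[k]])))
      op_add(d, xin)
    }
  } else {
    enc <- vector("list", L - 1L)
    enc[[1L]] <- layer_rebnconv(net, paste0(name, ".u.enc1"), spec$c_out, m)
    if (L >= 3L)
      for (k in 2:(L - 1L))
        enc[[k]] <- layer_rebnconv(net, paste0(name, ".u.enc", k), m, m)
    bottom <- layer_rebnconv(net, paste0(name, ".u.bottom"), m, m,
                             dilation = 2L)
    dec <- vector("list", L - 1L)
    for (k in seq_len(L - 1L))
      dec[[k]] <- layer_rebnconv(net, paste0(name, ".u.dec", k), 2L * m,
                                 if (k == 1L) spec$c_out else m)
    forward <- function(x) {
      d <- fm_dim(x)
      if (min(d[1L], d[2L]) < 2L^(L - 2L))
        stop(sprintf("RSU-%d needs spatial size >= %d, got %dx%d",
                     L, 2L^(L - 2L), d[1L], d[2L]))
      xin <- conv_in(x)
      e <- vector("list", L - 1L)
      sizes <- vector("list", L - 1L)
      e[[1L]] <- enc[[1L]](xin)
      sizes[[1L]] <- fm_dim(e[[1L]])[1:2]
      if (L >= 3L) {
        for (k in 2:(L - 1L)) {
          e[[k]] <- enc[[k]](op_maxpool(e[[k - 1L]]))
          sizes[[k]] <- fm_dim(e[[k]])[1:2]
        }
      }
      d_ <- bottom(e[[L - 1L]])
      for (k in (L - 1L):1L) {
        d_ <- dec[[k]](op_concat(list(d_, e[[k]])))
        if (k > 1L) d_ <- op_resize(d_, sizes[[k - 1L]][1L], sizes[[k - 1L]][2L])
      }
      op_add(d_, xin)
    }
  }
  forward
}

#' Create a standalone residual U-block
#'
#' Instantiates one RSU block with freshly initialized weights. Mainly a
#' testing and inspection surface; inside PFSNet the blocks are built by
#' [new_pfsnet()].
#'
#' @param spec an [rsu_spec()].
#' @param seed integer seed for weight initialization.
#' @return A module environment with elements `forward` (maps an
#'   `(H, W, c_in, N)` array to an `(H, W, c_out, N)` array) and `params`.
#' @export
new_rsu <- function(spec, seed = 1L) {
  net <- new_module()
  set.seed(seed)
  fwd <- layer_rsu(net, "rsu", spec)
  net$forward <- function(x) ag_value(fwd(ag_const(x)))
  net
}

#' Zero the internal U-path of a standalone RSU block
#'
#' Sets every parameter of the block except its local `F1` input transform
#' to zero, so that the block's output must equal `F1(x)` exactly (the
#' residual contract).
#' @param rsu a module from [new_rsu()].
#' @export
rsu_zero_upath <- function(rsu) {
  for (nm in names(rsu$params))
    if (grepl("\\.u\\.", nm)) rsu$params[[nm]]$value[] <- 0
  invisible(rsu)
}

# Convolutional block attention: channel gate (shared MLP over global avg and
# max descriptors) followed by a spatial gate (7x7 conv over channelwise
# avg/max maps), both applied multiplicatively.
layer_cbam <- function(net, name, C, reduction = 16L) {
  r <- max(1L, C %/% reduction)
  W1 <- new_param_in(net, paste0(name, ".mlp.W1"),
                     matrix(stats::rnorm(r * C, sd = sqrt(2 / C)), r, C))
  b1 <- new_param_in(net, paste0(name, ".mlp.b1"), rep(0, r))
  W2 <- new_param_in(net, paste0(name, ".mlp.W2"),
                     matrix(stats::rnorm(C * r, sd = sqrt(2 / r)), C, r))
  b2 <- new_param_in(net, paste0(name, ".mlp.b2"), rep(0, C))
  Ws <- new_param_in(net, paste0(name, ".sp.W"), he_init(7L, 7L, 2L, 1L))
  bs <- new_param_in(net, paste0(name, ".sp.b"), 0)
  function(x) {
    mlp <- function(v) op_dense(op_relu(op_dense(v, W1, b1)), W2, b2)
    gate_c <- op_sigmoid(op_add(mlp(op_global_pool(x, "avg")),
                                mlp(op_global_pool(x, "max"))))
    x <- op_scale_channels(x, gate_c)
    stat <- op_concat(list(op_channel_stat(x, "avg"),
                           op_channel_stat(x, "max")))
    gate_s <- op_sigmoid(op_conv2d(stat, Ws, bs))
    op_scale_spatial(x, gate_s)
  }
}

#' Create a standalone CBAM module
#'
#' @param channels number of input channels.
#' @param reduction channel-gate bottleneck reduction ratio.
#' @param seed integer seed for weight initialization.
#' @return A module environment with `forward` and `params`.
#' @export
new_cbam <- function(channels, reduction = 16L, seed = 1L) {
  net <- new_module()
  set.seed(seed)
  fwd <- layer_cbam(net, "cbam", as.integer(channels), as.integer(reduction))
  net$forward <- function(x) ag_value(fwd(ag_const(x)))
  net
}

#' PFSNet architecture configuration
#'
#' Fully determines the network: encoder stages RSU7/RSU6/RSU5/RSU4/RSU4F
#' with the published residual-U channel plan (scaled by `width_mult`), the
#' nested dense skip grid, CBAM reduction ratio and input size. Per-row RSU
#' depths are clamped so that the innermost pooled map of each block stays
#' at least one pixel; at the nominal 512x512 input no clamping occurs.
#'
#' @param input_size input image side length in pixels (square input).
#' @param width_mult channel width multiplier (1 = full width; use e.g. 1/8
#'   for desk-scale experiments).
#' @param cbam_reduction CBAM channel-gate reduction ratio.
#' @return An object of class `pfs_config`.
#' @export
pfs_config <- function(input_size = 512L, width_mult = 1,
                       cbam_reduction = 16L) {
  input_size <- as.integer(input_size)
  # the stem reduces 4x and the encoder pools 4 more times; 64 is the
  # smallest input whose deepest row keeps at least one pixel
  stopifnot(input_size >= 64L, width_mult > 0)
  ch <- function(x) pmax(1L, as.integer(round(x * width_mult)))
  out_ch <- ch(c(64, 128, 256, 512, 512))
  mid_ch <- ch(c(32, 32, 64, 128, 256))
  stem_ch <- ch(64)
  # row i sits at input_size / 4 / 2^i
  row_res <- (input_size %/% 4L) %/% 2L^(0:4)
  L_default <- c(7L, 6L, 5L, 4L)
  L_row <- pmax(2L, pmin(L_default, as.integer(floor(log2(row_res[1:4]))) + 2L))
  structure(list(input_size = input_size, width_mult = width_mult,
                 stem_ch = stem_ch, out_ch = out_ch, mid_ch = mid_ch,
                 L_row = L_row, row_res = row_res,
                 cbam_reduction = as.integer(cbam_reduction),
                 n_side = 10L),
            class = "pfs_config")
}

config_hash <- function(cfg) {
  s <- jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA)
  # FNV-1a over the canonical JSON text
  h <- 2166136261
  for (b in utf8ToInt(s)) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

#' Build a PFSNet
#'
#' Constructs the full network: a GoogLeNet-style input stem (7x7 stride-2
#' convolution, batch norm, 3x3 stride-2 max pool, together reducing the
#' input 4x), the five-stage residual-U encoder, the nested dense skip grid
#' with CBAM at every fusion junction, side-output heads and the
#' multi-side-output fusion layers.
#'
#' @param config a [pfs_config()].
#' @param seed integer seed for weight initialization.
#' @return A module environment; use [pfs_forward()] to run it.
#' @export
new_pfsnet <- function(config = pfs_config(), seed = 1L) {
  stopifnot(inherits(config, "pfs_config"))
  net <- new_module()
  net$config <- config
  net$seed <- as.integer(seed)
  set.seed(seed)
  oc <- config$out_ch; mc <- config$mid_ch; Lr <- config$L_row

  stem_W <- new_param_in(net, "stem.W", he_init(7L, 7L, 1L, config$stem_ch))
  stem_b <- new_param_in(net, "stem.b", rep(0, config$stem_ch))
  stem_g <- new_param_in(net, "stem.bn.g", rep(1, config$stem_ch))
  stem_bt <- new_param_in(net, "stem.bn.b", rep(0, config$stem_ch))
  stem_st <- new_bn_state(net, "stem.bn", config$stem_ch)
  net$stem <- function(x) {
    h <- op_conv2d(x, stem_W, stem_b, stride = 2L, pad = 3L)
    h <- op_relu(op_batchnorm(h, stem_g, stem_bt, stem_st, net$training))
    op_maxpool(h, k = 3L, stride = 2L, pad = 1L, ceil_mode = FALSE)
  }

  # encoder column j = 0
  enc_specs <- list(
    rsu_spec(Lr[1L], config$stem_ch, mc[1L], oc[1L]),
    rsu_spec(Lr[2L], oc[1L], mc[2L], oc[2L]),
    rsu_spec(Lr[3L], oc[2L], mc[3L], oc[3L]),
    rsu_spec(Lr[4L], oc[3L], mc[4L], oc[4L]),
    rsu_spec(4L, oc[4L], mc[5L], oc[5L], dilated = TRUE))
  net$encoder <- lapply(1:5, function(i)
    layer_rsu(net, sprintf("enc%d", i - 1L), enc_specs[[i]]))

  # nested grid nodes (i, j), i = 0..3, j = 1..(4 - i); CBAM on the
  # concatenated inputs, then an RSU at the row's depth
  net$nested <- list()
  for (i in 0:3) {
    for (j in 1:(4L - i)) {
      cin <- j * oc[i + 1L] + oc[i + 2L]
      key <- sprintf("x%d%d", i, j)
      cb <- layer_cbam(net, paste0(key, ".cbam"), cin, config$cbam_reduction)
      rs <- layer_rsu(net, paste0(key, ".rsu"),
                      rsu_spec(Lr[i + 1L], cin, mc[i + 1L], oc[i + 1L]))
      net$nested[[key]] <- local({
        cb_ <- cb; rs_ <- rs
        function(inputs) rs_(cb_(op_concat(inputs)))
      })
    }
  }

  # side-output heads: 3x3 conv to one channel (logits)
  head_nodes <- c(sprintf("x%d0", 0:4), sprintf("x0%d", 1:4))
  net$heads <- list()
  for (key in head_nodes) {
    # x00..x40 carry their row's channels; x01..x04 all carry row-0 channels
    cch <- if (substr(key, 3L, 3L) == "0")
      oc[as.integer(substr(key, 2L, 2L)) + 1L] else oc[1L]
    W <- new_param_in(net, paste0("head.", key, ".W"), he_init(3L, 3L, cch, 1L))
    b <- new_param_in(net, paste0("head.", key, ".b"), 0)
    net$heads[[key]] <- local({
      W_ <- W; b_ <- b
      function(x) op_conv2d(x, W_, b_)
    })
  }

  # MSOF fusion: concatenation (+ 1x1 conv) of side logits, initialized to
  # plain averaging so an untrained fusion is the mean of its inputs
  fuse_conv <- function(name, k) {
    W <- new_param_in(net, paste0("fuse.", name, ".W"),
                      array(1 / k, dim = c(1L, 1L, k, 1L)))
    b <- new_param_in(net, paste0("fuse.", name, ".b"), 0)
    local({
      W_ <- W; b_ <- b
      function(xs) op_conv2d(op_concat(xs), W_, b_)
    })
  }
  net$fuse05 <- fuse_conv("y05", 4L)
  net$fuse50 <- fuse_conv("y50", 5L)
  net$fuse55 <- fuse_conv("y55", 2L)
  net$hash <- config_hash(config)
  net
}

# Full forward pass returning ag nodes for the 11 sigmoid maps.
pfs_forward_nodes <- function(net, x) {
  cfg <- net$config
  d <- fm_dim(x)
  if (d[1L] != cfg$input_size || d[2L] != cfg$input_size || d[3L] != 1L)
    stop(sprintf("input must be %dx%dx1, got %dx%dx%d",
                 cfg$input_size, cfg$input_size, d[1L], d[2L], d[3L]))
  in_h <- d[1L]; in_w <- d[2L]

  stem_out <- net$stem(x)
  X <- list()
  X[["x00"]] <- net$encoder[[1L]](stem_out)
  for (i in 1:4)
    X[[sprintf("x%d0", i)]] <-
      net$encoder[[i + 1L]](op_maxpool(X[[sprintf("x%d0", i - 1L)]]))

  for (j in 1:4) {
    for (i in 0:(4L - j)) {
      same_row <- lapply(0:(j - 1L), function(k) X[[sprintf("x%d%d", i, k)]])
      below <- X[[sprintf("x%d%d", i + 1L, j - 1L)]]
      tgt <- fm_dim(same_row[[1L]])
      below_up <- op_resize(below, tgt[1L], tgt[2L])
      X[[sprintf("x%d%d", i, j)]] <-
        net$nested[[sprintf("x%d%d", i, j)]](c(same_row, list(below_up)))
    }
  }

  logit <- function(key)
    op_resize(net$heads[[key]](X[[key]]), in_h, in_w)
  l_col <- lapply(sprintf("x%d0", 0:4), logit)        # encoder column
  l_row <- lapply(sprintf("x0%d", 1:4), logit)        # top decoder row
  f05 <- net$fuse05(l_row)
  f50 <- net$fuse50(l_col)
  f55 <- net$fuse55(list(f50, f05))

  logits <- c(
    stats::setNames(l_row, sprintf("y0%d", 1:4)),
    list(y05 = f05),
    stats::setNames(l_col[2:5], sprintf("y%d0", 1:4)),
    list(y50 = f50, y55 = f55))
  list(maps = lapply(logits, op_sigmoid), logits = logits)
}

#' Run a forward pass of PFSNet
#'
#' @param net a network from [new_pfsnet()].
#' @param images numeric array `(H, W, 1, N)`, a single `H x W` matrix, or a
#'   list of matrices, with values in `[0, 1]`.
#' @return An object of class `side_outputs`: a list with `maps` (the 11
#'   named sigmoid saliency maps `y01..y04, y05, y10..y40, y50, y55`, each an
#'   `(H, W, N)` array) and `fused` (the final `y55` map).
#' @export
pfs_forward <- function(net, images) {
  x <- as_input_array(images, net$config$input_size)
  nodes <- pfs_forward_nodes(net, ag_const(x))
  maps <- lapply(nodes$maps, function(n) {
    v <- ag_value(n)
    array(v, dim = dim(v)[c(1L, 2L, 4L)])
  })
  structure(list(maps = maps, fused = maps$y55), class = "side_outputs")
}

as_input_array <- function(images, size) {
  if (is.list(images)) {
    n <- length(images)
    x <- array(0, c(size, size, 1L, n))
    for (i in seq_len(n)) {
      im <- images[[i]]
      stopifnot(is.matrix(im), nrow(im) == size, ncol(im) == size)
      x[, , 1L, i] <- im
    }
    x
  } else if (is.matrix(images)) {
    array(images, c(nrow(images), ncol(images), 1L, 1L))
  } else {
    stopifnot(length(dim(images)) == 4L)
    images
  }
}

#' Number of trainable parameters
#' @param net a module environment.
#' @return Integer parameter count.
#' @export
param_count <- function(net) {
  sum(vapply(net$params, function(p) length(p$value), numeric(1)))
}

#' Save / load a PFSNet checkpoint
#'
#' The checkpoint stores the architecture configuration, an architecture
#' hash, all parameter values and the batch-norm running statistics.
#' Loading refuses a checkpoint whose architecture hash does not match the
#' network rebuilt from its own stored configuration.
#'
#' @param net a network from [new_pfsnet()].
#' @param path file path.
#' @return `load_checkpoint()` returns the restored network.
#' @export
save_checkpoint <- function(net, path) {
  obj <- list(
    format = "pfseg-checkpoint-1",
    config = unclass(net$config),
    hash = net$hash,
    seed = net$seed,
    params = lapply(net$params, function(p) p$value),
    states = lapply(net$states, function(s)
      list(mean = s$running_mean, var = s$running_var)))
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  stopifnot(identical(obj$format, "pfseg-checkpoint-1"))
  cfg <- structure(obj$config, class = "pfs_config")
  if (!identical(config_hash(cfg), obj$hash))
    stop("checkpoint architecture hash mismatch; refusing to load")
  net <- new_pfsnet(cfg, seed = obj$seed)
  stopifnot(identical(sort(names(net$params)), sort(names(obj$params))))
  for (nm in names(obj$params)) net$params[[nm]]$value <- obj$params[[nm]]
  for (nm in names(obj$states)) {
    net$states[[nm]]$running_mean <- obj$states[[nm]]$mean
    net$states[[nm]]$running_var <- obj$states[[nm]]$var
  }
  net
}
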