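# Differentiable operations on (H, W, C, N) feature maps.

fm_dim <- function(x) {
  d <- dim(ag_value(x))
  stopifnot(length(d) == 4L)
  d
}

# 2-D convolution via im2col + BLAS matrix multiply.
# W: array (kh, kw, c_in, c_out); b: numeric length c_out or NULL.
# pad defaults to "same" padding for stride 1 and odd kernels.
op_conv2d <- function(x, W, b = NULL, stride = 1L, dilation = 1L, pad = NULL) {
  d <- fm_dim(x)
  wd <- dim(ag_value(W))
  stopifnot(wd[3L] == d[3L])
  kh <- wd[1L]; kw <- wd[2L]; cout <- wd[4L]
  if (is.null(pad)) pad <- dilation * (kh - 1L) %/% 2L
  col <- cpp_im2col(as.numeric(ag_value(x)), d[1L], d[2L], d[3L], d[4L],
                    kh, kw, as.integer(stride), as.integer(pad),
                    as.integer(dilation))
  Wm <- matrix(ag_value(W), nrow = kh * kw * d[3L], ncol = cout)
  out <- crossprod(Wm, col)                       # cout x (Ho*Wo*N)
  eff_h <- dilation * (kh - 1L) + 1L
  eff_w <- dilation * (kw - 1L) + 1L
  Ho <- (d[1L] + 2L * pad - eff_h) %/% stride + 1L
  Wo <- (d[2L] + 2L * pad - eff_w) %/% stride + 1L
  if (!is.null(b)) out <- out + ag_value(b)
  val <- aperm(array(out, c(cout, Ho, Wo, d[4L])), c(2L, 3L, 1L, 4L))
  parents <- list(x, W)
  if (!is.null(b)) parents <- c(parents, list(b))
  ag_node(val, parents = parents, backward = function(g) {
    gm <- matrix(aperm(g, c(3L, 1L, 2L, 4L)), nrow = cout)  # cout x (Ho*Wo*N)
    dW <- array(col %*% t(gm), dim = wd)
    dxm <- Wm %*% gm
    dx <- array(cpp_col2im(dxm, d[1L], d[2L], d[3L], d[4L],
                           kh, kw, as.integer(stride), as.integer(pad),
                           as.integer(dilation)), dim = d)
    out <- list(dx, dW)
    if (!is.null(b)) out <- c(out, list(rowSums(gm)))
    out
  })
}

# Batch normalization over (H, W, N) per channel. `state` is an environment
# holding running_mean / running_var (updated by side effect in training
# mode); gamma/beta are per-channel affine parameters.
op_batchnorm <- function(x, gamma, beta, state, training, eps = 1e-5,
                         momentum = 0.9) {
  d <- fm_dim(x)
  C <- d[3L]; m <- d[1L] * d[2L] * d[4L]
  xv <- ag_value(x)
  xm <- matrix(aperm(xv, c(1L, 2L, 4L, 3L)), ncol = C)   # m x C
  if (training) {
    mu <- colMeans(xm)
    va <- colMeans(xm^2) - mu^2
    va <- pmax(va, 0)
    state$running_mean <- momentum * state$running_mean + (1 - momentum) * mu
    state$running_var <- momentum * state$running_var + (1 - momentum) * va
  } else {
    mu <- state$running_mean
    va <- state$running_var
  }
  inv_sd <- 1 / sqrt(va + eps)
  xhat <- sweep(sweep(xm, 2L, mu, "-"), 2L, inv_sd, "*")
  g <- ag_value(gamma); bta <- ag_value(beta)
  outm <- sweep(sweep(xhat, 2L, g, "*"), 2L, bta, "+")
  val <- aperm(array(outm, c(d[1L], d[2L], d[4L], C)), c(1L, 2L, 4L, 3L))
  ag_node(val, parents = list(x, gamma, beta), backward = function(go) {
    gm <- matrix(aperm(go, c(1L, 2L, 4L, 3L)), ncol = C)
    dgamma <- colSums(gm * xhat)
    dbeta <- colSums(gm)
    if (training) {
      mean_g <- colMeans(gm)
      mean_gx <- colMeans(gm * xhat)
      dxm <- sweep(gm, 2L, mean_g, "-") -
        sweep(xhat, 2L, mean_gx, "*")
      dxm <- sweep(dxm, 2L, g * inv_sd, "*")
    } else {
      dxm <- sweep(gm, 2L, g * inv_sd, "*")
    }
    dx <- aperm(array(dxm, c(d[1L], d[2L], d[4L], C)), c(1L, 2L, 4L, 3L))
    list(dx, dgamma, dbeta)
  })
}

op_relu <- function(x) {
  v <- ag_value(x)
  mask <- v > 0
  ag_node(v * mask, parents = list(x),
          backward = function(g) list(g * mask))
}

op_sigmoid <- function(x) {
  s <- 1 / (1 + exp(-ag_value(x)))
  ag_node(s, parents = list(x),
          backward = function(g) list(g * s * (1 - s)))
}

op_maxpool <- function(x, k = 2L, stride = 2L, pad = 0L, ceil_mode = TRUE) {
  d <- fm_dim(x)
  res <- cpp_maxpool(as.numeric(ag_value(x)), d[1L], d[2L], d[3L], d[4L],
                     as.integer(k), as.integer(stride), as.integer(pad),
                     isTRUE(ceil_mode))
  od <- attr(res$value, "outdim")
  val <- array(res$value, dim = od)
  idx <- res$idx
  ag_node(val, parents = list(x), backward = function(g) {
    list(array(cpp_maxpool_bwd(as.numeric(g), idx, prod(d)), dim = d))
  })
}

op_resize <- function(x, out_h, out_w) {
  d <- fm_dim(x)
  if (d[1L] == out_h && d[2L] == out_w) return(x)
  val <- array(cpp_resize_bilinear(as.numeric(ag_value(x)),
                                   d[1L], d[2L], d[3L], d[4L],
                                   as.integer(out_h), as.integer(out_w)),
               dim = c(out_h, out_w, d[3L], d[4L]))
  ag_node(val, parents = list(x), backward = function(g) {
    list(array(cpp_resize_bilinear_bwd(as.numeric(g),
                                       d[1L], d[2L], d[3L], d[4L],
                                       as.integer(out_h), as.integer(out_w)),
               dim = d))
  })
}

op_concat <- function(xs) {
  ds <- lapply(xs, fm_dim)
  d1 <- ds[[1L]]
  chans <- vapply(ds, `[`, integer(1L), 3L)
  for (d in ds)
    if (d[1L] != d1[1L] || d[2L] != d1[2L] || d[4L] != d1[4L])
      stop("op_concat: spatial/batch shape mismatch")
  HW <- d1[1L] * d1[2L]
  parts <- lapply(xs, function(x) {
    v <- ag_value(x)
    dim(v) <- c(HW, dim(v)[3L], d1[4L])
    v
  })
  Ctot <- sum(chans)
  val <- array(0, c(HW, Ctot, d1[4L]))
  at <- 0L
  for (i in seq_along(parts)) {
    val[, at + seq_len(chans[i]), ] <- parts[[i]]
    at <- at + chans[i]
  }
  dim(val) <- c(d1[1L], d1[2L], Ctot, d1[4L])
  ag_node(val, parents = xs, backward = function(g) {
    dim(g) <- c(HW, Ctot, d1[4L])
    out <- vector("list", length(xs))
    at <- 0L
    for (i in seq_along(xs)) {
      gi <- g[, at + seq_len(chans[i]), , drop = FALSE]
      dim(gi) <- ds[[i]]
      out[[i]] <- gi
      at <- at + chans[i]
    }
    out
  })
}

op_add <- function(a, b) {
  ag_node(ag_value(a) + ag_value(b), parents = list(a, b),
          backward = function(g) list(g, g))
}

# Multiply by a per-channel gate s with dim (1, 1, C, N).
op_scale_channels <- function(x, s) {
  d <- fm_dim(x)
  HW <- d[1L] * d[2L]
  sv <- ag_value(s)
  sx <- rep(as.numeric(sv), each = HW)
  xv <- ag_value(x)
  ag_node(array(as.numeric(xv) * sx, dim = d), parents = list(x, s),
          backward = function(g) {
            dx <- array(as.numeric(g) * sx, dim = d)
            dsm <- colSums(matrix(as.numeric(g) * as.numeric(xv), nrow = HW))
            list(dx, array(dsm, dim = c(1L, 1L, d[3L], d[4L])))
          })
}

# Multiply by a spatial gate s with dim (H, W, 1, N).
op_scale_spatial <- function(x, s) {
  d <- fm_dim(x)
  sv <- ag_value(s)
  sfull <- aperm(array(as.numeric(sv), c(d[1L], d[2L], d[4L], d[3L])),
                 c(1L, 2L, 4L, 3L))
  xv <- ag_value(x)
  ag_node(xv * sfull, parents = list(x, s), backward = function(g) {
    dx <- g * sfull
    prod_ <- aperm(g * xv, c(1L, 2L, 4L, 3L))         # H,W,N,C
    dim(prod_) <- c(d[1L] * d[2L] * d[4L], d[3L])
    ds <- array(rowSums(prod_), dim = c(d[1L], d[2L], 1L, d[4L]))
    list(dx, ds)
  })
}

# Global pooling over (H, W) -> (1, 1, C, N).
op_global_pool <- function(x, type = c("avg", "max")) {
  type <- match.arg(type)
  d <- fm_dim(x)
  HW <- d[1L] * d[2L]
  xm <- matrix(ag_value(x), nrow = HW)                 # HW x (C*N)
  if (type == "avg") {
    val <- array(colMeans(xm), dim = c(1L, 1L, d[3L], d[4L]))
    ag_node(val, parents = list(x), backward = function(g) {
      gv <- rep(as.numeric(g) / HW, each = HW)
      list(array(gv, dim = d))
    })
  } else {
    which_max <- max.col(t(xm), ties.method = "first")
    val <- array(xm[cbind(which_max, seq_len(ncol(xm)))],
                 dim = c(1L, 1L, d[3L], d[4L]))
    ag_node(val, parents = list(x), backward = function(g) {
      dxm <- matrix(0, nrow = HW, ncol = ncol(xm))
      dxm[cbind(which_max, seq_len(ncol(xm)))] <- as.numeric(g)
      list(array(dxm, dim = d))
    })
  }
}

# Per-pixel statistic across channels -> (H, W, 1, N).
op_channel_stat <- function(x, type = c("avg", "max")) {
  type <- match.arg(type)
  d <- fm_dim(x)
  xp <- aperm(ag_value(x), c(1L, 2L, 4L, 3L))          # H,W,N,C
  xm <- matrix(xp, ncol = d[3L])                       # (H*W*N) x C
  if (type == "avg") {
    val <- array(rowMeans(xm), dim = c(d[1L], d[2L], 1L, d[4L]))
    ag_node(val, parents = list(x), backward = function(g) {
      gm <- matrix(as.numeric(g) / d[3L], nrow = nrow(xm), ncol = d[3L])
      dim(gm) <- c(d[1L], d[2L], d[4L], d[3L])
      list(aperm(gm, c(1L, 2L, 4L, 3L)))
    })
  } else {
    which_max <- max.col(xm, ties.method = "first")
    val <- array(xm[cbind(seq_len(nrow(xm)), which_max)],
                 dim = c(d[1L], d[2L], 1L, d[4L]))
    ag_node(val, parents = list(x), backward = function(g) {
      gm <- matrix(0, nrow = nrow(xm), ncol = d[3L])
      gm[cbind(seq_len(nrow(xm)), which_max)] <- as.numeric(g)
      dim(gm) <- c(d[1L], d[2L], d[4L], d[3L])
      list(aperm(gm, c(1L, 2L, 4L, 3L)))
    })
  }
}

# Fully connected layer acting on the channel dim of a (1, 1, C, N) node.
# W: (c_out x c_in) matrix; b: length c_out or NULL.
op_dense <- function(x, W, b = NULL) {
  d <- fm_dim(x)
  stopifnot(d[1L] == 1L, d[2L] == 1L)
  xm <- matrix(ag_value(x), nrow = d[3L])              # C x N
  Wv <- ag_value(W)
  out <- Wv %*% xm
  if (!is.null(b)) out <- out + ag_value(b)
  parents <- list(x, W)
  if (!is.null(b)) parents <- c(parents, list(b))
  ag_node(array(out, dim = c(1L, 1L, nrow(Wv), d[4L])),
          parents = parents, backward = function(g) {
            gm <- matrix(g, nrow = nrow(Wv))
            res <- list(array(crossprod(Wv, gm), dim = d), gm %*% t(xm))
            if (!is.null(b)) res <- c(res, list(rowSums(gm)))
            res
          })
}

op_scalar_mul <- function(x, k) {
  ag_node(ag_value(x) * k, parents = list(x),
          backward = function(g) list(g * k))
}

# Summed binary cross-entropy on logits (fused with the sigmoid for
# numerical stability): e = sum[max(z,0) - z*t + log(1 + exp(-|z|))],
# d e / d z = sigmoid(z) - t.
op_bce_logits_sum <- function(logits, target) {
  z <- ag_value(logits)
  t_ <- ag_value(target)
  val <- sum(pmax(z, 0) - z * t_ + log1p(exp(-abs(z))))
  ag_node(val, parents = list(logits), backward = function(g) {
    list(g * (1 / (1 + exp(-z)) - t_))
  })
}

# Summed binary cross-entropy between predicted probabilities and a binary
# target, with hard epsilon clipping (zero gradient in the clipped region).
op_bce_sum <- function(pred, target, eps = 1e-7) {
  p <- ag_value(pred)
  t_ <- ag_value(target)
  pc <- pmin(pmax(p, eps), 1 - eps)
  inside <- (p > eps) & (p < 1 - eps)
  val <- -sum(t_ * log(pc) + (1 - t_) * log(1 - pc))
  ag_node(val, parents = list(pred), backward = function(g) {
    dp <- ifelse(inside, (pc - t_) / (pc * (1 - pc)), 0)
    list(g * dp)
  })
}
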