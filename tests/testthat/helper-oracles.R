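# Independent oracles used across the suite. Each is deliberately written
# on a different route than the implementation it checks (scalar loops,
# sorting, exhaustive enumeration).

# Rank-based quantile: smallest pixel value whose empirical CDF reaches q.
oracle_quantile <- function(values, q) {
  s <- sort(as.numeric(values))
  n <- length(s)
  s[which((seq_len(n) / n) >= q)[1L]]
}

# Empirical CDF at threshold t by direct counting.
oracle_cdf_at <- function(values, t) mean(as.numeric(values) <= t)

# Scalar-loop binary cross-entropy.
oracle_bce <- function(p, g, eps = 1e-7) {
  p <- as.numeric(p); g <- as.numeric(g)
  total <- 0
  for (i in seq_along(p)) {
    pi_ <- min(max(p[i], eps), 1 - eps)
    total <- total - (g[i] * log(pi_) + (1 - g[i]) * log(1 - pi_))
  }
  total
}

# Exhaustive all-pairs directed Hausdorff distance on boundary sets.
oracle_hd <- function(a, b) {
  boundary_pts <- function(m) {
    pts <- list()
    for (r in seq_len(nrow(m))) for (c in seq_len(ncol(m))) {
      if (!m[r, c]) next
      nb <- c(if (r > 1) m[r - 1, c] else FALSE,
              if (r < nrow(m)) m[r + 1, c] else FALSE,
              if (c > 1) m[r, c - 1] else FALSE,
              if (c < ncol(m)) m[r, c + 1] else FALSE)
      if (!all(nb)) pts[[length(pts) + 1L]] <- c(r, c)
    }
    do.call(rbind, pts)
  }
  pa <- boundary_pts(a); pb <- boundary_pts(b)
  directed <- function(from, to) {
    worst <- 0
    for (i in seq_len(nrow(from))) {
      best <- Inf
      for (j in seq_len(nrow(to))) {
        d <- sqrt(sum((from[i, ] - to[j, ])^2))
        if (d < best) best <- d
      }
      if (best > worst) worst <- best
    }
    worst
  }
  max(directed(pa, pb), directed(pb, pa))
}

# Independent F1 oracle for an RSU block in evaluation mode with fresh
# normalization statistics (running mean 0, var 1, unit affine): a
# scalar-loop same-padded 3x3 convolution, scaled by 1/sqrt(1 + eps),
# then ReLU. x: (H, W, c_in, 1) array.
oracle_rsu_f1 <- function(blk, x) {
  W <- blk$params[["rsu.in.W"]]$value
  b <- blk$params[["rsu.in.b"]]$value
  H <- dim(x)[1]; Wd <- dim(x)[2]
  cin <- dim(W)[3]; cout <- dim(W)[4]
  out <- array(0, c(H, Wd, cout, 1))
  for (co in seq_len(cout)) {
    acc <- matrix(b[co], H, Wd)
    for (ci in seq_len(cin)) for (kr in 1:3) for (kc in 1:3) {
      for (r in seq_len(H)) for (c in seq_len(Wd)) {
        rr <- r + kr - 2; cc <- c + kc - 2
        if (rr >= 1 && rr <= H && cc >= 1 && cc <= Wd)
          acc[r, c] <- acc[r, c] + W[kr, kc, ci, co] * x[rr, cc, ci, 1]
      }
    }
    out[, , co, 1] <- pmax(acc / sqrt(1 + 1e-5), 0)
  }
  out
}

# Random blob mask for property tests.
random_mask <- function(h, w, p = 0.3) {
  matrix(stats::runif(h * w) < p, h, w)
}

# Random mask guaranteed non-empty with a connected-ish blob.
random_blob_mask <- function(h, w) {
  cy <- sample(h, 1); cx <- sample(w, 1)
  ry <- stats::runif(1, 1, h / 3); rx <- stats::runif(1, 1, w / 3)
  rr <- matrix(seq_len(h), h, w)
  cc <- matrix(seq_len(w), h, w, byrow = TRUE)
  ((rr - cy) / ry)^2 + ((cc - cx) / rx)^2 <= 1
}
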