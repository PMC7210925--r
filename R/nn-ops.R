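# Differentiable image operations used by the enhancement networks.
#
# Feature maps are (H*W) x C matrices (column-major pixel order, one column
# per channel); spatial dimensions travel alongside. Convolutions are
# im2col + GEMM with cached gather indices, so the heavy lifting runs in
# BLAS and the index bookkeeping is computed once per spatial size. Every
# op returns its forward value plus the cache its backward pass needs.

.idx_cache <- new.env(parent = emptyenv())

idx_cached <- function(key, make) {
  v <- .idx_cache[[key]]
  if (is.null(v)) {
    v <- make()
    .idx_cache[[key]] <- v
  }
  v
}

# Gather indices for "same"-padded k x k convolution at spatial size H x W:
# IDX[, q] maps output pixel -> padded-plane linear index for kernel tap q
# (q = di + (dj-1)k, matching the column-major weight layout).
conv_idx <- function(H, W, k, Cin) {
  idx_cached(paste("conv", H, W, k, Cin), function() {
    p <- (k - 1L) %/% 2L
    Hp <- H + 2L * p
    i <- rep(seq_len(H), times = W)
    j <- rep(seq_len(W), each = H)
    IDX <- matrix(0L, H * W, k * k)
    q <- 0L
    for (dj in seq_len(k)) {
      for (di in seq_len(k)) {
        q <- q + 1L
        IDX[, q] <- (j + dj - 2L) * Hp + (i + di - 1L)
      }
    }
    plane <- Hp * (W + 2L * p)
    list(IDX = IDX,
         interior = (j + p - 1L) * Hp + (i + p),
         plane = plane,
         bigidx = rep(as.vector(IDX), Cin) +
           rep((seq_len(Cin) - 1L) * plane, each = length(IDX)))
  })
}

conv2d_fwd <- function(xm, H, W, Wt, b) {
  k <- dim(Wt)[1]; Cin <- dim(Wt)[3]; Cout <- dim(Wt)[4]
  if (k == 1L) {
    cols <- xm
  } else {
    ci <- conv_idx(H, W, k, Cin)
    xp <- matrix(0, ci$plane, Cin)
    xp[ci$interior, ] <- xm
    cols <- xp[ci$bigidx]
    dim(cols) <- c(H * W, k * k * Cin)
  }
  out <- cols %*% matrix(Wt, k * k * Cin, Cout)
  out <- out + rep(b, each = H * W)
  list(out = out, cache = cols)
}

conv2d_bwd <- function(gm, cols, H, W, Wt, need_gx = TRUE) {
  k <- dim(Wt)[1]; Cin <- dim(Wt)[3]; Cout <- dim(Wt)[4]
  gW <- array(crossprod(cols, gm), dim(Wt))
  gb <- colSums(gm)
  gx <- NULL
  if (need_gx) {
    gcols <- tcrossprod(gm, matrix(Wt, k * k * Cin, Cout))
    if (k == 1L) {
      gx <- gcols
    } else {
      ci <- conv_idx(H, W, k, Cin)
      gxp <- matrix(0, ci$plane, Cin)
      for (q in seq_len(k * k)) {
        idx <- ci$IDX[, q]
        gxp[idx, ] <- gxp[idx, ] + gcols[, q + (seq_len(Cin) - 1L) * k * k]
      }
      gx <- gxp[ci$interior, , drop = FALSE]
    }
  }
  list(gx = gx, gW = gW, gb = gb)
}

# -- ReLU -------------------------------------------------------------------

relu_fwd <- function(x) list(out = pmax(x, 0), cache = x > 0)
relu_bwd <- function(g, cache) g * cache

# -- 2x2 pooling (even input sizes) -----------------------------------------

pool_idx <- function(H, W) {
  idx_cached(paste("pool", H, W), function() {
    H2 <- H %/% 2L; W2 <- W %/% 2L
    i2 <- rep(seq_len(H2), times = W2)
    j2 <- rep(seq_len(W2), each = H2)
    sub <- function(rd, cd) (2L * (j2 - 1L) + cd - 1L) * H + 2L * (i2 - 1L) + rd
    list(i11 = sub(1L, 1L), i21 = sub(2L, 1L),
         i12 = sub(1L, 2L), i22 = sub(2L, 2L))
  })
}

maxpool2_fwd <- function(xm, H, W) {
  px <- pool_idx(H, W)
  x11 <- xm[px$i11, , drop = FALSE]; x21 <- xm[px$i21, , drop = FALSE]
  x12 <- xm[px$i12, , drop = FALSE]; x22 <- xm[px$i22, , drop = FALSE]
  m <- pmax(x11, x21, x12, x22)
  list(out = m, cache = list(x11 = x11, x21 = x21, x12 = x12, x22 = x22,
                             m = m, H = H, W = W))
}

maxpool2_bwd <- function(g, cache) {
  i11 <- cache$x11 == cache$m; i21 <- cache$x21 == cache$m
  i12 <- cache$x12 == cache$m; i22 <- cache$x22 == cache$m
  g <- g / (i11 + i21 + i12 + i22)   # ties share the gradient equally
  px <- pool_idx(cache$H, cache$W)
  gx <- matrix(0, cache$H * cache$W, ncol(g))
  gx[px$i11, ] <- g * i11; gx[px$i21, ] <- g * i21
  gx[px$i12, ] <- g * i12; gx[px$i22, ] <- g * i22
  gx
}

# 2x2 mean pooling (used for the injected input pyramid; no cache needed).
meanpool2 <- function(xm, H, W) {
  px <- pool_idx(H, W)
  (xm[px$i11, , drop = FALSE] + xm[px$i21, , drop = FALSE] +
     xm[px$i12, , drop = FALSE] + xm[px$i22, , drop = FALSE]) / 4
}

# -- bilinear 2x upsampling (separable linear map, cached per size) ---------

up2_matrix <- function(n) {
  idx_cached(paste("up2", n), function() {
    A <- matrix(0, 2L * n, n)
    for (i0 in 0:(2L * n - 1L)) {
      src <- (i0 + 0.5) / 2 - 0.5
      f <- floor(src); w <- src - f
      lo <- min(max(f, 0), n - 1); hi <- min(max(f + 1, 0), n - 1)
      A[i0 + 1L, lo + 1L] <- A[i0 + 1L, lo + 1L] + (1 - w)
      A[i0 + 1L, hi + 1L] <- A[i0 + 1L, hi + 1L] + w
    }
    A
  })
}

bilinear_up2_fwd <- function(xm, H, W) {
  AH <- up2_matrix(H); AW <- up2_matrix(W)
  C <- ncol(xm)
  out <- matrix(0, 4L * H * W, C)
  for (c in seq_len(C)) {
    out[, c] <- AH %*% matrix(xm[, c], H, W) %*% t(AW)
  }
  list(out = out, cache = c(H, W))
}

bilinear_up2_bwd <- function(g, cache) {
  H <- cache[1]; W <- cache[2]
  AH <- up2_matrix(H); AW <- up2_matrix(W)
  C <- ncol(g)
  gx <- matrix(0, H * W, C)
  for (c in seq_len(C)) {
    gx[, c] <- t(AH) %*% matrix(g[, c], 2L * H, 2L * W) %*% AW
  }
  gx
}

# -- 2x2 stride-2 transposed convolution ------------------------------------

tconv_idx <- function(H, W) {
  idx_cached(paste("tconv", H, W), function() {
    i <- rep(seq_len(H), times = W)
    j <- rep(seq_len(W), each = H)
    sub <- function(rd, cd) (2L * (j - 1L) + cd - 1L) * (2L * H) +
      2L * (i - 1L) + rd
    list(sub(1L, 1L), sub(2L, 1L), sub(1L, 2L), sub(2L, 2L))
  })
}

tconv2_fwd <- function(xm, H, W, Wt, b) {
  Cin <- dim(Wt)[3]; Cout <- dim(Wt)[4]
  ti <- tconv_idx(H, W)
  out <- matrix(0, 4L * H * W, Cout)
  q <- 0L
  for (dj in 1:2) {
    for (di in 1:2) {
      q <- q + 1L
      out[ti[[q]], ] <- xm %*% matrix(Wt[di, dj, , ], Cin, Cout)
    }
  }
  out <- out + rep(b, each = 4L * H * W)
  list(out = out, cache = list(xm = xm, H = H, W = W))
}

tconv2_bwd <- function(g, cache, Wt, need_gx = TRUE) {
  Cin <- dim(Wt)[3]; Cout <- dim(Wt)[4]
  ti <- tconv_idx(cache$H, cache$W)
  gW <- array(0, dim(Wt))
  gb <- numeric(Cout)
  gx <- if (need_gx) matrix(0, nrow(cache$xm), Cin) else NULL
  q <- 0L
  for (dj in 1:2) {
    for (di in 1:2) {
      q <- q + 1L
      gsub <- g[ti[[q]], , drop = FALSE]
      gW[di, dj, , ] <- crossprod(cache$xm, gsub)
      gb <- gb + colSums(gsub)
      if (need_gx) gx <- gx + tcrossprod(gsub, matrix(Wt[di, dj, , ], Cin, Cout))
    }
  }
  list(gx = gx, gW = gW, gb = gb)
}
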