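#' Enhancement network specification
#'
#' Describes one member of the encoder-decoder family used for B-scan
#' enhancement. `"unet"` is the standard U-net (concatenation skips, no
#' input pyramid); `"brunet"` is the branch-residual U-shaped lineage
#' (concatenation skips plus an injected input pyramid); `"brunet94"` is
#' its 9.4 revision: two back-to-back 3 x 3 convolution blocks per pyramid
#' level on both paths, a horizontal convolution block at the coarsest
#' level, and summation (instead of concatenation) skip connections.
#'
#' @param family `"unet"`, `"brunet"` or `"brunet94"`.
#' @param levels Pyramid depth L (>= 2, default 4).
#' @param base_channels Channel count at the finest level (default 16;
#'   channels double per level).
#' @param upsampling `"transposed"` or `"bilinear"`; default transposed for
#'   unet, bilinear for the brunet family.
#' @param skip_mode `"sum"` or `"concat"`; forced to `"sum"` for brunet94
#'   and `"concat"` for unet.
#' @param pyramid_inject Feed the 2^k-downsampled input image to encoder
#'   level k as an extra channel; default on for the brunet family.
#' @param alt_skips If `TRUE`, apply skips only at every other level (a
#'   literal reading of the skip description); default `FALSE` (all
#'   levels).
#' @param project_on_upsample For bilinear upsampling, insert a 1 x 1
#'   channel-halving convolution after the resize (required for summation
#'   skips to match channel counts).
#' @param residual_head Add the network input to the head output before
#'   clamping, so an untrained network is the identity map.
#' @return A `network_spec` object.
#' @export
network_spec <- function(family = c("brunet94", "brunet", "unet"),
                         levels = 4L, base_channels = 16L,
                         upsampling = NULL, skip_mode = NULL,
                         pyramid_inject = NULL, alt_skips = FALSE,
                         project_on_upsample = TRUE, residual_head = TRUE) {
  family <- match.arg(family)
  if (levels < 2) stop_invalid("levels must be >= 2")
  if (base_channels < 1) stop_invalid("base_channels must be >= 1")
  forced_skip <- switch(family, brunet94 = "sum", unet = "concat", NULL)
  if (is.null(skip_mode)) {
    skip_mode <- forced_skip %||% "concat"
  } else if (!is.null(forced_skip) && skip_mode != forced_skip) {
    stop_invalid("family '%s' requires skip_mode '%s'", family, forced_skip)
  }
  if (!skip_mode %in% c("sum", "concat")) stop_invalid("bad skip_mode")
  if (is.null(upsampling)) {
    upsampling <- if (family == "unet") "transposed" else "bilinear"
  }
  if (!upsampling %in% c("transposed", "bilinear")) {
    stop_invalid("bad upsampling mode")
  }
  if (is.null(pyramid_inject)) pyramid_inject <- family != "unet"
  structure(list(
    family = family, levels = as.integer(levels),
    base_channels = as.integer(base_channels), upsampling = upsampling,
    skip_mode = skip_mode, pyramid_inject = isTRUE(pyramid_inject),
    alt_skips = isTRUE(alt_skips),
    project_on_upsample = isTRUE(project_on_upsample),
    residual_head = isTRUE(residual_head)
  ), class = "network_spec")
}

# Channel bookkeeping shared by construction, forward and the audit.
network_schedule <- function(spec) {
  L <- spec$levels
  ch <- spec$base_channels * 2^(seq_len(L) - 1L)
  enc_in <- c(1L, ch[-L] + as.integer(spec$pyramid_inject))
  dec <- list()
  for (k in rev(seq_len(L - 1L))) {
    up_out <- if (spec$upsampling == "transposed" || spec$project_on_upsample) {
      ch[k]
    } else {
      ch[k + 1L]
    }
    has_skip <- !spec$alt_skips || ((L - 1L - k) %% 2L == 0L)
    comb <- if (!has_skip) up_out
            else if (spec$skip_mode == "sum") up_out
            else up_out + ch[k]
    if (has_skip && spec$skip_mode == "sum" && up_out != ch[k]) {
      stop_invalid(paste0(
        "summation skip at level %d needs matching channel counts ",
        "(skip %d vs upsampled %d); enable project_on_upsample or use ",
        "transposed upsampling"), k, ch[k], up_out)
    }
    dec[[as.character(k)]] <- list(up_out = up_out, has_skip = has_skip,
                                   comb = comb)
  }
  list(ch = ch, enc_in = enc_in, dec = dec)
}

he_init <- function(dims, fan_in) {
  array(rnorm(prod(dims), 0, sqrt(2 / fan_in)), dims)
}

#' Build an enhancement network
#'
#' Constructs the network described by `spec` with deterministic
#' He-initialized parameters. The channel schedule is audited at
#' construction: summation skips with mismatched channel counts raise an
#' error. With `residual_head`, the 1 x 1 output head is zero-initialized so
#' the freshly built network is the identity map.
#'
#' @param spec A [network_spec()].
#' @param seed Integer seed for parameter initialization.
#' @return An `oct_network` object (spec, flat named parameter list,
#'   training history).
#' @export
build_network <- function(spec = network_spec(), seed = 1L) {
  if (!inherits(spec, "network_spec")) stop_invalid("`spec` must be a network_spec")
  sch <- network_schedule(spec)
  L <- spec$levels; ch <- sch$ch
  with_local_seed(seed, {
    P <- list()
    conv_pair <- function(prefix, cin, cout) {
      P[[paste0(prefix, ".conv1.W")]] <<- he_init(c(3, 3, cin, cout), 9 * cin)
      P[[paste0(prefix, ".conv1.b")]] <<- numeric(cout)
      P[[paste0(prefix, ".conv2.W")]] <<- he_init(c(3, 3, cout, cout), 9 * cout)
      P[[paste0(prefix, ".conv2.b")]] <<- numeric(cout)
    }
    for (k in seq_len(L)) conv_pair(paste0("enc", k), sch$enc_in[k], ch[k])
    conv_pair("horiz", ch[L], ch[L])
    for (k in rev(seq_len(L - 1L))) {
      d <- sch$dec[[as.character(k)]]
      if (spec$upsampling == "transposed") {
        P[[paste0("dec", k, ".up.W")]] <- he_init(c(2, 2, ch[k + 1L], ch[k]),
                                                  4 * ch[k + 1L])
        P[[paste0("dec", k, ".up.b")]] <- numeric(ch[k])
      } else if (spec$project_on_upsample) {
        P[[paste0("dec", k, ".up.W")]] <- he_init(c(1, 1, ch[k + 1L], ch[k]),
                                                  ch[k + 1L])
        P[[paste0("dec", k, ".up.b")]] <- numeric(ch[k])
      }
      conv_pair(paste0("dec", k), d$comb, ch[k])
    }
    if (spec$residual_head) {
      P[["head.W"]] <- array(0, c(1, 1, ch[1], 1))
    } else {
      P[["head.W"]] <- he_init(c(1, 1, ch[1], 1), ch[1])
    }
    P[["head.b"]] <- numeric(1)
    structure(list(spec = spec, params = P, history = numeric(0),
                   seed = seed, trained = FALSE),
              class = "oct_network")
  })
}

#' Number of trainable parameters
#'
#' @param net An `oct_network`.
#' @return Integer parameter count.
#' @export
count_parameters <- function(net) {
  sum(vapply(net$params, length, integer(1)))
}

#' @export
print.oct_network <- function(x, ...) {
  cat(sprintf("<oct_network %s, L=%d, base=%d, %s upsampling, %s skips, %s params%s>\n",
              x$spec$family, x$spec$levels, x$spec$base_channels,
              x$spec$upsampling, x$spec$skip_mode,
              format(count_parameters(x), big.mark = ","),
              if (x$trained) ", trained" else ""))
  invisible(x)
}

# Mirror-pad a matrix on the bottom/right to multiples of `m`.
pad_to_multiple <- function(x, m) {
  H <- nrow(x); W <- ncol(x)
  Ht <- as.integer(ceiling(H / m) * m); Wt <- as.integer(ceiling(W / m) * m)
  if (Ht == H && Wt == W) return(list(x = x, H = H, W = W))
  stopifnot(Ht - H <= H - 1, Wt - W <= W - 1)
  ridx <- c(seq_len(H), seq(H - 1L, by = -1L, length.out = Ht - H))
  cidx <- c(seq_len(W), seq(W - 1L, by = -1L, length.out = Wt - W))
  list(x = x[ridx, cidx, drop = FALSE], H = H, W = W)
}

# Full forward pass; with train = TRUE also returns the caches the backward
# pass consumes. `x` is a plain numeric matrix in [0, 1]. Internally feature
# maps are (H*W) x C matrices (see nn-ops.R).
net_forward <- function(net, x, train = FALSE) {
  spec <- net$spec; P <- net$params; L <- spec$levels
  sch <- network_schedule(spec)
  pd <- pad_to_multiple(x, 2L^(L - 1L))
  Hp <- nrow(pd$x); Wp <- ncol(pd$x)
  xm <- matrix(as.vector(pd$x), Hp * Wp, 1L)
  dims <- lapply(seq_len(L), function(k) c(Hp, Wp) %/% 2L^(k - 1L))
  C <- list()  # caches

  inject <- list(xm)
  if (spec$pyramid_inject) {
    for (k in 2:L) {
      inject[[k]] <- meanpool2(inject[[k - 1L]],
                               dims[[k - 1L]][1], dims[[k - 1L]][2])
    }
  }

  conv_block <- function(cur, prefix, H, W) {
    c1 <- conv2d_fwd(cur, H, W, P[[paste0(prefix, ".conv1.W")]],
                     P[[paste0(prefix, ".conv1.b")]])
    r1 <- relu_fwd(c1$out)
    c2 <- conv2d_fwd(r1$out, H, W, P[[paste0(prefix, ".conv2.W")]],
                     P[[paste0(prefix, ".conv2.b")]])
    r2 <- relu_fwd(c2$out)
    C[[prefix]] <<- list(c1 = c1$cache, r1 = r1$cache,
                         c2 = c2$cache, r2 = r2$cache)
    r2$out
  }

  enc_out <- list()
  cur <- xm
  for (k in seq_len(L)) {
    d <- dims[[k]]
    if (k > 1L) {
      mp <- maxpool2_fwd(cur, dims[[k - 1L]][1], dims[[k - 1L]][2])
      C[[paste0("pool", k)]] <- mp$cache
      cur <- mp$out
      if (spec$pyramid_inject) cur <- cbind(cur, inject[[k]])
    }
    cur <- conv_block(cur, paste0("enc", k), d[1], d[2])
    enc_out[[k]] <- cur
  }
  cur <- conv_block(cur, "horiz", dims[[L]][1], dims[[L]][2])
  for (k in rev(seq_len(L - 1L))) {
    d <- sch$dec[[as.character(k)]]
    dk <- dims[[k]]; dk1 <- dims[[k + 1L]]
    if (spec$upsampling == "transposed") {
      up <- tconv2_fwd(cur, dk1[1], dk1[2], P[[paste0("dec", k, ".up.W")]],
                       P[[paste0("dec", k, ".up.b")]])
      C[[paste0("dec", k, ".up")]] <- up$cache
      cur <- up$out
    } else {
      bl <- bilinear_up2_fwd(cur, dk1[1], dk1[2])
      C[[paste0("dec", k, ".bl")]] <- bl$cache
      cur <- bl$out
      if (spec$project_on_upsample) {
        pj <- conv2d_fwd(cur, dk[1], dk[2], P[[paste0("dec", k, ".up.W")]],
                         P[[paste0("dec", k, ".up.b")]])
        C[[paste0("dec", k, ".up")]] <- pj$cache
        cur <- pj$out
      }
    }
    if (d$has_skip) {
      if (spec$skip_mode == "sum") {
        if (ncol(cur) != ncol(enc_out[[k]])) {
          stop("internal: summation skip channel mismatch")  # audited at build
        }
        cur <- cur + enc_out[[k]]
      } else {
        cur <- cbind(cur, enc_out[[k]])
      }
    }
    cur <- conv_block(cur, paste0("dec", k), dk[1], dk[2])
  }
  hd <- conv2d_fwd(cur, Hp, Wp, P[["head.W"]], P[["head.b"]])
  C[["head"]] <- hd$cache
  pre <- matrix(hd$out, Hp, Wp)
  if (spec$residual_head) pre <- pre + pd$x
  out_full <- pmin(pmax(pre, 0), 1)
  C[["clamp_mask"]] <- pre > 0 & pre < 1
  out <- out_full[seq_len(pd$H), seq_len(pd$W), drop = FALSE]
  if (train) {
    list(out = out, caches = C, padded_dim = c(Hp, Wp),
         orig_dim = c(pd$H, pd$W))
  } else {
    out
  }
}

# Backward pass: gradient of a scalar loss with respect to every parameter,
# given the gradient with respect to the (cropped) output. Returns a flat
# named list mirroring net$params.
net_backward <- function(net, fw, gout) {
  spec <- net$spec; P <- net$params; L <- spec$levels
  sch <- network_schedule(spec)
  C <- fw$caches
  Hp <- fw$padded_dim[1]; Wp <- fw$padded_dim[2]
  dims <- lapply(seq_len(L), function(k) c(Hp, Wp) %/% 2L^(k - 1L))
  G <- list()

  gfull <- matrix(0, Hp, Wp)
  gfull[seq_len(fw$orig_dim[1]), seq_len(fw$orig_dim[2])] <- gout
  gpre <- gfull * C[["clamp_mask"]]
  # the residual branch into the input carries no parameter gradient
  bw <- conv2d_bwd(matrix(gpre, Hp * Wp, 1L), C[["head"]], Hp, Wp,
                   P[["head.W"]])
  G[["head.W"]] <- bw$gW
  G[["head.b"]] <- bw$gb
  g <- bw$gx

  conv_block_bwd <- function(g, prefix, H, W, need_gx = TRUE) {
    cc <- C[[prefix]]
    g <- relu_bwd(g, cc$r2)
    bw2 <- conv2d_bwd(g, cc$c2, H, W, P[[paste0(prefix, ".conv2.W")]])
    G[[paste0(prefix, ".conv2.W")]] <<- bw2$gW
    G[[paste0(prefix, ".conv2.b")]] <<- bw2$gb
    g <- relu_bwd(bw2$gx, cc$r1)
    bw1 <- conv2d_bwd(g, cc$c1, H, W, P[[paste0(prefix, ".conv1.W")]],
                      need_gx = need_gx)
    G[[paste0(prefix, ".conv1.W")]] <<- bw1$gW
    G[[paste0(prefix, ".conv1.b")]] <<- bw1$gb
    bw1$gx
  }

  # Decoder: the forward ran k = L-1 .. 1, so gradients are unwound in
  # ascending k (dec1 sits next to the head; dec_k's upsample input is the
  # output of dec_{k+1}, or of the horizontal block at k = L-1).
  g_enc <- vector("list", L)  # gradients flowing into enc_out[[k]] via skips
  for (k in seq_len(L - 1L)) {
    d <- sch$dec[[as.character(k)]]
    dk <- dims[[k]]
    g <- conv_block_bwd(g, paste0("dec", k), dk[1], dk[2])
    if (d$has_skip) {
      if (spec$skip_mode == "sum") {
        g_enc[[k]] <- g
      } else {
        keep <- seq_len(ncol(g) - sch$ch[k])
        g_enc[[k]] <- g[, -keep, drop = FALSE]
        g <- g[, keep, drop = FALSE]
      }
    }
    if (spec$upsampling == "transposed") {
      bw <- tconv2_bwd(g, C[[paste0("dec", k, ".up")]],
                       P[[paste0("dec", k, ".up.W")]])
      G[[paste0("dec", k, ".up.W")]] <- bw$gW
      G[[paste0("dec", k, ".up.b")]] <- bw$gb
      g <- bw$gx
    } else {
      if (spec$project_on_upsample) {
        bw <- conv2d_bwd(g, C[[paste0("dec", k, ".up")]], dk[1], dk[2],
                         P[[paste0("dec", k, ".up.W")]])
        G[[paste0("dec", k, ".up.W")]] <- bw$gW
        G[[paste0("dec", k, ".up.b")]] <- bw$gb
        g <- bw$gx
      }
      g <- bilinear_up2_bwd(g, C[[paste0("dec", k, ".bl")]])
    }
  }
  g <- conv_block_bwd(g, "horiz", dims[[L]][1], dims[[L]][2])
  # Encoder, deepest level first; skip gradients join at their level.
  for (k in rev(seq_len(L))) {
    if (!is.null(g_enc[[k]])) g <- g + g_enc[[k]]
    g <- conv_block_bwd(g, paste0("enc", k), dims[[k]][1], dims[[k]][2],
                        need_gx = k > 1L)
    if (k > 1L) {
      if (spec$pyramid_inject) g <- g[, -ncol(g), drop = FALSE]
      g <- maxpool2_bwd(g, C[[paste0("pool", k)]])
    }
  }
  G[names(P)]
}

#' Enhance a B-scan with a network
#'
#' Runs the forward pass. If the input dimensions are not divisible by
#' `2^(levels - 1)` the image is mirror-padded to the next multiple and the
#' output cropped back, so output dimensions always equal input dimensions.
#' The output is clamped to `[0, 1]`. Deterministic for fixed parameters.
#'
#' @param object An `oct_network`.
#' @param img A [bscan()] or numeric matrix in `[0, 1]`.
#' @param ... Unused.
#' @return Enhanced [bscan()], same dimensions as `img`.
#' @export
predict.oct_network <- function(object, img, ...) {
  m <- as.matrix(img)
  if (!all(is.finite(m))) stop_invalid("input contains non-finite pixels")
  out <- net_forward(object, m)
  rewrap_bscan(out, if (is_bscan(img)) img else NULL,
               list(enhanced_by = object$spec$family))
}

#' @exportS3Method generics::tidy
tidy.oct_network <- function(x, ...) {
  tibble::tibble(epoch = seq_along(x$history), loss = x$history)
}

#' @exportS3Method generics::glance
glance.oct_network <- function(x, ...) {
  tibble::tibble(
    family = x$spec$family, levels = x$spec$levels,
    base_channels = x$spec$base_channels,
    n_parameters = count_parameters(x),
    epochs_trained = length(x$history),
    final_loss = if (length(x$history)) x$history[length(x$history)] else NA_real_
  )
}
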