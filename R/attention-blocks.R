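# Attention operators on convolutional feature maps.
#
# Three trainable blocks are provided:
#   * the self-residual attention block (SRAB): conv -> batch norm ->
#     Softplus -> channel gate -> spatial gate, plus a residual shortcut
#     (1x1-projected when the channel counts differ);
#   * the attention block: channel gate then spatial gate applied directly
#     to the input, with no convolutional preamble and no residual;
#   * the reverse attention block: conv -> batch norm -> Softplus followed
#     by a channel gate; an optional complement mode gates with (1 - w) so
#     that previously down-weighted channels are emphasised.
#
# Channel gates pool each channel to its global average and global maximum,
# concatenate the two statistics and pass them through a single dense layer
# with a sigmoid, giving one multiplicative weight in (0, 1) per channel.
# Spatial gates reduce across channels (mean and max per location), pass the
# two pooled maps through a 7x7 convolution with a sigmoid, and give one
# weight in (0, 1) per spatial location.

## ---- global pooling (public) ----------------------------------------------

#' Global average pooling over spatial locations
#'
#' Reduces an `H x W x C` feature map to a length-`C` vector whose k-th entry
#' is the mean of channel k over all `H * W` locations. A batched
#' `H x W x C x N` array yields a `C x N` matrix.
#'
#' @param x numeric feature map, `[H, W, C]` or `[H, W, C, N]`.
#' @return numeric vector of length `C` (or a `C x N` matrix for batches).
#' @examples
#' global_average_pool(array(c(1, 5, 3, 7), c(2, 2, 1)))  # 4
#' @export
global_average_pool <- function(x) {
  b <- as_batch(x)
  d <- dim(b$x)
  out <- matrix(colMeans(matrix(b$x, d[1] * d[2])), d[3], d[4])
  if (b$had_batch) out else drop(out[, 1])
}

#' Global max pooling over spatial locations
#'
#' Reduces an `H x W x C` feature map to a length-`C` vector whose k-th entry
#' is the maximum of channel k over all locations.
#'
#' @inheritParams global_average_pool
#' @return numeric vector of length `C` (or a `C x N` matrix for batches).
#' @export
global_max_pool <- function(x) {
  b <- as_batch(x)
  d <- dim(b$x)
  M <- matrix(b$x, d[1] * d[2])
  out <- matrix(apply(M, 2, max), d[3], d[4])
  if (b$had_batch) out else drop(out[, 1])
}

## ---- channel attention -----------------------------------------------------

channel_att_layer <- function(c_in, complement = FALSE) {
  # single affine map from the concatenated [GAP, GMP] statistics to C logits
  sd <- sqrt(2 / (3 * c_in))  # Glorot for fan-in 2C, fan-out C
  new_layer("channel_att", list(
    c_in = as.integer(c_in), complement = isTRUE(complement),
    params = list(W = matrix(stats::rnorm(2 * c_in * c_in, sd = sd), 2 * c_in, c_in),
                  b = numeric(c_in))
  ))
}

layer_forward.layer_channel_att <- function(layer, x, training = FALSE) {
  d <- dim(x); C <- d[3]; N <- d[4]
  if (C != layer$c_in) {
    stop(sprintf("channel gate built for %d channels, got %d", layer$c_in, C))
  }
  HW <- d[1] * d[2]
  M <- matrix(x, HW)                                   # HW x (C*N)
  gap <- matrix(colMeans(M), C, N)
  amax <- max.col(t(M), ties.method = "first")          # spatial argmax per (c, n)
  gmp <- matrix(M[cbind(amax, seq_along(amax))], C, N)
  z <- rbind(gap, gmp)                                  # 2C x N
  a <- sigmoid(crossprod(layer$params$W, z) + layer$params$b)
  g <- if (layer$complement) 1 - a else a
  y <- x * rep(as.vector(g), each = HW)
  list(out = y,
       cache = list(x = x, amax = amax, z = z, a = a, g = g, d = d))
}

layer_backward.layer_channel_att <- function(layer, dout, cache) {
  d <- cache$d; C <- d[3]; N <- d[4]; HW <- d[1] * d[2]
  a <- cache$a; g <- cache$g
  dg <- matrix(colSums(matrix(dout * cache$x, HW)), C, N)
  da <- if (layer$complement) -dg else dg
  dlogits <- da * a * (1 - a)
  layer$grads <- list(W = cache$z %*% t(dlogits), b = rowSums(dlogits))
  dz <- layer$params$W %*% dlogits                     # 2C x N
  dx <- dout * rep(as.vector(g), each = HW)
  dx <- dx + rep(as.vector(dz[seq_len(C), , drop = FALSE]) / HW, each = HW)
  flat <- cache$amax + (seq_len(C * N) - 1) * HW
  dgmp <- as.vector(dz[C + seq_len(C), , drop = FALSE])
  dxv <- as.vector(dx)
  dxv[flat] <- dxv[flat] + dgmp
  dim(dxv) <- d
  dxv
}

## ---- spatial attention -----------------------------------------------------

spatial_att_layer <- function(kernel = 7L) {
  new_layer("spatial_att", list(
    kernel = as.integer(kernel),
    conv = conv2d_layer(2L, 1L, kernel = kernel, stride = 1L, pad = "same",
                        init_sd = sqrt(2 / (kernel * kernel * 3)))
  ))
}

layer_children.layer_spatial_att <- function(layer) list(layer$conv)

spatial_pool <- function(x) {
  d <- dim(x); HW <- d[1] * d[2]; C <- d[3]; N <- d[4]
  A <- x
  dim(A) <- c(HW, C, N)
  ap <- matrix(0, HW, N)
  cmax <- matrix(0L, HW, N)
  mp <- matrix(0, HW, N)
  for (n in seq_len(N)) {
    An <- A[, , n, drop = TRUE]
    if (C == 1L) An <- matrix(An, HW, 1L)
    ap[, n] <- rowMeans(An)
    cm <- max.col(An, ties.method = "first")
    cmax[, n] <- cm
    mp[, n] <- An[cbind(seq_len(HW), cm)]
  }
  pooled <- array(0, c(d[1], d[2], 2L, N))
  pooled[, , 1L, ] <- ap
  pooled[, , 2L, ] <- mp
  list(pooled = pooled, cmax = cmax)
}

layer_forward.layer_spatial_att <- function(layer, x, training = FALSE) {
  d <- dim(x); C <- d[3]
  sp <- spatial_pool(x)
  cf <- layer_forward(layer$conv, sp$pooled, training)
  s <- sigmoid(cf$out)                                  # [H, W, 1, N]
  sx <- s[, , rep(1L, C), , drop = FALSE]
  y <- x * sx
  list(out = y,
       cache = list(x = x, s = s, sx = sx, cmax = sp$cmax, conv = cf$cache, d = d))
}

layer_backward.layer_spatial_att <- function(layer, dout, cache) {
  d <- cache$d; HW <- d[1] * d[2]; C <- d[3]; N <- d[4]
  s <- cache$s
  B <- dout * cache$x
  dim(B) <- c(HW, C, N)
  ds <- matrix(0, HW, N)
  for (n in seq_len(N)) {
    Bn <- B[, , n, drop = TRUE]
    ds[, n] <- if (C == 1L) Bn else rowSums(Bn)
  }
  dlogits <- array(ds, c(d[1], d[2], 1L, N)) * s * (1 - s)
  dpooled <- layer_backward(layer$conv, dlogits, cache$conv)
  dap <- dpooled[, , 1L, , drop = FALSE]                # [H, W, 1, N]
  dmp <- dpooled[, , 2L, , drop = FALSE]
  dx <- dout * cache$sx
  dx <- dx + dap[, , rep(1L, C), , drop = FALSE] / C
  flat <- rep(seq_len(HW), N) + (as.vector(cache$cmax) - 1) * HW +
    rep((seq_len(N) - 1) * HW * C, each = HW)
  dxv <- as.vector(dx)
  dxv[flat] <- dxv[flat] + as.vector(dmp)
  dim(dxv) <- d
  dxv
}

## ---- composite blocks ------------------------------------------------------

srab_layer <- function(c_in, filters, kernel = 3L) {
  new_layer("srab", list(
    c_in = as.integer(c_in), filters = as.integer(filters),
    conv = conv2d_layer(c_in, filters, kernel = kernel),
    bn = batchnorm_layer(filters),
    ca = channel_att_layer(filters),
    sa = spatial_att_layer(),
    proj = if (c_in != filters) conv2d_layer(c_in, filters, kernel = 1L) else NULL
  ))
}

layer_children.layer_srab <- function(layer) {
  kids <- list(layer$conv, layer$bn, layer$ca, layer$sa)
  if (!is.null(layer$proj)) kids <- c(kids, list(layer$proj))
  kids
}

layer_forward.layer_srab <- function(layer, x, training = FALSE) {
  f1 <- layer_forward(layer$conv, x, training)
  check_finite(f1$out, "srab/conv")
  f2 <- layer_forward(layer$bn, f1$out, training)
  check_finite(f2$out, "srab/batchnorm")
  act <- softplus(f2$out)
  f3 <- layer_forward(layer$ca, act, training)
  f4 <- layer_forward(layer$sa, f3$out, training)
  check_finite(f4$out, "srab/attention")
  if (is.null(layer$proj)) {
    res <- x
    rc <- NULL
  } else {
    fr <- layer_forward(layer$proj, x, training)
    res <- fr$out
    rc <- fr$cache
  }
  list(out = f4$out + res,
       cache = list(c1 = f1$cache, c2 = f2$cache, act_in = f2$out,
                    c3 = f3$cache, c4 = f4$cache, cr = rc))
}

layer_backward.layer_srab <- function(layer, dout, cache) {
  d4 <- layer_backward(layer$sa, dout, cache$c4)
  d3 <- layer_backward(layer$ca, d4, cache$c3)
  dact <- d3 * sigmoid(cache$act_in)
  d2 <- layer_backward(layer$bn, dact, cache$c2)
  dx <- layer_backward(layer$conv, d2, cache$c1)
  if (is.null(layer$proj)) {
    dx + dout
  } else {
    dx + layer_backward(layer$proj, dout, cache$cr)
  }
}

attention_block_layer <- function(c_in) {
  new_layer("attention_block", list(
    c_in = as.integer(c_in),
    ca = channel_att_layer(c_in),
    sa = spatial_att_layer()
  ))
}

layer_children.layer_attention_block <- function(layer) list(layer$ca, layer$sa)

layer_forward.layer_attention_block <- function(layer, x, training = FALSE) {
  f1 <- layer_forward(layer$ca, x, training)
  f2 <- layer_forward(layer$sa, f1$out, training)
  check_finite(f2$out, "attention_block")
  list(out = f2$out, cache = list(c1 = f1$cache, c2 = f2$cache))
}

layer_backward.layer_attention_block <- function(layer, dout, cache) {
  d2 <- layer_backward(layer$sa, dout, cache$c2)
  layer_backward(layer$ca, d2, cache$c1)
}

reverse_att_layer <- function(c_in, filters, kernel = 3L, complement_gate = FALSE) {
  new_layer("reverse_att", list(
    c_in = as.integer(c_in), filters = as.integer(filters),
    complement_gate = isTRUE(complement_gate),
    conv = conv2d_layer(c_in, filters, kernel = kernel),
    bn = batchnorm_layer(filters),
    ra = channel_att_layer(filters, complement = complement_gate)
  ))
}

layer_children.layer_reverse_att <- function(layer) {
  list(layer$conv, layer$bn, layer$ra)
}

layer_forward.layer_reverse_att <- function(layer, x, training = FALSE) {
  f1 <- layer_forward(layer$conv, x, training)
  check_finite(f1$out, "reverse_att/conv")
  f2 <- layer_forward(layer$bn, f1$out, training)
  check_finite(f2$out, "reverse_att/batchnorm")
  act <- softplus(f2$out)
  f3 <- layer_forward(layer$ra, act, training)
  check_finite(f3$out, "reverse_att/gate")
  list(out = f3$out,
       cache = list(c1 = f1$cache, c2 = f2$cache, act_in = f2$out, c3 = f3$cache))
}

layer_backward.layer_reverse_att <- function(layer, dout, cache) {
  d3 <- layer_backward(layer$ra, dout, cache$c3)
  dact <- d3 * sigmoid(cache$act_in)
  d2 <- layer_backward(layer$bn, dact, cache$c2)
  layer_backward(layer$conv, d2, cache$c1)
}

## ---- public functional interface ------------------------------------------

#' Create parameters for a channel-attention gate
#'
#' The gate maps the concatenated global-average/global-max channel
#' statistics (length `2C`) through one dense layer to `C` sigmoid weights.
#'
#' @param c_in number of input channels the gate is built for.
#' @param seed integer seed for the random initialisation.
#' @return a parameter object usable with [channel_attention_apply()].
#' @export
channel_attention_params <- function(c_in, seed = 1L) {
  withr::with_seed(seed, channel_att_layer(c_in))
}

#' Apply channel attention to a feature map
#'
#' Multiplies each channel of `x` by its gate weight in (0, 1), computed from
#' the channel's global average and maximum.
#'
#' @param x feature map `[H, W, C]` (or batched `[H, W, C, N]`).
#' @param p parameters from [channel_attention_params()].
#' @return gated feature map with the same shape as `x`.
#' @export
channel_attention_apply <- function(x, p) {
  b <- as_batch(x)
  drop_batch(layer_forward(p, b$x, training = FALSE)$out, b$had_batch)
}

#' Channel-attention gate weights for a feature map
#'
#' @inheritParams channel_attention_apply
#' @return numeric vector of length `C` (or `C x N`), strictly in (0, 1).
#' @export
channel_attention_weights <- function(x, p) {
  b <- as_batch(x)
  g <- layer_forward(p, b$x, training = FALSE)$cache$g
  if (b$had_batch) g else drop(g[, 1])
}

#' Create parameters for a spatial-attention gate
#'
#' @param kernel odd kernel size of the 2-to-1-channel gating convolution.
#' @param seed integer seed for the random initialisation.
#' @export
spatial_attention_params <- function(kernel = 7L, seed = 1L) {
  withr::with_seed(seed, spatial_att_layer(kernel))
}

#' Apply spatial attention to a feature map
#'
#' Each spatial location is weighted by a sigmoid gate computed from the
#' channel-mean and channel-max pooled maps, broadcast across channels.
#'
#' @param x feature map `[H, W, C]` (or batched).
#' @param p parameters from [spatial_attention_params()].
#' @export
spatial_attention_apply <- function(x, p) {
  b <- as_batch(x)
  drop_batch(layer_forward(p, b$x, training = FALSE)$out, b$had_batch)
}

#' Spatial-attention gate weights for a feature map
#'
#' @inheritParams spatial_attention_apply
#' @return `H x W` matrix of weights strictly in (0, 1).
#' @export
spatial_attention_weights <- function(x, p) {
  b <- as_batch(x)
  s <- layer_forward(p, b$x, training = FALSE)$cache$s
  if (b$had_batch) s else matrix(s, dim(b$x)[1], dim(b$x)[2])
}

#' Create parameters for a self-residual attention block
#'
#' @param c_in input channel count.
#' @param filters output channel count of the convolutional preamble.
#' @param kernel odd kernel size of the preamble convolution (default 3).
#' @param seed integer seed for the random initialisation.
#' @export
srab_params <- function(c_in, filters, kernel = 3L, seed = 1L) {
  withr::with_seed(seed, srab_layer(c_in, filters, kernel))
}

#' Self-residual attention block forward pass
#'
#' conv -> batch normalisation -> Softplus -> channel gate -> spatial gate,
#' plus a residual shortcut from the input (1x1-projected when the channel
#' counts differ). Batch normalisation uses its running statistics
#' (inference mode) unless `training = TRUE`.
#'
#' @param x feature map `[H, W, C]` (or batched).
#' @param p parameters from [srab_params()].
#' @param training logical; use batch statistics and update running ones.
#' @return feature map `[H, W, filters]`.
#' @export
srab_forward <- function(x, p, training = FALSE) {
  b <- as_batch(x)
  drop_batch(layer_forward(p, b$x, training = training)$out, b$had_batch)
}

#' Create parameters for an attention block (no conv preamble, no residual)
#'
#' @inheritParams channel_attention_params
#' @export
attention_block_params <- function(c_in, seed = 1L) {
  withr::with_seed(seed, attention_block_layer(c_in))
}

#' Attention block forward pass
#'
#' Channel gate followed by spatial gate applied directly to the input; the
#' shape is preserved.
#'
#' @inheritParams srab_forward
#' @param p parameters from [attention_block_params()].
#' @export
attention_block_forward <- function(x, p, training = FALSE) {
  b <- as_batch(x)
  drop_batch(layer_forward(p, b$x, training = training)$out, b$had_batch)
}

#' Create parameters for a reverse attention block
#'
#' @inheritParams srab_params
#' @param complement_gate gate with `1 - w` instead of `w`, emphasising
#'   channels the sigmoid down-weighted. Default `FALSE` (literal gating).
#' @export
reverse_attention_params <- function(c_in, filters, kernel = 3L,
                                     complement_gate = FALSE, seed = 1L) {
  withr::with_seed(seed, reverse_att_layer(c_in, filters, kernel, complement_gate))
}

#' Reverse attention block forward pass
#'
#' conv -> batch normalisation -> Softplus followed by a channel gate; no
#' spatial gate and no residual shortcut.
#'
#' @inheritParams srab_forward
#' @param p parameters from [reverse_attention_params()].
#' @return feature map `[H, W, filters]`.
#' @export
reverse_attention_forward <- function(x, p, training = FALSE) {
  b <- as_batch(x)
  drop_batch(layer_forward(p, b$x, training = training)$out, b$had_batch)
}

#' Set every trainable parameter of a block or model to a constant
#'
#' Mainly a diagnostic tool: with all parameters zero the gates reduce to
#' sigma(0) = 0.5 and the blocks have closed-form outputs, which is useful
#' for verifying an installation.
#'
#' @param p a parameter object or model.
#' @param value constant to fill with (default 0).
#' @return `p`, modified in place and returned invisibly.
#' @export
zero_all_parameters <- function(p, value = 0) {
  for (l in walk_layers(p)) {
    for (nm in names(l$params)) {
      l$params[[nm]][] <- value
    }
  }
  invisible(p)
}
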