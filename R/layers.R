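# Minimal trainable-layer framework.
#
# Each layer is an environment holding `params` (trainable arrays), optional
# `buffers` (non-trainable state such as batch-norm running statistics) and
# layer hyperparameters. `layer_forward()` returns list(out, cache);
# `layer_backward()` consumes the upstream gradient plus that cache, stores
# parameter gradients in `layer$grads` and returns the input gradient.
# Convolutions are evaluated as im2col gathers followed by a single BLAS
# matrix multiplication; all activations use the [H, W, C, N] layout.

new_layer <- function(kind, fields = list()) {
  e <- list2env(fields, parent = emptyenv())
  e$kind <- kind
  e$idx_cache <- list()
  class(e) <- c(paste0("layer_", kind), "nn_layer")
  e
}

is_nn_layer <- function(x) inherits(x, "nn_layer")

# Explicit kind-based dispatch (the layer set is closed, and this keeps the
# internal generics callable from tests without S3 registration).
layer_method <- function(prefix, kind, required = TRUE) {
  f <- get0(paste0(prefix, ".layer_", kind), mode = "function",
            envir = parent.env(environment()))
  if (is.null(f) && required) stop(sprintf("no %s method for layer '%s'", prefix, kind))
  f
}

layer_forward <- function(layer, x, training = FALSE) {
  layer_method("layer_forward", layer$kind)(layer, x, training)
}

layer_backward <- function(layer, dout, cache) {
  layer_method("layer_backward", layer$kind)(layer, dout, cache)
}

# Sub-layers of composite blocks, used when walking a model for its
# trainable state.
layer_children <- function(layer) {
  f <- layer_method("layer_children", layer$kind, required = FALSE)
  if (is.null(f)) list() else f(layer)
}

#' Flatten a model/layer tree into the list of parameter-bearing layers
#' @keywords internal
walk_layers <- function(x) {
  if (is.list(x) && !is_nn_layer(x)) {
    return(do.call(c, lapply(x, walk_layers)))
  }
  out <- list()
  if (!is.null(x$params)) out <- list(x)
  kids <- layer_children(x)
  if (length(kids)) out <- c(out, do.call(c, lapply(kids, walk_layers)))
  out
}

## ---- convolution ----------------------------------------------------------

conv2d_layer <- function(c_in, c_out, kernel = 3L, stride = 1L,
                         pad = c("same", "valid"), init_sd = NULL) {
  pad <- match.arg(pad)
  k <- as.integer(kernel)
  if (k < 1L || k %% 2L == 0L) stop("conv kernel must be a positive odd integer")
  fan_in <- k * k * c_in
  sd <- init_sd %||% sqrt(2 / fan_in)  # He initialisation
  new_layer("conv2d", list(
    c_in = as.integer(c_in), c_out = as.integer(c_out), k = k,
    stride = as.integer(stride),
    pad_n = if (pad == "same") (k - 1L) %/% 2L else 0L,
    params = list(
      W = matrix(stats::rnorm(fan_in * c_out, sd = sd), fan_in, c_out),
      b = numeric(c_out)
    )
  ))
}

# Precompute (and cache per input shape) the im2col gather indices.
conv_index <- function(layer, H, W, C, N) {
  key <- paste(H, W, N, sep = "x")
  hit <- layer$idx_cache[[key]]
  if (!is.null(hit)) return(hit)
  k <- layer$k; s <- layer$stride; p <- layer$pad_n
  Hp <- H + 2L * p; Wp <- W + 2L * p
  Hout <- (Hp - k) %/% s + 1L
  Wout <- (Wp - k) %/% s + 1L
  if (Hout < 1L || Wout < 1L) {
    stop(sprintf("input %dx%d too small for %dx%d conv (stride %d)", H, W, k, k, s))
  }
  n_out <- Hout * Wout
  ti <- (rep(seq_len(Hout), times = Wout) - 1L) * s       # top-left corner, padded coords
  tj <- (rep(seq_len(Wout), each = Hout) - 1L) * s
  ki <- rep(seq_len(k), times = k)
  kj <- rep(seq_len(k), each = k)
  idx1 <- outer(ti, ki, "+") + Hp * outer(tj, kj - 1L, "+")  # n_out x k^2
  kk <- k * k
  idx <- idx1[, rep.int(seq_len(kk), C), drop = FALSE]
  if (C > 1L) {
    idx <- idx + matrix(rep((seq_len(C) - 1L) * (Hp * Wp), each = kk),
                        n_out, kk * C, byrow = TRUE)
  }
  if (N > 1L) {
    idx <- idx[rep.int(seq_len(n_out), N), , drop = FALSE] +
      rep((seq_len(N) - 1L) * (Hp * Wp * C), each = n_out)
  }
  out <- list(idx = idx, Hout = Hout, Wout = Wout, Hp = Hp, Wp = Wp)
  layer$idx_cache[[key]] <- out
  out
}

layer_forward.layer_conv2d <- function(layer, x, training = FALSE) {
  d <- dim(x)
  if (d[3] != layer$c_in) {
    stop(sprintf("conv2d built for %d input channels, got %d", layer$c_in, d[3]))
  }
  ii <- conv_index(layer, d[1], d[2], d[3], d[4])
  p <- layer$pad_n
  if (p > 0L) {
    xp <- array(0, c(ii$Hp, ii$Wp, d[3], d[4]))
    xp[p + seq_len(d[1]), p + seq_len(d[2]), , ] <- x
  } else {
    xp <- x
  }
  P <- xp[as.vector(ii$idx)]  # as.vector: a k^2*C-column matrix index would
  dim(P) <- dim(ii$idx)       # otherwise be read as coordinate rows
  out <- P %*% layer$params$W
  out <- out + rep(layer$params$b, each = nrow(out))
  y <- array(out, c(ii$Hout, ii$Wout, d[4], layer$c_out))
  y <- aperm(y, c(1L, 2L, 4L, 3L))
  list(out = y, cache = list(P = P, ii = ii, dimx = d))
}

layer_backward.layer_conv2d <- function(layer, dout, cache) {
  ii <- cache$ii; d <- cache$dimx
  dmat <- matrix(aperm(dout, c(1L, 2L, 4L, 3L)),
                 nrow = ii$Hout * ii$Wout * d[4], ncol = layer$c_out)
  layer$grads <- list(W = crossprod(cache$P, dmat), b = colSums(dmat))
  dP <- tcrossprod(dmat, layer$params$W)
  dxp <- numeric(ii$Hp * ii$Wp * d[3] * d[4])
  idx <- ii$idx
  # Within one patch-offset column every target index is unique, so the
  # scatter-add can be vectorised column by column.
  for (j in seq_len(ncol(idx))) {
    jj <- idx[, j]
    dxp[jj] <- dxp[jj] + dP[, j]
  }
  dim(dxp) <- c(ii$Hp, ii$Wp, d[3], d[4])
  p <- layer$pad_n
  if (p > 0L) {
    dx <- dxp[p + seq_len(d[1]), p + seq_len(d[2]), , , drop = FALSE]
  } else {
    dx <- dxp
  }
  dim(dx) <- d
  dx
}

## ---- batch normalisation --------------------------------------------------

batchnorm_layer <- function(c_in, eps = 1e-3, momentum = 0.9) {
  new_layer("batchnorm", list(
    c_in = as.integer(c_in), eps = eps, momentum = momentum,
    params = list(gamma = rep(1, c_in), beta = numeric(c_in)),
    buffers = list(run_mean = numeric(c_in), run_var = rep(1, c_in))
  ))
}

layer_forward.layer_batchnorm <- function(layer, x, training = FALSE) {
  d <- dim(x); C <- d[3]
  if (C != layer$c_in) stop(sprintf("batchnorm built for %d channels, got %d", layer$c_in, C))
  M <- matrix(aperm(x, c(1L, 2L, 4L, 3L)), ncol = C)  # (H*W*N) x C
  if (training) {
    mu <- colMeans(M)
    v <- colMeans(M * M) - mu * mu
    v <- pmax(v, 0)
    m <- layer$momentum
    layer$buffers$run_mean <- m * layer$buffers$run_mean + (1 - m) * mu
    layer$buffers$run_var <- m * layer$buffers$run_var + (1 - m) * v
  } else {
    mu <- layer$buffers$run_mean
    v <- layer$buffers$run_var
  }
  inv_sd <- 1 / sqrt(v + layer$eps)
  n <- nrow(M)
  xhat <- (M - rep(mu, each = n)) * rep(inv_sd, each = n)
  Y <- xhat * rep(layer$params$gamma, each = n) + rep(layer$params$beta, each = n)
  y <- aperm(array(Y, c(d[1], d[2], d[4], C)), c(1L, 2L, 4L, 3L))
  list(out = y, cache = list(xhat = xhat, inv_sd = inv_sd, dimx = d, training = training))
}

layer_backward.layer_batchnorm <- function(layer, dout, cache) {
  d <- cache$dimx; C <- d[3]
  Dm <- matrix(aperm(dout, c(1L, 2L, 4L, 3L)), ncol = C)
  n <- nrow(Dm)
  xhat <- cache$xhat
  layer$grads <- list(gamma = colSums(Dm * xhat), beta = colSums(Dm))
  g <- rep(layer$params$gamma, each = n)
  dxhat <- Dm * g
  if (cache$training) {
    # full batch-statistics gradient
    s1 <- colSums(dxhat)
    s2 <- colSums(dxhat * xhat)
    DX <- (dxhat - rep(s1 / n, each = n) - xhat * rep(s2 / n, each = n)) *
      rep(cache$inv_sd, each = n)
  } else {
    DX <- dxhat * rep(cache$inv_sd, each = n)
  }
  aperm(array(DX, c(d[1], d[2], d[4], C)), c(1L, 2L, 4L, 3L))
}

## ---- activations ----------------------------------------------------------

activation_layer <- function(fn = c("softplus", "relu", "sigmoid", "linear")) {
  fn <- match.arg(fn)
  new_layer("act", list(fn = fn))
}

layer_forward.layer_act <- function(layer, x, training = FALSE) {
  y <- switch(layer$fn,
    softplus = softplus(x),
    relu = pmax(x, 0),
    sigmoid = sigmoid(x),
    linear = x
  )
  list(out = y, cache = list(x = x))
}

layer_backward.layer_act <- function(layer, dout, cache) {
  switch(layer$fn,
    softplus = dout * sigmoid(cache$x),
    relu = dout * (cache$x > 0),
    sigmoid = {
      s <- sigmoid(cache$x)
      dout * s * (1 - s)
    },
    linear = dout
  )
}

## ---- max pooling ----------------------------------------------------------

maxpool_layer <- function(k = 3L, stride = 2L, pad = 1L) {
  new_layer("maxpool", list(k = as.integer(k), stride = as.integer(stride),
                            pad_n = as.integer(pad)))
}

maxpool_index <- function(layer, H, W, CN) {
  key <- paste(H, W, CN, sep = "x")
  hit <- layer$idx_cache[[key]]
  if (!is.null(hit)) return(hit)
  k <- layer$k; s <- layer$stride; p <- layer$pad_n
  Hp <- H + 2L * p; Wp <- W + 2L * p
  Hout <- (Hp - k) %/% s + 1L
  Wout <- (Wp - k) %/% s + 1L
  n_out <- Hout * Wout
  ti <- (rep(seq_len(Hout), times = Wout) - 1L) * s
  tj <- (rep(seq_len(Wout), each = Hout) - 1L) * s
  ki <- rep(seq_len(k), times = k)
  kj <- rep(seq_len(k), each = k)
  idx1 <- outer(ti, ki, "+") + Hp * outer(tj, kj - 1L, "+")
  idx <- idx1[rep.int(seq_len(n_out), CN), , drop = FALSE] +
    rep((seq_len(CN) - 1L) * (Hp * Wp), each = n_out)
  out <- list(idx = idx, Hout = Hout, Wout = Wout, Hp = Hp, Wp = Wp)
  layer$idx_cache[[key]] <- out
  out
}

layer_forward.layer_maxpool <- function(layer, x, training = FALSE) {
  d <- dim(x)
  CN <- d[3] * d[4]
  ii <- maxpool_index(layer, d[1], d[2], CN)
  p <- layer$pad_n
  if (p > 0L) {
    xp <- array(-Inf, c(ii$Hp, ii$Wp, CN))
    xp[p + seq_len(d[1]), p + seq_len(d[2]), ] <- x
  } else {
    xp <- x
    dim(xp) <- c(ii$Hp, ii$Wp, CN)
  }
  P <- xp[as.vector(ii$idx)]
  dim(P) <- dim(ii$idx)
  amax <- max.col(P, ties.method = "first")
  y <- P[cbind(seq_len(nrow(P)), amax)]
  dim(y) <- c(ii$Hout, ii$Wout, d[3], d[4])
  list(out = y, cache = list(ii = ii, amax = amax, dimx = d))
}

layer_backward.layer_maxpool <- function(layer, dout, cache) {
  ii <- cache$ii; d <- cache$dimx
  CN <- d[3] * d[4]
  lin <- ii$idx[cbind(seq_len(nrow(ii$idx)), cache$amax)]
  # overlapping windows can pick the same source pixel -> aggregate first
  agg <- rowsum(as.vector(dout), group = lin)
  dxp <- numeric(ii$Hp * ii$Wp * CN)
  dxp[as.numeric(rownames(agg))] <- agg
  dim(dxp) <- c(ii$Hp, ii$Wp, CN)
  p <- layer$pad_n
  dx <- if (p > 0L) dxp[p + seq_len(d[1]), p + seq_len(d[2]), , drop = FALSE] else dxp
  dim(dx) <- d
  dx
}

## ---- flatten and dense ----------------------------------------------------

flatten_layer <- function() new_layer("flatten", list())

layer_forward.layer_flatten <- function(layer, x, training = FALSE) {
  d <- dim(x)
  y <- t(matrix(x, prod(d[1:3]), d[4]))  # N x D
  list(out = y, cache = list(dimx = d))
}

layer_backward.layer_flatten <- function(layer, dout, cache) {
  array(t(dout), cache$dimx)
}

dense_layer <- function(d_in, d_out, init_sd = NULL) {
  sd <- init_sd %||% sqrt(2 / d_in)
  new_layer("dense", list(
    d_in = as.integer(d_in), d_out = as.integer(d_out),
    params = list(W = matrix(stats::rnorm(d_in * d_out, sd = sd), d_in, d_out),
                  b = numeric(d_out))
  ))
}

layer_forward.layer_dense <- function(layer, x, training = FALSE) {
  if (ncol(x) != layer$d_in) {
    stop(sprintf("dense layer built for %d inputs, got %d", layer$d_in, ncol(x)))
  }
  y <- x %*% layer$params$W
  y <- y + rep(layer$params$b, each = nrow(y))
  list(out = y, cache = list(x = x))
}

layer_backward.layer_dense <- function(layer, dout, cache) {
  layer$grads <- list(W = crossprod(cache$x, dout), b = colSums(dout))
  tcrossprod(dout, layer$params$W)
}

## ---- sequential container -------------------------------------------------

sequential_layer <- function(layers) {
  new_layer("sequential", list(layers = layers))
}

layer_children.layer_sequential <- function(layer) layer$layers

layer_forward.layer_sequential <- function(layer, x, training = FALSE) {
  caches <- vector("list", length(layer$layers))
  for (i in seq_along(layer$layers)) {
    step <- layer_forward(layer$layers[[i]], x, training)
    x <- step$out
    caches[[i]] <- step$cache
  }
  list(out = x, cache = caches)
}

layer_backward.layer_sequential <- function(layer, dout, cache) {
  for (i in rev(seq_along(layer$layers))) {
    dout <- layer_backward(layer$layers[[i]], dout, cache[[i]])
  }
  dout
}
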