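# Convolutional backbones producing the feature map consumed by the
# attention blocks.
#
# * "resnet50": the standard 50-layer residual network truncated at its last
#   convolutional feature map (stem of 7x7/2 conv + 3x3/2 max pool, then
#   bottleneck stages of depth 3/4/6/3), giving a 32x-downsampled map with
#   2048 channels. Weights are randomly initialised (He) unless a saved
#   state is loaded; see `load_model()`.
# * "tiny": a 4-convolution CNN (three stride-2 stages and one stride-1
#   stage) for CPU-scale experiments and tests.

bottleneck_layer <- function(c_in, mid, c_out, stride = 1L) {
  new_layer("bottleneck", list(
    c_in = as.integer(c_in), c_out = as.integer(c_out),
    conv1 = conv2d_layer(c_in, mid, kernel = 1L),
    bn1 = batchnorm_layer(mid),
    conv2 = conv2d_layer(mid, mid, kernel = 3L, stride = stride),
    bn2 = batchnorm_layer(mid),
    conv3 = conv2d_layer(mid, c_out, kernel = 1L),
    bn3 = batchnorm_layer(c_out),
    down = if (c_in != c_out || stride != 1L) {
      list(conv = conv2d_layer(c_in, c_out, kernel = 1L, stride = stride),
           bn = batchnorm_layer(c_out))
    } else NULL
  ))
}

layer_children.layer_bottleneck <- function(layer) {
  kids <- list(layer$conv1, layer$bn1, layer$conv2, layer$bn2,
               layer$conv3, layer$bn3)
  if (!is.null(layer$down)) kids <- c(kids, list(layer$down$conv, layer$down$bn))
  kids
}

layer_forward.layer_bottleneck <- function(layer, x, training = FALSE) {
  f1 <- layer_forward(layer$conv1, x, training)
  g1 <- layer_forward(layer$bn1, f1$out, training)
  a1 <- pmax(g1$out, 0)
  f2 <- layer_forward(layer$conv2, a1, training)
  g2 <- layer_forward(layer$bn2, f2$out, training)
  a2 <- pmax(g2$out, 0)
  f3 <- layer_forward(layer$conv3, a2, training)
  g3 <- layer_forward(layer$bn3, f3$out, training)
  if (is.null(layer$down)) {
    res <- x
    dc <- NULL
  } else {
    fd <- layer_forward(layer$down$conv, x, training)
    gd <- layer_forward(layer$down$bn, fd$out, training)
    res <- gd$out
    dc <- list(conv = fd$cache, bn = gd$cache)
  }
  pre <- g3$out + res
  list(out = pmax(pre, 0),
       cache = list(c1 = f1$cache, b1 = g1$cache, z1 = g1$out,
                    c2 = f2$cache, b2 = g2$cache, z2 = g2$out,
                    c3 = f3$cache, b3 = g3$cache, pre = pre, down = dc))
}

layer_backward.layer_bottleneck <- function(layer, dout, cache) {
  dpre <- dout * (cache$pre > 0)
  d3 <- layer_backward(layer$bn3, dpre, cache$b3)
  d3 <- layer_backward(layer$conv3, d3, cache$c3)
  d3 <- d3 * (cache$z2 > 0)
  d2 <- layer_backward(layer$bn2, d3, cache$b2)
  d2 <- layer_backward(layer$conv2, d2, cache$c2)
  d2 <- d2 * (cache$z1 > 0)
  d1 <- layer_backward(layer$bn1, d2, cache$b1)
  dx <- layer_backward(layer$conv1, d1, cache$c1)
  if (is.null(layer$down)) {
    dx + dpre
  } else {
    dr <- layer_backward(layer$down$bn, dpre, cache$down$bn)
    dx + layer_backward(layer$down$conv, dr, cache$down$conv)
  }
}

conv_bn_relu <- function(c_in, c_out, kernel, stride) {
  list(conv2d_layer(c_in, c_out, kernel = kernel, stride = stride),
       batchnorm_layer(c_out),
       activation_layer("relu"))
}

build_resnet50_backbone <- function(input_channels = 3L) {
  layers <- conv_bn_relu(input_channels, 64L, kernel = 7L, stride = 2L)
  layers <- c(layers, list(maxpool_layer(k = 3L, stride = 2L, pad = 1L)))
  stage <- function(c_in, mid, c_out, n, stride) {
    out <- list(bottleneck_layer(c_in, mid, c_out, stride))
    for (i in seq_len(n - 1L)) out <- c(out, list(bottleneck_layer(c_out, mid, c_out, 1L)))
    out
  }
  layers <- c(layers,
              stage(64L, 64L, 256L, 3L, 1L),
              stage(256L, 128L, 512L, 4L, 2L),
              stage(512L, 256L, 1024L, 6L, 2L),
              stage(1024L, 512L, 2048L, 3L, 2L))
  list(layers = layers, c_out = 2048L, min_input = 32L)
}

build_tiny_backbone <- function(input_channels = 3L) {
  layers <- c(
    conv_bn_relu(input_channels, 8L, kernel = 3L, stride = 2L),
    conv_bn_relu(8L, 16L, kernel = 3L, stride = 2L),
    conv_bn_relu(16L, 32L, kernel = 3L, stride = 2L),
    conv_bn_relu(32L, 32L, kernel = 3L, stride = 1L)
  )
  list(layers = layers, c_out = 32L, min_input = 8L)
}
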