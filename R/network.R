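# The embedding generator and its Siamese triplet wrapper.
#
# Layer order: backbone feature map -> self-residual attention block 1 ->
# self-residual attention block 2 -> attention block -> reverse attention
# block -> flatten -> hidden dense (Softplus) -> linear embedding layer.

#' Configuration for the embedding network
#'
#' @param backbone `"resnet50"` (50-layer residual network truncated at its
#'   last convolutional feature map) or `"tiny"` (a 4-conv CPU-scale test
#'   backbone).
#' @param input_size height = width of the input images in pixels.
#' @param input_channels number of image channels fed to the network
#'   (grayscale sources are replicated to 3 channels upstream).
#' @param backbone_pretrained logical; if `TRUE`, `weights_file` must point
#'   to a saved model state providing backbone weights. There is no download
#'   mechanism; weights are otherwise randomly initialised.
#' @param weights_file optional path to a model state saved by [save_model()].
#' @param srab_filters integer pair: filter counts of the two self-residual
#'   attention blocks.
#' @param reverse_filters filter count of the reverse attention block.
#' @param complement_gate reverse-attention gate mode; see
#'   [reverse_attention_params()].
#' @param head_hidden_units width of the hidden dense layer.
#' @param embedding_dim length of the output embedding (default 256).
#' @param seed integer seed governing parameter initialisation.
#' @return a `network_config` list.
#' @export
network_config <- function(backbone = c("resnet50", "tiny"),
                           input_size = 200L,
                           input_channels = 3L,
                           backbone_pretrained = FALSE,
                           weights_file = NULL,
                           srab_filters = c(512L, 256L),
                           reverse_filters = 256L,
                           complement_gate = FALSE,
                           head_hidden_units = 512L,
                           embedding_dim = 256L,
                           seed = 1L) {
  backbone <- match.arg(backbone)
  stop_if_not_scalar_count(input_size, "input_size")
  stop_if_not_scalar_count(embedding_dim, "embedding_dim")
  if (embedding_dim < 2) stop("`embedding_dim` must be at least 2")
  if (length(srab_filters) != 2L || any(srab_filters < 1))
    stop("`srab_filters` must be two positive integers")
  structure(list(
    backbone = backbone,
    input_size = as.integer(input_size),
    input_channels = as.integer(input_channels),
    backbone_pretrained = isTRUE(backbone_pretrained),
    weights_file = weights_file,
    srab_filters = as.integer(srab_filters),
    reverse_filters = as.integer(reverse_filters),
    complement_gate = isTRUE(complement_gate),
    head_hidden_units = as.integer(head_hidden_units),
    embedding_dim = as.integer(embedding_dim),
    seed = as.integer(seed)
  ), class = "network_config")
}

#' Small-network configuration for CPU-scale experiments
#'
#' A convenience preset: tiny backbone, 64x64 inputs and narrow attention
#' blocks and head. All arguments of [network_config()] can be overridden.
#'
#' @param ... overrides passed to [network_config()].
#' @export
tiny_network_config <- function(...) {
  defaults <- list(backbone = "tiny", input_size = 64L,
                   srab_filters = c(32L, 32L), reverse_filters = 32L,
                   head_hidden_units = 64L, embedding_dim = 32L)
  args <- utils::modifyList(defaults, list(...))
  do.call(network_config, args)
}

#' Build the embedding generator
#'
#' Assembles backbone, the two self-residual attention blocks, the attention
#' block, the reverse attention block and the dense head into one model that
#' maps an `input_size x input_size x input_channels` image (or a batch) to a
#' length-`embedding_dim` vector. Parameter initialisation is fully
#' determined by `cfg$seed`.
#'
#' @param cfg a [network_config()].
#' @return an object of class `sran_model`; use [embed_images()] or
#'   `predict()` to compute embeddings.
#' @export
build_embedding_generator <- function(cfg) {
  if (!inherits(cfg, "network_config")) stop("`cfg` must be a network_config")
  model <- withr::with_seed(cfg$seed, {
    bb <- switch(cfg$backbone,
      resnet50 = build_resnet50_backbone(cfg$input_channels),
      tiny = build_tiny_backbone(cfg$input_channels)
    )
    if (cfg$input_size < bb$min_input) {
      stop(sprintf("backbone '%s' needs inputs of at least %d pixels",
                   cfg$backbone, bb$min_input))
    }
    f <- cfg$srab_filters
    layers <- c(bb$layers, list(
      srab_layer(bb$c_out, f[1]),
      srab_layer(f[1], f[2]),
      attention_block_layer(f[2]),
      reverse_att_layer(f[2], cfg$reverse_filters,
                        complement_gate = cfg$complement_gate),
      flatten_layer()
    ))
    # spatial extent of the backbone output determines the flatten width
    down <- if (cfg$backbone == "resnet50") 32L else 8L
    side <- ceiling_div(cfg$input_size, down)
    flat_dim <- side * side * cfg$reverse_filters
    layers <- c(layers, list(
      dense_layer(flat_dim, cfg$head_hidden_units),
      activation_layer("softplus"),
      dense_layer(cfg$head_hidden_units, cfg$embedding_dim,
                  init_sd = sqrt(1 / cfg$head_hidden_units))
    ))
    e <- new.env(parent = emptyenv())
    e$net <- sequential_layer(layers)
    e$cfg <- cfg
    class(e) <- "sran_model"
    e
  })
  if (cfg$backbone_pretrained) {
    if (is.null(cfg$weights_file)) {
      stop("`backbone_pretrained = TRUE` requires `weights_file`; ",
           "no weights are bundled and none can be downloaded")
    }
    restore_model_state(model, readRDS(cfg$weights_file)$state)
  }
  model
}

ceiling_div <- function(a, b) as.integer(ceiling(a / b))

#' @export
print.sran_model <- function(x, ...) {
  n_par <- sum(vapply(walk_layers(x$net),
                      function(l) sum(vapply(l$params, length, numeric(1))),
                      numeric(1)))
  cat(sprintf("<sran_model> backbone=%s input=%dx%dx%d embedding_dim=%d parameters=%s\n",
              x$cfg$backbone, x$cfg$input_size, x$cfg$input_size,
              x$cfg$input_channels, x$cfg$embedding_dim,
              format(n_par, big.mark = ",")))
  invisible(x)
}

#' Compute embeddings for a batch of images
#'
#' @param model an `sran_model`.
#' @param x an `[H, W, C]` image, an `[H, W, C, N]` batch, or a list of
#'   images.
#' @param training logical; `TRUE` uses batch statistics in the
#'   normalisation layers (only meaningful inside the training loop).
#'   Embedding extraction uses inference mode.
#' @return an `N x embedding_dim` matrix (single images give a 1-row matrix).
#' @export
embed_images <- function(model, x, training = FALSE) {
  if (is.list(x)) {
    d1 <- dim(x[[1]])
    xb <- array(0, c(d1[1], d1[2], d1[3], length(x)))
    for (i in seq_along(x)) xb[, , , i] <- x[[i]]
    x <- xb
  } else {
    x <- as_batch(x)$x
  }
  layer_forward(model$net, x, training = training)$out
}

#' @param object an `sran_model`.
#' @param ... unused.
#' @rdname embed_images
#' @export
predict.sran_model <- function(object, x, ...) embed_images(object, x)

## ---- distance layer and triplet loss --------------------------------------

#' Euclidean distance between two embedding vectors
#'
#' @param a,b numeric vectors of equal length.
#' @return a nonnegative scalar, `sqrt(sum((a - b)^2))`.
#' @examples
#' euclidean_distance(c(0, 0), c(3, 4))  # 5
#' @export
euclidean_distance <- function(a, b) {
  if (length(a) != length(b)) {
    stop(sprintf("embedding lengths differ (%d vs %d)", length(a), length(b)))
  }
  sqrt(sum((a - b)^2))
}

#' Triplet hinge loss
#'
#' `max(0, d_ap - d_an + margin)`: zero once the anchor-negative distance
#' exceeds the anchor-positive distance by at least the margin. Vectorised
#' over `d_ap`/`d_an`.
#'
#' @param d_ap anchor-positive distance(s), nonnegative.
#' @param d_an anchor-negative distance(s), nonnegative.
#' @param margin positive margin hyperparameter (default 0.5).
#' @return nonnegative loss value(s).
#' @export
triplet_loss <- function(d_ap, d_an, margin = 0.5) {
  if (!is.numeric(margin) || length(margin) != 1L || margin <= 0) {
    stop("`margin` must be a single positive number")
  }
  if (any(d_ap < 0) || any(d_an < 0)) stop("distances must be nonnegative")
  pmax(0, d_ap - d_an + margin)
}

#' Build the three-branch Siamese triplet model
#'
#' All three branches share one embedding generator (a single parameter set
#' by construction); the wrapper adds the Euclidean distance layer producing
#' the anchor-positive and anchor-negative distances fed to [triplet_loss()].
#'
#' @param cfg a [network_config()], or an existing `sran_model` to wrap.
#' @return an object of class `siamese_model` with element `$embedder`.
#' @export
build_siamese_triplet_model <- function(cfg) {
  embedder <- if (inherits(cfg, "sran_model")) cfg else build_embedding_generator(cfg)
  structure(list(embedder = embedder), class = "siamese_model")
}

#' Distances produced by the Siamese triplet model
#'
#' @param model a `siamese_model` (or `sran_model`).
#' @param anchor,positive,negative images or image batches.
#' @return data frame with columns `d_ap` and `d_an`, one row per triplet.
#' @export
siamese_distances <- function(model, anchor, positive, negative) {
  emb <- if (inherits(model, "siamese_model")) model$embedder else model
  ea <- embed_images(emb, anchor)
  ep <- embed_images(emb, positive)
  en <- embed_images(emb, negative)
  data.frame(d_ap = sqrt(rowSums((ea - ep)^2)),
             d_an = sqrt(rowSums((ea - en)^2)))
}

## ---- serialization ---------------------------------------------------------

model_state <- function(model) {
  lapply(walk_layers(model$net), function(l) {
    list(params = l$params, buffers = l$buffers)
  })
}

restore_model_state <- function(model, state) {
  layers <- walk_layers(model$net)
  if (length(layers) != length(state)) {
    stop("saved state does not match the model architecture")
  }
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    for (nm in names(state[[i]]$params)) {
      if (!identical(dim(l$params[[nm]]) %||% length(l$params[[nm]]),
                     dim(state[[i]]$params[[nm]]) %||% length(state[[i]]$params[[nm]]))) {
        stop("saved parameter shapes do not match the model architecture")
      }
    }
    l$params <- state[[i]]$params
    if (!is.null(state[[i]]$buffers)) l$buffers <- state[[i]]$buffers
  }
  invisible(model)
}

#' Save / load a model archive
#'
#' The archive holds the network configuration plus every trainable
#' parameter and normalisation running statistic; a round trip reproduces
#' embeddings exactly.
#'
#' @param model an `sran_model` or `siamese_model`.
#' @param path file path for the archive.
#' @export
save_model <- function(model, path) {
  if (inherits(model, "siamese_model")) model <- model$embedder
  saveRDS(list(cfg = model$cfg, state = model_state(model)), path)
  invisible(path)
}

#' @rdname save_model
#' @return `load_model()` returns the rebuilt `sran_model`.
#' @export
load_model <- function(path) {
  blob <- readRDS(path)
  cfg <- blob$cfg
  cfg$backbone_pretrained <- FALSE  # state is restored directly below
  model <- build_embedding_generator(cfg)
  restore_model_state(model, blob$state)
  model
}
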