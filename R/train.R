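# Triplet training of the Siamese embedding generator.
#
# Every batch stacks the anchor, positive and negative images of its
# triplets into one forward pass through the shared embedding generator
# (so normalisation statistics see all three branches), computes the
# Euclidean distance pairs, the hinge triplet loss, and backpropagates
# through the whole network. Optimisation uses Adam.

adam_step <- function(layers, lr, t, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (l in layers) {
    if (is.null(l$grads)) next
    if (is.null(l$opt)) {
      l$opt <- lapply(l$params, function(p) list(m = p * 0, v = p * 0))
    }
    for (nm in names(l$params)) {
      g <- l$grads[[nm]]
      st <- l$opt[[nm]]
      st$m <- beta1 * st$m + (1 - beta1) * g
      st$v <- beta2 * st$v + (1 - beta2) * g * g
      l$opt[[nm]] <- st
      mhat <- st$m / (1 - beta1^t)
      vhat <- st$v / (1 - beta2^t)
      l$params[[nm]] <- l$params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
    }
    l$grads <- NULL
  }
  invisible(NULL)
}

# Resolve image references of a triplet table into one [H, W, C, 3B] batch:
# anchors first, then positives, then negatives.
stack_triplet_batch <- function(triplets, provider) {
  refs <- c(triplets$anchor, triplets$positive, triplets$negative)
  imgs <- lapply(refs, provider)
  d1 <- dim(imgs[[1]])
  x <- array(0, c(d1[1], d1[2], d1[3], length(imgs)))
  for (i in seq_along(imgs)) x[, , , i] <- imgs[[i]]
  x
}

make_image_provider <- function(images, size) {
  if (is.function(images)) return(images)
  if (is.list(images)) {
    if (is.null(names(images))) stop("`images` list must be named by image reference")
    return(function(ref) images[[ref]])
  }
  # otherwise treat references as file paths
  function(ref) preprocess_image(ref, size = size)
}

#' Train the Siamese triplet model
#'
#' @param model a `siamese_model` or `sran_model`; updated in place.
#' @param triplets data frame with columns `anchor`, `positive`, `negative`
#'   (image references), e.g. from [sample_triplets()].
#' @param images how to resolve image references: a named list of
#'   `[H, W, C]` arrays, a `function(ref)` returning such an array, or
#'   `NULL` to treat references as PNG file paths.
#' @param epochs number of passes over the triplet list.
#' @param batch_size triplets per optimisation step (default 16).
#' @param lr Adam learning rate (default 1e-4).
#' @param margin triplet-loss margin (default 0.5).
#' @param seed integer seed governing shuffling (and any resampling).
#' @param resample_each_epoch logical; draw a fresh triplet list every epoch
#'   from `index` instead of reusing the fixed list.
#' @param index a patient index, required when `resample_each_epoch = TRUE`.
#' @param verbose print per-epoch mean loss.
#' @return list with elements `model` and `history` (data frame
#'   `epoch`, `mean_loss`).
#' @export
train_triplet_model <- function(model, triplets, images = NULL,
                                epochs = 10L, batch_size = 16L, lr = 1e-4,
                                margin = 0.5, seed = 1L,
                                resample_each_epoch = FALSE, index = NULL,
                                verbose = FALSE) {
  emb <- if (inherits(model, "siamese_model")) model$embedder else model
  if (!inherits(emb, "sran_model")) stop("`model` must be a siamese_model or sran_model")
  if (is.null(triplets) || nrow(triplets) == 0L) stop("empty triplet stream")
  if (resample_each_epoch && is.null(index)) {
    stop("`index` is required when `resample_each_epoch = TRUE`")
  }
  provider <- make_image_provider(images, emb$cfg$input_size)
  layers <- walk_layers(emb$net)
  history <- numeric(epochs)
  step_t <- 0L
  withr::with_seed(seed, {
    for (ep in seq_len(epochs)) {
      tri <- if (resample_each_epoch && ep > 1L) {
        sample_triplets(index, nrow(triplets), seed = sample.int(2^30, 1L))
      } else {
        triplets
      }
      ord <- sample.int(nrow(tri))
      losses <- numeric(0)
      for (start in seq(1L, nrow(tri), by = batch_size)) {
        batch <- tri[ord[start:min(start + batch_size - 1L, nrow(tri))], , drop = FALSE]
        B <- nrow(batch)
        x <- stack_triplet_batch(batch, provider)
        fw <- layer_forward(emb$net, x, training = TRUE)
        E <- fw$out                                   # 3B x D
        ia <- seq_len(B); ip <- B + ia; in_ <- 2L * B + ia
        dap_v <- sqrt(rowSums((E[ia, , drop = FALSE] - E[ip, , drop = FALSE])^2))
        dan_v <- sqrt(rowSums((E[ia, , drop = FALSE] - E[in_, , drop = FALSE])^2))
        li <- triplet_loss(dap_v, dan_v, margin)
        loss <- mean(li)
        if (!is.finite(loss)) {
          stop(sprintf("non-finite triplet loss at epoch %d (d_ap range %.3g-%.3g)",
                       ep, min(dap_v), max(dap_v)))
        }
        losses <- c(losses, loss)
        active <- as.numeric(li > 0) / B
        uap <- (E[ia, , drop = FALSE] - E[ip, , drop = FALSE]) / pmax(dap_v, 1e-12)
        uan <- (E[ia, , drop = FALSE] - E[in_, , drop = FALSE]) / pmax(dan_v, 1e-12)
        dE <- matrix(0, nrow(E), ncol(E))
        dE[ia, ] <- active * (uap - uan)
        dE[ip, ] <- -active * uap
        dE[in_, ] <- active * uan
        layer_backward(emb$net, dE, fw$cache)
        step_t <- step_t + 1L
        adam_step(layers, lr, step_t)
      }
      history[ep] <- mean(losses)
      if (verbose) {
        message(sprintf("epoch %d/%d mean triplet loss %.5f", ep, epochs, history[ep]))
      }
    }
  })
  list(model = model, history = data.frame(epoch = seq_len(epochs), mean_loss = history))
}

#' Write a per-epoch loss history to CSV
#'
#' @param history data frame from [train_triplet_model()].
#' @param path output CSV path.
#' @export
write_loss_history <- function(history, path) {
  utils::write.csv(history, path, row.names = FALSE)
  invisible(path)
}
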