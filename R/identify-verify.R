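# Testing-phase pipeline: embedding galleries, one-to-many identification,
# one-to-one verification, threshold calibration and evaluation reports.
#
# New individuals never require retraining: their images are embedded once
# and appended to the gallery; queries are answered by nearest-neighbour
# search in embedding space.

#' Construct an embedding store
#'
#' @param image_ids character vector of unique image identifiers.
#' @param patient_ids character vector of patient identifiers, same length.
#' @param embeddings numeric matrix, one row per image.
#' @return an `embedding_store`: list with `meta` (data frame) and `emb`.
#' @export
embedding_store <- function(image_ids, patient_ids, embeddings) {
  image_ids <- as.character(image_ids)
  patient_ids <- as.character(patient_ids)
  if (anyDuplicated(image_ids)) stop("image_ids must be unique")
  embeddings <- as.matrix(embeddings)
  if (nrow(embeddings) != length(image_ids) ||
      length(patient_ids) != length(image_ids)) {
    stop("image_ids, patient_ids and embedding rows must align")
  }
  if (!all(is.finite(embeddings))) stop("embeddings must be finite")
  rownames(embeddings) <- image_ids
  structure(list(meta = data.frame(image_id = image_ids,
                                   patient_id = patient_ids,
                                   stringsAsFactors = FALSE),
                 emb = embeddings,
                 embedding_dim = ncol(embeddings)),
            class = "embedding_store")
}

#' @export
print.embedding_store <- function(x, ...) {
  cat(sprintf("<embedding_store> %d images, %d patients, dim %d\n",
              nrow(x$meta), length(unique(x$meta$patient_id)), x$embedding_dim))
  invisible(x)
}

#' Embed every image of a patient index into a gallery store
#'
#' Images are processed in inference mode in fixed index order, so the
#' result is deterministic. Unreadable images are skipped with a warning and
#' counted in the `n_skipped` attribute.
#'
#' @param model an `sran_model` (or `siamese_model`).
#' @param index a [index_patients()] result (or any named list
#'   patient -> image references).
#' @param images reference resolver as in [train_triplet_model()]: named
#'   list of arrays, function, or `NULL` for file paths.
#' @param batch_size images per forward pass.
#' @return an [embedding_store()].
#' @export
embed_collection <- function(model, index, images = NULL, batch_size = 32L) {
  emb_model <- if (inherits(model, "siamese_model")) model$embedder else model
  provider <- make_image_provider(images, emb_model$cfg$input_size)
  image_ids <- unlist(index, use.names = FALSE)
  patient_ids <- rep(names(index), lengths(index))
  loaded <- vector("list", length(image_ids))
  ok <- logical(length(image_ids))
  for (i in seq_along(image_ids)) {
    loaded[[i]] <- tryCatch(provider(image_ids[i]), error = function(e) NULL)
    ok[i] <- !is.null(loaded[[i]])
    if (!ok[i]) warning(sprintf("skipping unreadable image '%s'", image_ids[i]))
  }
  n_skipped <- sum(!ok)
  loaded <- loaded[ok]
  image_ids <- image_ids[ok]
  patient_ids <- patient_ids[ok]
  if (length(loaded) == 0L) stop("no readable images in the collection")
  out <- matrix(0, length(loaded), emb_model$cfg$embedding_dim)
  for (start in seq(1L, length(loaded), by = batch_size)) {
    sel <- start:min(start + batch_size - 1L, length(loaded))
    out[sel, ] <- embed_images(emb_model, loaded[sel])
  }
  store <- embedding_store(image_ids, patient_ids, out)
  attr(store, "n_skipped") <- n_skipped
  store
}

store_distances <- function(query, store) {
  if (length(query) != store$embedding_dim) {
    stop(sprintf("query length %d does not match store dimension %d",
                 length(query), store$embedding_dim))
  }
  sqrt(rowSums(sweep(store$emb, 2, query)^2))
}

#' Rank a gallery against a query embedding (top-k identification)
#'
#' Computes the Euclidean distance from the query to every stored embedding
#' and returns the `k` closest entries, distance ties broken
#' lexicographically by image id.
#'
#' @param query numeric embedding vector.
#' @param store an [embedding_store()].
#' @param k number of matches to return (default 5).
#' @return data frame `image_id`, `patient_id`, `distance` with
#'   nondecreasing distances.
#' @export
identify_topk <- function(query, store, k = 5L) {
  stop_if_not_scalar_count(k, "k")
  n <- nrow(store$meta)
  if (n == 0L) stop("embedding store is empty")
  if (k > n) {
    warning(sprintf("k = %d exceeds store size %d; returning all %d entries", k, n, n))
    k <- n
  }
  d <- store_distances(query, store)
  ord <- order(d, store$meta$image_id)[seq_len(k)]
  data.frame(image_id = store$meta$image_id[ord],
             patient_id = store$meta$patient_id[ord],
             distance = d[ord],
             stringsAsFactors = FALSE)
}

#' One-to-one verification decision
#'
#' Two images are declared the same person iff the Euclidean distance
#' between their embeddings falls below the threshold.
#'
#' @param a,b embedding vectors.
#' @param threshold positive decision threshold.
#' @return list with `distance`, `threshold`, `same_person`.
#' @export
verify_pair <- function(a, b, threshold) {
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold <= 0) {
    stop("`threshold` must be a single positive number")
  }
  d <- euclidean_distance(a, b)
  list(distance = d, threshold = threshold, same_person = d < threshold)
}

threshold_candidates <- function(d) {
  du <- sort(unique(d))
  if (length(du) == 1L) {
    lo <- if (du > 0) du / 2 else .Machine$double.eps
    return(c(lo, du + max(du, 1) * 0.5))
  }
  mids <- (du[-1] + du[-length(du)]) / 2
  lo <- if (du[1] > 0) du[1] / 2 else .Machine$double.eps
  c(lo, mids, du[length(du)] + (du[length(du)] - du[1]) / 2)
}

#' Calibrate the verification threshold on labelled pairs
#'
#' Sweeps the midpoints between consecutive observed distances (plus one
#' candidate below and above all of them) and returns the threshold
#' maximising pair-classification accuracy under the rule
#' `same <=> distance < threshold`; ties pick the smallest threshold. The
#' equal-error-rate operating point is reported alongside.
#'
#' @param pairs data frame with `image_a`, `image_b`, `same_patient`
#'   (logical), e.g. from [sample_labeled_pairs()]; alternatively columns
#'   `distance` and `same_patient`.
#' @param store an [embedding_store()] used to look up embeddings (not
#'   needed when `pairs` already carries distances).
#' @return list with `threshold`, `accuracy`, `eer_threshold`, `eer`.
#' @export
calibrate_threshold <- function(pairs, store = NULL) {
  same <- as.logical(pairs$same_patient)
  if (all(same) || !any(same)) {
    stop("calibration needs both same-patient and different-patient pairs")
  }
  if (!is.null(pairs$distance)) {
    d <- pairs$distance
  } else {
    if (is.null(store)) stop("`store` is required when pairs carry no distances")
    E <- store$emb
    d <- sqrt(rowSums((E[pairs$image_a, , drop = FALSE] -
                       E[pairs$image_b, , drop = FALSE])^2))
  }
  cand <- threshold_candidates(d)
  acc <- vapply(cand, function(t) mean((d < t) == same), numeric(1))
  best <- which.max(acc)  # which.max returns the first (smallest) maximiser
  far <- vapply(cand, function(t) mean(d[!same] < t), numeric(1))
  frr <- vapply(cand, function(t) mean(d[same] >= t), numeric(1))
  ieer <- which.min(abs(far - frr))
  list(threshold = cand[best], accuracy = acc[best],
       eer_threshold = cand[ieer], eer = (far[ieer] + frr[ieer]) / 2)
}

#' Binary classification metrics for verification decisions
#'
#' @param predicted,actual logical vectors (`TRUE` = same person).
#' @return list with `accuracy`, `precision`, `recall` and the confusion
#'   counts. Precision/recall are `NA` when undefined.
#' @export
pair_metrics <- function(predicted, actual) {
  tp <- sum(predicted & actual)
  fp <- sum(predicted & !actual)
  tn <- sum(!predicted & !actual)
  fn <- sum(!predicted & actual)
  list(accuracy = (tp + tn) / length(actual),
       precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
       recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       tp = tp, fp = fp, tn = tn, fn = fn)
}

#' Evaluation protocol settings
#'
#' @param k ranking depth for the hit rate (default 5).
#' @param n_pairs verification pairs to sample.
#' @param calib_fraction fraction of pairs used to calibrate the threshold;
#'   the rest are held out for the reported metrics.
#' @param seed integer seed for pair sampling and the split.
#' @export
reid_protocol <- function(k = 5L, n_pairs = 200L, calib_fraction = 0.5,
                          seed = 1L) {
  list(k = as.integer(k), n_pairs = as.integer(n_pairs),
       calib_fraction = calib_fraction, seed = as.integer(seed))
}

#' Evaluate identification and verification on an embedding store
#'
#' Identification: every image whose patient has at least one other image
#' serves as a query against the gallery of all other images (the query
#' itself is excluded); top-1 accuracy is the fraction whose nearest
#' neighbour shares the patient, and the top-k hit rate the fraction with a
#' same-patient image among the `k` nearest. Verification: labelled pairs
#' are sampled, the threshold is calibrated on one split and accuracy /
#' precision / recall are reported on the held-out split.
#'
#' @param store an [embedding_store()].
#' @param protocol a [reid_protocol()].
#' @return a `reid_report` list.
#' @export
evaluate_reid <- function(store, protocol = reid_protocol()) {
  meta <- store$meta
  counts <- table(meta$patient_id)
  queryable <- meta$patient_id %in% names(counts)[counts >= 2]
  if (!any(queryable)) {
    stop("no patient has 2+ images in the store; identification is undefined")
  }
  qidx <- which(queryable)
  top1 <- logical(length(qidx))
  topk <- logical(length(qidx))
  for (j in seq_along(qidx)) {
    i <- qidx[j]
    gallery <- embedding_store(meta$image_id[-i], meta$patient_id[-i],
                               store$emb[-i, , drop = FALSE])
    res <- identify_topk(store$emb[i, ], gallery, k = min(protocol$k, nrow(meta) - 1L))
    top1[j] <- res$patient_id[1] == meta$patient_id[i]
    topk[j] <- meta$patient_id[i] %in% res$patient_id
  }
  index <- split(meta$image_id, meta$patient_id)
  index <- index[vapply(index, length, integer(1)) >= 1L]
  class(index) <- "patient_index"
  pairs <- sample_labeled_pairs(index_patients(
    data.frame(`Image Index` = meta$image_id, `Patient ID` = meta$patient_id,
               check.names = FALSE)),
    protocol$n_pairs, seed = protocol$seed)
  n_cal <- max(2L, round(protocol$calib_fraction * nrow(pairs)))
  split_id <- withr::with_seed(protocol$seed + 1L, sample.int(nrow(pairs)))
  cal <- pairs[split_id[seq_len(n_cal)], ]
  held <- pairs[split_id[-seq_len(n_cal)], ]
  calib <- calibrate_threshold(cal, store)
  E <- store$emb
  dh <- sqrt(rowSums((E[held$image_a, , drop = FALSE] -
                      E[held$image_b, , drop = FALSE])^2))
  vm <- pair_metrics(dh < calib$threshold, held$same_patient)
  structure(list(
    top1_accuracy = mean(top1),
    top5_hit_rate = mean(topk),
    verification_accuracy = vm$accuracy,
    verification_precision = vm$precision,
    verification_recall = vm$recall,
    threshold = calib$threshold,
    calibration_accuracy = calib$accuracy,
    eer = calib$eer,
    n_queries = length(qidx),
    n_pairs = nrow(held)
  ), class = "reid_report")
}

#' @export
print.reid_report <- function(x, ...) {
  cat(sprintf(paste0(
    "Identification: top-1 %.3f, top-5 hit rate %.3f (%d queries)\n",
    "Verification:   accuracy %.3f, precision %.3f, recall %.3f ",
    "(threshold %.3f, %d held-out pairs)\n"),
    x$top1_accuracy, x$top5_hit_rate, x$n_queries,
    x$verification_accuracy, x$verification_precision, x$verification_recall,
    x$threshold, x$n_pairs))
  invisible(x)
}

## ---- persistence -----------------------------------------------------------

#' Persist / reload an embedding store as CSV
#'
#' Writes two plain-text files: `<prefix>_manifest.csv` (image and patient
#' ids) and `<prefix>_embeddings.csv` (one row per image). The round trip
#' preserves pairwise distances to full printed precision.
#'
#' @param store an [embedding_store()].
#' @param prefix file path prefix.
#' @export
write_embedding_store <- function(store, prefix) {
  utils::write.csv(store$meta, paste0(prefix, "_manifest.csv"), row.names = FALSE)
  emb <- as.data.frame(store$emb)
  names(emb) <- sprintf("e%03d", seq_len(ncol(emb)))
  utils::write.csv(cbind(image_id = store$meta$image_id, emb),
                   paste0(prefix, "_embeddings.csv"), row.names = FALSE)
  invisible(prefix)
}

#' @rdname write_embedding_store
#' @return `read_embedding_store()` returns the reloaded store.
#' @export
read_embedding_store <- function(prefix) {
  meta <- utils::read.csv(paste0(prefix, "_manifest.csv"),
                          colClasses = "character")
  emb <- utils::read.csv(paste0(prefix, "_embeddings.csv"), check.names = FALSE)
  stopifnot(identical(meta$image_id, as.character(emb$image_id)))
  embedding_store(meta$image_id, meta$patient_id,
                  as.matrix(emb[, -1, drop = FALSE]))
}

#' Write an evaluation report to JSON
#' @param report a `reid_report`.
#' @param path output path.
#' @export
write_reid_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
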