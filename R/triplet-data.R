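# Patient indexing, triplet sampling and image preprocessing.

#' Index images by patient, keeping patients with enough samples
#'
#' Builds the patient -> images mapping used for triplet sampling and
#' gallery construction. Patients with fewer than `min_images` distinct
#' images are excluded (a positive pair cannot be formed for them).
#'
#' @param metadata data frame holding an image-name column and a patient-ID
#'   column (NIH naming by default: `Image Index`, `Patient ID`).
#' @param image_col,patient_col column names; override for other metadata
#'   dialects.
#' @param min_images minimum images per retained patient (default 2).
#' @return a named list of character vectors (class `patient_index`),
#'   patients sorted by ID, images in first-appearance order.
#' @export
index_patients <- function(metadata, image_col = "Image Index",
                           patient_col = "Patient ID", min_images = 2L) {
  if (!is.data.frame(metadata)) stop("`metadata` must be a data frame")
  missing_cols <- setdiff(c(image_col, patient_col), names(metadata))
  if (length(missing_cols)) {
    stop(sprintf("metadata is missing column(s): %s",
                 paste(sprintf("'%s'", missing_cols), collapse = ", ")))
  }
  img <- as.character(metadata[[image_col]])
  pid <- as.character(metadata[[patient_col]])
  keep <- !duplicated(img)
  img <- img[keep]; pid <- pid[keep]
  idx <- split(img, pid)
  idx <- idx[vapply(idx, length, integer(1)) >= min_images]
  idx <- idx[order(names(idx))]
  if (length(idx) == 0L) {
    warning(sprintf("no patient has at least %d images; index is empty", min_images))
  }
  structure(idx, class = "patient_index")
}

#' @export
print.patient_index <- function(x, ...) {
  cat(sprintf("<patient_index> %d patients, %d images\n",
              length(x), sum(lengths(x))))
  invisible(x)
}

#' Sample anchor/positive/negative training triplets
#'
#' Patients are cycled so each contributes one anchor per pass; the anchor
#' is drawn at random from the patient's images, the positive uniformly from
#' the patient's remaining images, and the negative uniformly from another
#' patient's images. Fully reproducible from `seed`.
#'
#' @param index a [index_patients()] result with at least 2 patients.
#' @param n number of triplets.
#' @param seed integer seed.
#' @return data frame with columns `anchor`, `positive`, `negative`,
#'   `anchor_patient`, `negative_patient`.
#' @export
sample_triplets <- function(index, n, seed = 1L) {
  stop_if_not_scalar_count(n, "n")
  if (length(index) < 2L) {
    stop("triplet sampling needs at least 2 patients (no negative exists otherwise)")
  }
  pats <- names(index)
  withr::with_seed(seed, {
    anchor <- positive <- negative <- anchor_patient <- negative_patient <-
      character(n)
    k <- 0L
    while (k < n) {
      for (p in pats[sample.int(length(pats))]) {
        if (k >= n) break
        k <- k + 1L
        imgs <- index[[p]]
        a <- resample(imgs)
        pos <- resample(setdiff(imgs, a))
        np <- resample(setdiff(pats, p))
        anchor[k] <- a
        positive[k] <- pos
        negative[k] <- resample(index[[np]])
        anchor_patient[k] <- p
        negative_patient[k] <- np
      }
    }
  })
  data.frame(anchor = anchor, positive = positive, negative = negative,
             anchor_patient = anchor_patient, negative_patient = negative_patient,
             stringsAsFactors = FALSE)
}

#' Sample labelled image pairs for verification
#'
#' Draws `n` pairs, half positive (two distinct images of one patient) and
#' half negative (images of two different patients), reproducibly from
#' `seed`.
#'
#' @inheritParams sample_triplets
#' @return data frame with columns `image_a`, `image_b`, `same_patient`.
#' @export
sample_labeled_pairs <- function(index, n, seed = 1L) {
  stop_if_not_scalar_count(n, "n")
  if (length(index) < 2L) stop("pair sampling needs at least 2 patients")
  pats <- names(index)
  n_pos <- n %/% 2L
  withr::with_seed(seed, {
    image_a <- image_b <- character(n)
    same <- logical(n)
    for (k in seq_len(n)) {
      if (k <= n_pos) {
        p <- resample(pats)
        pick <- resample(index[[p]], 2L)
        image_a[k] <- pick[1]; image_b[k] <- pick[2]; same[k] <- TRUE
      } else {
        pq <- resample(pats, 2L)
        image_a[k] <- resample(index[[pq[1]]])
        image_b[k] <- resample(index[[pq[2]]])
        same[k] <- FALSE
      }
    }
  })
  data.frame(image_a = image_a, image_b = image_b, same_patient = same,
             stringsAsFactors = FALSE)
}

#' Write a triplet manifest CSV for audit
#' @param triplets data frame from [sample_triplets()].
#' @param path output CSV path.
#' @export
write_triplet_manifest <- function(triplets, path) {
  utils::write.csv(triplets, path, row.names = FALSE)
  invisible(path)
}

#' Load and standardise one image for the network
#'
#' Reads an 8-bit PNG (or accepts an in-memory array), converts to three
#' identical channels if grayscale, resizes to `size x size` with bilinear
#' interpolation (antialiased), and scales intensities to `[0, 1]`.
#'
#' @param ref a PNG file path, or a numeric matrix/array (`[H, W]` or
#'   `[H, W, C]`; values either already in `[0, 1]` or on the 0-255 scale).
#' @param size output side length (default 200).
#' @return an array `[size, size, 3]` with values in `[0, 1]`.
#' @export
preprocess_image <- function(ref, size = 200L) {
  stop_if_not_scalar_count(size, "size")
  if (is.character(ref)) {
    if (length(ref) != 1L || !file.exists(ref)) {
      stop(sprintf("image file not found: '%s'", paste(ref, collapse = ", ")))
    }
    x <- tryCatch(png::readPNG(ref),
                  error = function(e) stop(sprintf("cannot read PNG '%s': %s",
                                                   ref, conditionMessage(e)),
                                           call. = FALSE))
  } else if (is.numeric(ref)) {
    x <- ref
    if (max(x, na.rm = TRUE) > 1) x <- x / 255
  } else {
    stop("`ref` must be a file path or a numeric image array")
  }
  if (!all(is.finite(x))) stop("image contains non-finite values")
  d <- dim(x)
  if (length(d) == 3L && d[3] >= 3L) {
    x <- x[, , 1:3, drop = FALSE]            # drop alpha if present
  } else {
    gray <- if (length(d) == 2L) x else matrix(x[, , 1L], d[1], d[2])
    x <- array(rep(as.vector(gray), 3L), c(d[1], d[2], 3L))
  }
  d <- dim(x)
  if (d[1] != size || d[2] != size) {
    x <- EBImage::resize(x, w = size, h = size, filter = "bilinear",
                         antialias = TRUE)
  }
  clamp01(array(x, c(size, size, 3L)))
}
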