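# Patient indexing, triplet/pair sampling and image preprocessing.

meta_fixture <- function(counts) {
  imgs <- unlist(lapply(seq_along(counts), function(i) {
    sprintf("p%02d_%02d.png", i, seq_len(counts[i]))
  }))
  data.frame(
    `Image Index` = as.character(imgs %||% character(0)),
    `Patient ID` = rep(sprintf("p%02d", seq_along(counts)), counts),
    check.names = FALSE, stringsAsFactors = FALSE
  )
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("patient indexing keeps exactly the patients with enough images", {
  idx <- index_patients(meta_fixture(c(3, 1, 2)))
  expect_length(idx, 2L)
  expect_equal(sort(unname(lengths(idx))), c(2L, 3L))
  expect_false("p02" %in% names(idx))

  expect_warning(idx0 <- index_patients(meta_fixture(integer(0))), "no patient")
  expect_length(idx0, 0L)

  expect_error(index_patients(data.frame(a = 1)), "missing column")

  # duplicated image references are dropped before counting
  meta <- meta_fixture(c(2, 2))
  meta <- rbind(meta, meta[1, ])
  idx2 <- index_patients(meta)
  expect_equal(unname(lengths(idx2)), c(2L, 2L))

  # bookkeeping against the synthetic generator's ground truth
  ds <- generate_dataset(4, 3, size = 16, seed = 5)
  idx3 <- index_patients(ds$metadata)
  expect_length(idx3, 4L)
  expect_true(all(lengths(idx3) == 3L))
})

test_that("sampled triplets always satisfy the patient constraints", {
  idx <- index_patients(meta_fixture(c(3, 2, 4, 2)))
  tri <- sample_triplets(idx, 1000, seed = 9)
  expect_equal(nrow(tri), 1000L)
  expect_true(all(tri$anchor != tri$positive))
  expect_true(all(tri$anchor_patient != tri$negative_patient))
  # anchor and positive really share the anchor patient
  ref_pat <- function(img) sub("_.*", "", img)
  expect_true(all(ref_pat(tri$anchor) == tri$anchor_patient))
  expect_true(all(ref_pat(tri$positive) == tri$anchor_patient))
  expect_true(all(ref_pat(tri$negative) == tri$negative_patient))

  expect_identical(sample_triplets(idx, 50, seed = 4),
                   sample_triplets(idx, 50, seed = 4))

  single <- index_patients(meta_fixture(c(3)))
  expect_error(sample_triplets(single, 5), "at least 2 patients")
})

test_that("labelled pairs are balanced and correctly labelled", {
  idx <- index_patients(meta_fixture(c(3, 2, 4)))
  pr <- sample_labeled_pairs(idx, 100, seed = 2)
  ref_pat <- function(img) sub("_.*", "", img)
  expect_equal(sum(pr$same_patient), 50L)
  expect_true(all((ref_pat(pr$image_a) == ref_pat(pr$image_b)) == pr$same_patient))
  expect_true(all(pr$image_a != pr$image_b | !pr$same_patient))
})

test_that("preprocessing standardises size, channels and intensity range", {
  # grayscale PNG on disk -> 200 x 200 x 3 with identical planes
  img <- withr::with_seed(3, matrix(runif(256 * 256), 256, 256))
  path <- withr::local_tempfile(fileext = ".png")
  png::writePNG(img, path)
  out <- preprocess_image(path, size = 200)
  expect_equal(dim(out), c(200L, 200L, 3L))
  expect_identical(out[, , 1], out[, , 2])
  expect_identical(out[, , 1], out[, , 3])
  expect_true(min(out) >= 0 && max(out) <= 1)

  # constant 8-bit white maps to 1.0
  out255 <- preprocess_image(matrix(255, 64, 64), size = 32)
  expect_equal(as.vector(out255), rep(1, length(out255)))

  # in-memory [0,1] arrays pass through with range preserved
  out2 <- preprocess_image(withr::with_seed(4, array(runif(50 * 40 * 3), c(50, 40, 3))),
                           size = 24)
  expect_true(min(out2) >= 0 && max(out2) <= 1)

  # unreadable file
  bad <- withr::local_tempfile(fileext = ".png")
  writeLines("not a png", bad)
  expect_error(preprocess_image(bad), "cannot read PNG")
  expect_error(preprocess_image("no/such/file.png"), "not found")
})

test_that("the training stream is replayable bit-exactly from one seed", {
  co <- make_cohort(n_identities = 3, images_per_identity = 2, size = 16,
                    seed = 7)
  t1 <- sample_triplets(co$index, 10, seed = 42)
  t2 <- sample_triplets(co$index, 10, seed = 42)
  expect_identical(t1, t2)
  x1 <- sranet:::stack_triplet_batch(t1, co$provider)
  x2 <- sranet:::stack_triplet_batch(t2, co$provider)
  expect_identical(x1, x2)
})
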