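# Gallery embedding, top-k identification, verification and evaluation.

tiny_model_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- build_embedding_generator(
        tiny_network_config(input_size = 32, embedding_dim = 8, seed = 77))
    }
    cache
  }
})

test_that("embedding a collection is deterministic bookkeeping", {
  co <- make_cohort(n_identities = 3, images_per_identity = 2, size = 32,
                    seed = 41)
  m <- tiny_model_fixture()
  st <- embed_collection(m, co$index, images = co$provider)
  expect_s3_class(st, "embedding_store")
  expect_equal(nrow(st$meta), 6L)
  expect_equal(st$embedding_dim, 8L)

  st2 <- embed_collection(m, co$index, images = co$provider)
  expect_equal(st$emb, st2$emb, tolerance = 1e-6)

  # persistence round trip preserves pairwise distances
  prefix <- file.path(withr::local_tempdir(), "store")
  write_embedding_store(st, prefix)
  st3 <- read_embedding_store(prefix)
  d0 <- as.matrix(stats::dist(st$emb))
  d1 <- as.matrix(stats::dist(st3$emb))
  expect_equal(unname(d1), unname(d0), tolerance = 1e-6)

  # unreadable images are skipped with a warning
  bad_provider <- function(ref) {
    if (ref == names(co$ds$images)[1]) stop("corrupt") else co$provider(ref)
  }
  expect_warning(st4 <- embed_collection(m, co$index, images = bad_provider),
                 "skipping")
  expect_equal(nrow(st4$meta), 5L)
  expect_equal(attr(st4, "n_skipped"), 1L)
})

test_that("top-k identification equals a brute-force sort with tie rules", {
  withr::with_seed(51, {
    emb <- matrix(rnorm(100 * 8), 100, 8)
    ids <- sprintf("img%03d", 1:100)
    pats <- rep(sprintf("p%02d", 1:20), each = 5)
  })
  st <- embedding_store(ids, pats, emb)

  q <- emb[37, ]
  res <- identify_topk(q, st, k = 5)
  expect_equal(nrow(res), 5L)
  expect_equal(res$image_id[1], "img037")
  expect_equal(res$distance[1], 0)
  expect_true(all(diff(res$distance) >= 0))

  # brute-force equivalence on random queries
  withr::with_seed(52, {
    for (i in 1:10) {
      qq <- rnorm(8)
      d <- sqrt(colSums((t(emb) - qq)^2))
      ord <- order(d, ids)
      res <- identify_topk(qq, st, k = 7)
      expect_equal(res$image_id, ids[ord[1:7]])
      expect_equal(res$distance, d[ord[1:7]], tolerance = 1e-12)
    }
  })

  # ties break lexicographically by image id
  st_tie <- embedding_store(c("b", "a", "c"), c("x", "y", "z"),
                            matrix(c(1, 1, 5), 3, 1))
  res_tie <- identify_topk(0, st_tie, k = 2)
  expect_equal(res_tie$image_id, c("a", "b"))

  expect_warning(res_all <- identify_topk(0, st_tie, k = 5), "exceeds")
  expect_equal(nrow(res_all), 3L)
  expect_error(identify_topk(0, st_tie, k = 0), "positive integer")
})

test_that("verification decisions follow the threshold rule exactly", {
  a <- rnorm(8)
  expect_true(verify_pair(a, a, threshold = 0.1)$same_person)
  expect_false(verify_pair(c(0, 0), c(3, 4), threshold = 4)$same_person)
  expect_error(verify_pair(a, a, threshold = 0), "positive")

  withr::with_seed(53, {
    for (i in 1:50) {
      x <- rnorm(8); y <- rnorm(8); t <- runif(1, 0.1, 6)
      dec <- verify_pair(x, y, t)
      expect_identical(dec$same_person, sqrt(sum((x - y)^2)) < t)  # oracle
    }
  })
})

test_that("threshold calibration maximises sweep accuracy", {
  # separable: all positive distances below all negatives
  pairs <- data.frame(distance = c(0.2, 0.4, 2.1, 3.3),
                      same_patient = c(TRUE, TRUE, FALSE, FALSE))
  cal <- calibrate_threshold(pairs)
  expect_equal(cal$accuracy, 1)
  expect_gt(cal$threshold, 0.4)
  expect_lt(cal$threshold, 2.1)

  # degenerate: all distances equal -> majority label fraction
  deg <- data.frame(distance = rep(1, 5),
                    same_patient = c(TRUE, TRUE, TRUE, FALSE, FALSE))
  expect_equal(calibrate_threshold(deg)$accuracy, 0.6)

  expect_error(calibrate_threshold(data.frame(distance = 1, same_patient = TRUE)),
               "both")

  # random instances: equals the exhaustive sweep, and no swept threshold
  # beats the calibrated one
  withr::with_seed(54, {
    for (i in 1:20) {
      d <- runif(40, 0, 5)
      same <- runif(40) < 0.5
      if (all(same) || !any(same)) next
      cal <- calibrate_threshold(data.frame(distance = d, same_patient = same))
      sweep_acc <- vapply(c(d, d / 2, d + 1e-9, max(d) + 1),
                          function(t) mean((d < t) == same), numeric(1))
      expect_gte(cal$accuracy + 1e-12, max(sweep_acc))
      expect_equal(cal$accuracy, mean((d < cal$threshold) == same))
    }
  })
})

test_that("verification metrics match hand counts", {
  # TP, FP, TN, FN one each
  m <- pair_metrics(predicted = c(TRUE, TRUE, FALSE, FALSE),
                    actual = c(TRUE, FALSE, FALSE, TRUE))
  expect_equal(m$accuracy, 0.5)
  expect_equal(m$precision, 0.5)
  expect_equal(m$recall, 0.5)
  expect_equal(c(m$tp, m$fp, m$tn, m$fn), c(1, 1, 1, 1))
})

test_that("evaluation reports a perfect score on a constructed optimum", {
  # 4 patients x 2 images in tight, well-separated clusters
  centers <- matrix(c(0, 0, 10, 0, 0, 10, 10, 10), 4, 2, byrow = TRUE)
  emb <- centers[rep(1:4, each = 2), ] + 0.01 * matrix(seq_len(16), 8, 2)
  st <- embedding_store(sprintf("i%02d", 1:8), rep(sprintf("p%d", 1:4), each = 2),
                        emb)
  rep <- evaluate_reid(st, reid_protocol(n_pairs = 40, seed = 3))
  expect_equal(rep$top1_accuracy, 1)
  expect_equal(rep$top5_hit_rate, 1)
  expect_equal(rep$verification_accuracy, 1)
  expect_true(all(unlist(rep[c("top1_accuracy", "top5_hit_rate",
                               "verification_accuracy")]) <= 1))

  # a store with only singleton patients cannot be evaluated
  st1 <- embedding_store(c("a", "b"), c("p1", "p2"), matrix(rnorm(4), 2, 2))
  expect_error(evaluate_reid(st1), "2\\+ images")
})
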