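# Embedding generator, distance layer, triplet loss, Siamese wrapper and
# training behaviour (all on the CPU-scale tiny backbone).

test_that("euclidean distance is the root of summed squared differences", {
  expect_equal(euclidean_distance(c(0, 0), c(3, 4)), 5)
  x <- rnorm(10)
  expect_equal(euclidean_distance(x, x), 0)

  a <- withr::with_seed(1, rnorm(256))
  b <- withr::with_seed(2, rnorm(256))
  s <- 0
  for (i in seq_along(a)) s <- s + (a[i] - b[i])^2  # loop-sum oracle
  expect_equal(euclidean_distance(a, b), sqrt(s), tolerance = 1e-6)

  expect_error(euclidean_distance(1:3, 1:4), "lengths differ")
})

test_that("euclidean distance satisfies the metric axioms", {
  withr::with_seed(5, {
    for (i in 1:50) {
      a <- rnorm(16); b <- rnorm(16); c <- rnorm(16)
      dab <- euclidean_distance(a, b)
      dba <- euclidean_distance(b, a)
      expect_gte(dab, 0)
      expect_equal(dab, dba)
      expect_lte(euclidean_distance(a, c), dab + euclidean_distance(b, c) + 1e-12)
    }
  })
})

test_that("triplet loss implements the hinge with margin", {
  expect_equal(triplet_loss(2, 1, margin = 0.5), 1.5)
  expect_equal(triplet_loss(1, 3, margin = 0.5), 0)
  for (m in c(0.1, 0.5, 2)) {
    expect_equal(triplet_loss(1.3, 1.3, margin = m), m)  # equal distances
  }
  expect_error(triplet_loss(1, 1, margin = -1), "positive")
  expect_error(triplet_loss(-1, 1), "nonnegative")
})

test_that("embedding generator respects its configuration", {
  cfg <- tiny_network_config(seed = 3)
  m <- build_embedding_generator(cfg)
  x <- withr::with_seed(4, array(runif(64 * 64 * 3), c(64, 64, 3)))
  e1 <- embed_images(m, x)
  expect_equal(dim(e1), c(1L, 32L))
  expect_true(all(is.finite(e1)))

  # inference mode is deterministic
  expect_identical(e1, embed_images(m, x))

  # config propagation
  cfg2 <- tiny_network_config(input_size = 32, embedding_dim = 8, seed = 3)
  m2 <- build_embedding_generator(cfg2)
  x2 <- withr::with_seed(4, array(runif(32 * 32 * 3), c(32, 32, 3)))
  expect_equal(ncol(embed_images(m2, x2)), 8L)

  expect_error(network_config(backbone = "vgg"), "arg")
  expect_error(build_embedding_generator(
    network_config(backbone = "resnet50", input_size = 16)), "at least")
})

test_that("the Siamese wrapper shares one embedding generator", {
  cfg <- tiny_network_config(input_size = 32, embedding_dim = 8, seed = 6)
  sm <- build_siamese_triplet_model(cfg)
  a <- withr::with_seed(7, array(runif(32 * 32 * 3), c(32, 32, 3)))
  n <- withr::with_seed(8, array(runif(32 * 32 * 3), c(32, 32, 3)))

  d <- siamese_distances(sm, a, a, n)
  expect_equal(d$d_ap, 0)
  expect_gt(d$d_an, 0)

  # compositional oracle: wrapper distances == embed + euclidean_distance
  ea <- drop(embed_images(sm$embedder, a))
  en <- drop(embed_images(sm$embedder, n))
  expect_equal(d$d_an, euclidean_distance(ea, en), tolerance = 1e-10)

  # the branches are literally one parameter set
  expect_true(is.environment(sm$embedder))
})

test_that("triplet training reduces the loss and is seed-reproducible", {
  co <- make_cohort(n_identities = 5, images_per_identity = 3, size = 32,
                    seed = 21)
  cfg <- tiny_network_config(input_size = 32, embedding_dim = 8, seed = 22)
  tri <- sample_triplets(co$index, 30, seed = 23)

  m1 <- build_embedding_generator(cfg)
  fit1 <- train_triplet_model(m1, tri, co$provider, epochs = 2, lr = 1e-3,
                              seed = 24)
  expect_equal(nrow(fit1$history), 2L)
  expect_lt(fit1$history$mean_loss[2], fit1$history$mean_loss[1])

  m2 <- build_embedding_generator(cfg)
  fit2 <- train_triplet_model(m2, tri, co$provider, epochs = 2, lr = 1e-3,
                              seed = 24)
  expect_equal(fit1$history$mean_loss, fit2$history$mean_loss, tolerance = 1e-6)

  expect_error(train_triplet_model(m1, tri[0, ], co$provider), "empty")
})

test_that("model archives round-trip embeddings exactly", {
  cfg <- tiny_network_config(input_size = 32, embedding_dim = 8, seed = 31)
  m <- build_embedding_generator(cfg)
  x <- withr::with_seed(32, array(runif(32 * 32 * 3), c(32, 32, 3)))
  e0 <- embed_images(m, x)
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(m, path)
  m2 <- load_model(path)
  expect_equal(embed_images(m2, x), e0, tolerance = 1e-6)
})

test_that("requesting pretrained weights without a file is an error", {
  cfg <- tiny_network_config(seed = 1, backbone_pretrained = TRUE)
  expect_error(build_embedding_generator(cfg), "weights_file")
})
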