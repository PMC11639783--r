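# Attention operators: pooling statistics, gates, and the three blocks.

test_that("global pooling matches hand arithmetic and the loop oracle", {
  x <- array(c(1, 3, 5, 7), c(2, 2, 1))
  expect_equal(global_average_pool(x), 4)
  expect_equal(global_max_pool(x), 7)

  const <- array(2.5, c(3, 5, 4))
  expect_equal(global_average_pool(const), rep(2.5, 4))
  expect_equal(global_max_pool(const), rep(2.5, 4))

  r <- rand_map(4, 4, 3, seed = 101)
  expect_equal(global_average_pool(r), oracle_gap(r), tolerance = 1e-6)
  expect_identical(global_max_pool(r), oracle_gmp(r))

  expect_error(global_average_pool(numeric(0)), "array")
})

test_that("per channel, the max statistic dominates the mean statistic", {
  for (seed in 1:10) {
    r <- rand_map(5, 6, 4, seed = seed)
    gap <- global_average_pool(r)
    gmp <- global_max_pool(r)
    expect_true(all(gmp >= gap))
    expect_true(all(gmp > gap))  # random entries: no constant channel
  }
  const <- array(1.5, c(4, 4, 2))
  expect_equal(global_max_pool(const), global_average_pool(const))
})

test_that("channel attention gates and applies per-channel weights", {
  x <- rand_map(5, 5, 3, seed = 7)
  p <- channel_attention_params(3, seed = 1)

  zero_all_parameters(p)
  expect_equal(channel_attention_apply(x, p), 0.5 * x)

  p$params$b[] <- 20  # saturated gate
  expect_equal(channel_attention_apply(x, p), x, tolerance = 1e-6)

  p2 <- channel_attention_params(3, seed = 42)
  expect_equal(channel_attention_apply(x, p2), oracle_channel_attention(x, p2),
               tolerance = 1e-5)
  w <- channel_attention_weights(x, p2)
  expect_true(all(w > 0 & w < 1))

  expect_error(channel_attention_apply(rand_map(4, 4, 5, 1), p2), "channels")
})

test_that("spatial attention gates per location and broadcasts over channels", {
  x <- rand_map(6, 6, 4, seed = 9)
  p <- spatial_attention_params(seed = 2)

  zero_all_parameters(p)
  expect_equal(spatial_attention_apply(x, p), 0.5 * x)

  p2 <- spatial_attention_params(seed = 13)
  expect_equal(spatial_attention_apply(x, p2), oracle_spatial_attention(x, p2),
               tolerance = 1e-5)
  s <- spatial_attention_weights(x, p2)
  expect_equal(dim(s), c(6L, 6L))
  expect_true(all(s > 0 & s < 1))

  # C = 1: mean and max pooling across channels coincide with the channel
  x1 <- rand_map(5, 5, 1, seed = 3)
  expect_equal(spatial_attention_apply(x1, p2), oracle_spatial_attention(x1, p2),
               tolerance = 1e-5)
})

test_that("gating strictly shrinks nonzero entries", {
  x <- rand_map(5, 5, 3, seed = 21)
  pc <- channel_attention_params(3, seed = 4)
  ps <- spatial_attention_params(seed = 5)
  yc <- channel_attention_apply(x, pc)
  ys <- spatial_attention_apply(x, ps)
  nz <- x != 0
  expect_true(all(abs(yc[nz]) < abs(x[nz])))
  expect_true(all(abs(ys[nz]) < abs(x[nz])))
})

test_that("self-residual attention block propagates shape and residual", {
  x <- rand_map(8, 8, 4, seed = 31)
  p <- srab_params(4, 6, seed = 6)
  y <- srab_forward(x, p)
  expect_equal(dim(y), c(8L, 8L, 6L))

  # channel-preserving zero-parameter block: x plus a constant map
  p0 <- srab_params(4, 4, seed = 7)
  zero_all_parameters(p0)
  expect_equal(srab_forward(x, p0), x + 0.25 * log(2), tolerance = 1e-4)

  # seeded random block agrees with the straight-line reference
  p1 <- srab_params(4, 5, seed = 8)
  expect_equal(srab_forward(x, p1), oracle_srab(x, p1), tolerance = 1e-5)

  # deterministic in inference mode
  expect_identical(srab_forward(x, p1), srab_forward(x, p1))
})

test_that("attention block is two gates with no conv preamble and no residual", {
  x <- rand_map(8, 8, 4, seed = 41)
  p <- attention_block_params(4, seed = 9)

  zero_all_parameters(p)
  expect_equal(attention_block_forward(x, p), 0.25 * x)

  # saturate both gates -> output approaches the input
  p$ca$params$b[] <- 20
  p$sa$conv$params$b[] <- 20
  expect_equal(attention_block_forward(x, p), x, tolerance = 1e-6)

  p1 <- attention_block_params(4, seed = 10)
  expect_equal(attention_block_forward(x, p1), oracle_attention_block(x, p1),
               tolerance = 1e-5)
  expect_equal(dim(attention_block_forward(x, p1)), dim(x))
})

test_that("reverse attention block matches its reference and complement mode", {
  x <- rand_map(8, 8, 4, seed = 51)
  p0 <- reverse_attention_params(4, 4, seed = 11)
  zero_all_parameters(p0)
  y0 <- reverse_attention_forward(x, p0)
  expect_equal(as.vector(y0), rep(0.5 * log(2), length(y0)), tolerance = 1e-4)

  p1 <- reverse_attention_params(4, 3, seed = 12)
  expect_equal(dim(reverse_attention_forward(x, p1)), c(8L, 8L, 3L))
  expect_equal(reverse_attention_forward(x, p1), oracle_reverse_attention(x, p1),
               tolerance = 1e-5)

  pc <- reverse_attention_params(4, 3, complement_gate = TRUE, seed = 12)
  expect_equal(reverse_attention_forward(x, pc), oracle_reverse_attention(x, pc),
               tolerance = 1e-5)
  # complement mode gates with 1 - w: the two outputs sum to the ungated map
  ungated <- oracle_reverse_attention(x, p1) / rep(
    oracle_channel_gate(
      oracle_softplus(oracle_bn_inference(
        oracle_conv2d(x, p1$conv$params$W, p1$conv$params$b, p1$conv$k),
        p1$bn$params$gamma, p1$bn$params$beta,
        p1$bn$buffers$run_mean, p1$bn$buffers$run_var)),
      p1$ra$params$W, p1$ra$params$b),
    each = 64)
  expect_equal(reverse_attention_forward(x, p1) + reverse_attention_forward(x, pc),
               ungated, tolerance = 1e-5)
})
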