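# Independent straight-line / explicit-loop reference implementations of the
# attention arithmetic, used as oracles against the package's vectorised
# code. They share only the parameter *values* with the implementation,
# never its code paths.

rand_map <- function(H, W, C, seed) {
  withr::with_seed(seed, array(stats::rnorm(H * W * C), c(H, W, C)))
}

oracle_sigmoid <- function(z) 1 / (1 + exp(-z))
oracle_softplus <- function(z) log(1 + exp(z))

oracle_gap <- function(x) {
  d <- dim(x)
  out <- numeric(d[3])
  for (k in seq_len(d[3])) {
    s <- 0
    for (i in seq_len(d[1])) for (j in seq_len(d[2])) s <- s + x[i, j, k]
    out[k] <- s / (d[1] * d[2])
  }
  out
}

oracle_gmp <- function(x) {
  d <- dim(x)
  out <- numeric(d[3])
  for (k in seq_len(d[3])) {
    m <- -Inf
    for (i in seq_len(d[1])) for (j in seq_len(d[2])) m <- max(m, x[i, j, k])
    out[k] <- m
  }
  out
}

# weight layout of the package's conv: row index r = (c-1)*k^2 + (kj-1)*k + ki
oracle_conv2d <- function(x, W, b, k, stride = 1L, pad = (k - 1L) %/% 2L) {
  d <- dim(x)
  c_out <- ncol(W)
  Hout <- (d[1] + 2 * pad - k) %/% stride + 1L
  Wout <- (d[2] + 2 * pad - k) %/% stride + 1L
  y <- array(0, c(Hout, Wout, c_out))
  for (oi in seq_len(Hout)) for (oj in seq_len(Wout)) for (co in seq_len(c_out)) {
    s <- b[co]
    for (c in seq_len(d[3])) for (kj in seq_len(k)) for (ki in seq_len(k)) {
      i <- (oi - 1L) * stride + ki - pad
      j <- (oj - 1L) * stride + kj - pad
      if (i >= 1 && i <= d[1] && j >= 1 && j <= d[2]) {
        r <- (c - 1L) * k * k + (kj - 1L) * k + ki
        s <- s + x[i, j, c] * W[r, co]
      }
    }
    y[oi, oj, co] <- s
  }
  y
}

oracle_bn_inference <- function(x, gamma, beta, mean, var, eps = 1e-3) {
  d <- dim(x)
  y <- x
  for (k in seq_len(d[3])) {
    y[, , k] <- gamma[k] * (x[, , k] - mean[k]) / sqrt(var[k] + eps) + beta[k]
  }
  y
}

oracle_channel_gate <- function(x, W, b, complement = FALSE) {
  z <- c(oracle_gap(x), oracle_gmp(x))
  C <- length(b)
  w <- numeric(C)
  for (co in seq_len(C)) {
    s <- b[co]
    for (r in seq_along(z)) s <- s + W[r, co] * z[r]
    w[co] <- oracle_sigmoid(s)
  }
  if (complement) 1 - w else w
}

oracle_channel_attention <- function(x, p, complement = FALSE) {
  w <- oracle_channel_gate(x, p$params$W, p$params$b, complement)
  d <- dim(x)
  y <- x
  for (k in seq_len(d[3])) y[, , k] <- x[, , k] * w[k]
  y
}

oracle_spatial_attention <- function(x, p) {
  d <- dim(x)
  ap <- mp <- matrix(0, d[1], d[2])
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
    ap[i, j] <- mean(x[i, j, ])
    mp[i, j] <- max(x[i, j, ])
  }
  pooled <- array(0, c(d[1], d[2], 2))
  pooled[, , 1] <- ap
  pooled[, , 2] <- mp
  logits <- oracle_conv2d(pooled, p$conv$params$W, p$conv$params$b, p$conv$k)
  s <- oracle_sigmoid(logits[, , 1])
  y <- x
  for (k in seq_len(d[3])) y[, , k] <- x[, , k] * s
  y
}

oracle_srab <- function(x, p) {
  h <- oracle_conv2d(x, p$conv$params$W, p$conv$params$b, p$conv$k)
  h <- oracle_bn_inference(h, p$bn$params$gamma, p$bn$params$beta,
                           p$bn$buffers$run_mean, p$bn$buffers$run_var)
  h <- oracle_softplus(h)
  h <- oracle_channel_attention(h, p$ca)
  h <- oracle_spatial_attention(h, p$sa)
  res <- if (is.null(p$proj)) {
    x
  } else {
    oracle_conv2d(x, p$proj$params$W, p$proj$params$b, 1L)
  }
  h + res
}

oracle_attention_block <- function(x, p) {
  oracle_spatial_attention(oracle_channel_attention(x, p$ca), p$sa)
}

oracle_reverse_attention <- function(x, p) {
  h <- oracle_conv2d(x, p$conv$params$W, p$conv$params$b, p$conv$k)
  h <- oracle_bn_inference(h, p$bn$params$gamma, p$bn$params$beta,
                           p$bn$buffers$run_mean, p$bn$buffers$run_var)
  h <- oracle_softplus(h)
  oracle_channel_attention(h, p$ra, complement = p$complement_gate)
}

# Small in-memory synthetic cohort shared by pipeline tests.
make_cohort <- function(n_identities = 4L, images_per_identity = 3L,
                        size = 32L, seed = 11L) {
  ds <- generate_dataset(n_identities, images_per_identity, size = size,
                         seed = seed)
  provider <- function(ref) {
    img <- ds$images[[ref]]
    array(rep(as.vector(img), 3L), c(size, size, 3L))
  }
  list(ds = ds, index = index_patients(ds$metadata), provider = provider,
       size = size)
}
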