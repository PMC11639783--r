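#' @keywords internal
"_PACKAGE"

#' Numerically safe logistic sigmoid
#'
#' Logits are clamped to +/-30 before the logistic transform so gate weights
#' stay strictly inside (0, 1) in double precision (sigma(30) < 1 - 9e-14).
#' @param x numeric vector/array of logits.
#' @return values strictly in (0, 1), same shape as `x`.
#' @keywords internal
sigmoid <- function(x) {
  1 / (1 + exp(-pmin(pmax(x, -30), 30)))
}

#' Overflow-safe softplus, log(1 + exp(x))
#' @param x numeric vector/array.
#' @keywords internal
softplus <- function(x) {
  pmax(x, 0) + log1p(exp(-abs(x)))
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

`%||%` <- function(a, b) if (is.null(a)) b else a

# sample() treats a length-1 numeric as 1:n; this never does.
resample <- function(x, n = 1L) x[sample.int(length(x), n)]

stop_if_not_scalar_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 1 || x != floor(x)) {
    stop(sprintf("`%s` must be a single positive integer", name), call. = FALSE)
  }
}

#' Promote a feature map to batched [H, W, C, N] layout
#'
#' Activations are stored column-major as height x width x channels x batch.
#' A 2-d matrix is treated as a single-channel image, a 3-d array as a
#' single-sample batch.
#' @param x numeric array of 2, 3 or 4 dimensions.
#' @return list with the 4-d array and a flag saying whether a batch
#'   dimension was already present.
#' @keywords internal
as_batch <- function(x) {
  if (!is.numeric(x)) stop("feature map must be numeric", call. = FALSE)
  d <- dim(x)
  if (is.null(d) || length(d) < 2L || length(d) > 4L) {
    stop("feature map must be an array of shape [H, W], [H, W, C] or [H, W, C, N]",
         call. = FALSE)
  }
  if (any(d == 0L)) stop("feature map has an empty dimension", call. = FALSE)
  had_batch <- length(d) == 4L
  if (length(d) == 2L) dim(x) <- c(d, 1L, 1L)
  if (length(d) == 3L) dim(x) <- c(d, 1L)
  list(x = x, had_batch = had_batch)
}

drop_batch <- function(x, had_batch) {
  if (had_batch) return(x)
  array(x, dim(x)[1:3])
}

check_finite <- function(x, stage) {
  if (!all(is.finite(x))) {
    stop(sprintf("non-finite values produced at stage '%s'", stage), call. = FALSE)
  }
  invisible(x)
}
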