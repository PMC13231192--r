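#' @useDynLib attnmil, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm runif setNames predict
#' @importFrom utils head tail
NULL

#' Derive a named RNG sub-stream seed from a master seed
#'
#' A single experiment seed fans out into independent named sub-streams
#' (splitting, weight initialisation, per-epoch shuffling/augmentation, ...)
#' so that each stage is individually reproducible. The derivation is a
#' deterministic polynomial hash of the stream name folded into the master
#' seed, reduced modulo 2^31 - 2 so it is always a valid `set.seed()` value.
#'
#' @param seed integer master seed.
#' @param name character scalar naming the stream.
#' @return An integer seed.
#' @export
#' @examples
#' substream_seed(1, "split")
substream_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(name))
  m <- 2147483646  # 2^31 - 2
  s <- as.numeric(seed) %% m
  for (ch in utf8ToInt(name)) s <- (s * 31 + ch) %% m
  as.integer(s + 1)
}

with_stream <- function(seed, name, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(substream_seed(seed, name))
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  force(code)
}

# round() uses banker's rounding; splits need "ties away from zero"
round_half_up <- function(x) floor(x + 0.5)

#' Numerically stable softmax
#'
#' @param x numeric vector or matrix (softmax taken row-wise for matrices).
#' @return Same shape as `x`, rows/elements nonnegative and summing to 1.
#' @export
softmax <- function(x) {
  if (is.matrix(x)) {
    m <- apply(x, 1L, max)
    e <- exp(x - m)
    e / rowSums(e)
  } else {
    e <- exp(x - max(x))
    e / sum(e)
  }
}

# row-major (over H then W) flattening of a (H, W, C[, N]) array into a
# (H*W[*N]) x C matrix; position index p = (i-1)*W + j. Pinned by oracle tests.
flatten_hw <- function(x) {
  d <- dim(x)
  if (length(d) == 3L) {
    matrix(aperm(x, c(2L, 1L, 3L)), nrow = d[1L] * d[2L], ncol = d[3L])
  } else {
    matrix(aperm(x, c(2L, 1L, 4L, 3L)), nrow = d[1L] * d[2L] * d[4L], ncol = d[3L])
  }
}

# inverse of flatten_hw for a single instance
unflatten_hw <- function(m, H, W) {
  C <- ncol(m)
  aperm(array(m, dim = c(W, H, C)), c(2L, 1L, 3L))
}

# inverse of the batched flatten_hw: m is (H*W*N) x C -> (H, W, C, N)
unflatten_hw_batch <- function(m, H, W, N) {
  C <- ncol(m)
  aperm(array(m, dim = c(W, H, N, C)), c(2L, 1L, 4L, 3L))
}

# 2x2 average pooling on (H, W, C, N); exact equivalent of bilinear
# downsampling at scale 0.5 with the corner-excluding convention.
avgpool2 <- function(x) {
  d <- dim(x)
  H <- d[1L]; W <- d[2L]
  if (H %% 2L != 0L || W %% 2L != 0L)
    stop("spatial attention requires even feature-map sizes (H, W); got ",
         H, "x", W)
  io <- seq(1L, H, by = 2L); jo <- seq(1L, W, by = 2L)
  (x[io, jo, , , drop = FALSE] + x[io + 1L, jo, , , drop = FALSE] +
     x[io, jo + 1L, , , drop = FALSE] + x[io + 1L, jo + 1L, , , drop = FALSE]) / 4
}

# gradient of avgpool2: spread each output gradient over its 2x2 block
avgpool2_bwd <- function(dy, H, W) {
  d <- dim(dy)
  dx <- array(0, dim = c(H, W, d[3L], d[4L]))
  io <- seq(1L, H, by = 2L); jo <- seq(1L, W, by = 2L)
  g <- dy / 4
  dx[io, jo, , ] <- g; dx[io + 1L, jo, , ] <- g
  dx[io, jo + 1L, , ] <- g; dx[io + 1L, jo + 1L, , ] <- g
  dx
}

# recursive map over parallel nested lists of numeric leaves
nested_map2 <- function(x, y, f) {
  if (is.numeric(x)) return(f(x, y))
  out <- x
  for (nm in seq_along(x)) {
    if (is.null(x[[nm]])) next
    out[[nm]] <- nested_map2(x[[nm]], y[[nm]], f)
  }
  out
}

nested_zeros <- function(x) {
  if (is.numeric(x)) {
    z <- x; z[] <- 0; return(z)
  }
  lapply(x, function(e) if (is.null(e)) NULL else nested_zeros(e))
}

# sum all leaves of |x| (diagnostics / tests)
nested_abs_sum <- function(x) {
  if (is.numeric(x)) return(sum(abs(x)))
  sum(vapply(x, function(e) if (is.null(e)) 0 else nested_abs_sum(e), numeric(1)))
}
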