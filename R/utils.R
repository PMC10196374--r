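# Shared helpers: seeded RNG scoping, image normalization, small array ops.

#' Evaluate an expression under a local RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded package operations are
#' pure functions of their `(config, seed)` arguments and do not perturb the
#' caller's RNG stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

#' Derive a per-item seed from a master seed
#'
#' Mixes a master seed with an item index (and an optional stream id) through
#' a Lehmer-style congruential hash so datasets are extensible: sample `i` of
#' a run keeps its seed when `n` grows.
#'
#' @param master integer master seed.
#' @param index item index (1-based).
#' @param stream small integer separating independent uses (e.g. the corrupted
#'   and clean pools of an unpaired dataset).
#' @return an integer in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(master, index, stream = 0L) {
  m <- 2147483647
  h <- (as.double(master) %% m) * 48271 %% m
  h <- (h + as.double(index) * 1299721 + as.double(stream) * 7919) %% m
  as.integer(h %% (m - 2) + 1)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Convert between 8-bit and model intensity scales
#'
#' The package-wide normalization convention is `x_model = x_8bit / 127.5 - 1`
#' mapping `[0, 255]` onto `[-1, 1]` (and back, with clipping).
#'
#' @param img numeric array on the 8-bit `[0, 255]` scale (`to_model`) or the
#'   model `[-1, 1]` scale (`from_model`).
#' @return numeric array on the other scale.
#' @export
to_model <- function(img) img / 127.5 - 1

#' @rdname to_model
#' @export
from_model <- function(img) clamp((img + 1) * 127.5, 0, 255)

# stack two (H, W, C, N) batches along the channel axis
concat_channels <- function(a, b) {
  da <- dim(a); db <- dim(b)
  stopifnot(length(da) == 4L, all(da[c(1, 2, 4)] == db[c(1, 2, 4)]))
  out <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  out[, , seq_len(da[3]), ] <- a
  out[, , da[3] + seq_len(db[3]), ] <- b
  out
}

# promote a single (H, W, C) image to a batch of one
as_batch <- function(x) {
  d <- dim(x)
  if (length(d) == 3L) dim(x) <- c(d, 1L)
  else if (length(d) != 4L) stop("expected an (H, W, C) image or (H, W, C, N) batch")
  x
}

drop_batch <- function(x) {
  d <- dim(x)
  if (length(d) == 4L && d[4] == 1L) dim(x) <- d[1:3]
  x
}

check_image <- function(img, name = "image") {
  if (!is.numeric(img) || length(dim(img)) != 3L)
    stop(sprintf("%s must be a numeric (H, W, C) array", name), call. = FALSE)
  invisible(img)
}

check_same_shape <- function(a, b, what = "images") {
  if (!identical(dim(a), dim(b)))
    stop(sprintf("shape mismatch: %s have dims %s vs %s", what,
                 paste(dim(a), collapse = "x"), paste(dim(b), collapse = "x")),
         call. = FALSE)
  invisible(NULL)
}

#' Separable Gaussian blur of a matrix
#'
#' Reflect-padded separable Gaussian filtering, used to soften rendered
#' eyelash alpha maps and to build halos. `sigma = 0` returns the input.
#'
#' @param m numeric matrix.
#' @param sigma Gaussian standard deviation in pixels.
#' @return blurred matrix, same dimensions.
#' @export
gaussian_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  kk <- exp(-((-r:r)^2) / (2 * sigma^2))
  kk <- kk / sum(kk)
  blur_1d <- function(x) { # along rows of a matrix
    n <- nrow(x)
    idx <- c(rev(seq_len(r)), seq_len(n), n + 1 - seq_len(r)) # reflect
    xp <- x[clamp(idx, 1, n), , drop = FALSE]
    out <- matrix(0, n, ncol(x))
    for (i in seq_along(kk))
      out <- out + kk[i] * xp[(i - 1) + seq_len(n), , drop = FALSE]
    out
  }
  t(blur_1d(t(blur_1d(m))))
}

# lightweight structural checksum for change-detection in tests
param_checksum <- function(params) {
  sum(vapply(params, function(p) {
    v <- as.numeric(p)
    sum(v * (seq_along(v) %% 97 + 1))
  }, numeric(1)))
}
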