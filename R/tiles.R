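# Tiled inference for frames larger than one training patch: plan an
# overlapping tile grid, restore each tile through the network, and blend
# overlaps with linear feathering so no seams appear.

#' Plan an overlapping tile grid
#'
#' Tiles of side `tile_size` advance by `tile_size - overlap`; the last tile
#' origin along each axis clamps to the frame border so every pixel is
#' covered. A frame smaller than one tile yields a single clamped tile.
#'
#' @param height,width frame dimensions in pixels.
#' @param tile_size tile side length (default 1024, the training patch
#'   size).
#' @param overlap pixels shared by adjacent tiles (default 64).
#' @return tibble of class `tile_grid` with columns `row0`, `col0` (1-based
#'   origins), `height`, `width`.
#' @export
plan_tiles <- function(height, width, tile_size = 1024L, overlap = 64L) {
  if (overlap < 0 || tile_size <= overlap)
    stop("need tile_size > overlap >= 0", call. = FALSE)
  axis_origins <- function(extent) {
    th <- min(tile_size, extent)
    step <- tile_size - overlap
    o <- seq(1L, max(1L, extent - th + 1L), by = step)
    if (o[length(o)] + th - 1L < extent) o <- c(o, extent - th + 1L)
    o <- pmin(o, max(1L, extent - th + 1L))
    list(origins = unique(o), size = th)
  }
  rows <- axis_origins(height)
  cols <- axis_origins(width)
  grid <- expand.grid(row0 = rows$origins, col0 = cols$origins)
  out <- tibble::tibble(row0 = as.integer(grid$row0),
                        col0 = as.integer(grid$col0),
                        height = as.integer(rows$size),
                        width = as.integer(cols$size))
  class(out) <- c("tile_grid", class(out))
  out
}

# linear feathering weight for one axis: ramps over the overlap at interior
# edges, flat (1) at frame borders
feather_profile <- function(n, overlap, at_start_edge, at_end_edge) {
  w <- rep(1, n)
  r <- max(1L, overlap)
  if (!at_start_edge && overlap > 0)
    w[seq_len(r)] <- seq(1, r) / (r + 1)
  if (!at_end_edge && overlap > 0)
    w[n + 1 - seq_len(r)] <- seq(1, r) / (r + 1)
  w
}

#' Restore a whole frame through tiled inference
#'
#' Loads an image, splits it into overlapping tiles, runs each tile through
#' the generator and (when present) the refinement module in evaluation
#' mode, and writes the blended 8-bit restoration. Frames smaller than a
#' tile (or with a tile overhanging the border) are reflection-padded and
#' cropped back. Overlapping tile predictions are averaged with linear
#' feathering weights.
#'
#' @param checkpoint path to a checkpoint from [save_checkpoint()], or a
#'   network bundle list.
#' @param input,output image paths (PNG/TIFF).
#' @param tile_size,overlap tile geometry; `tile_size` must be divisible by
#'   `2^depth` of the generator.
#' @return the restored (H, W, 3) array, invisibly (also written to
#'   `output` when non-`NULL`).
#' @export
infer_image <- function(checkpoint, input, output = NULL,
                        tile_size = 1024L, overlap = 64L) {
  nets <- if (is.character(checkpoint)) load_checkpoint(checkpoint)$nets
          else checkpoint
  depth <- nets$g$spec$depth
  if (tile_size %% 2^depth != 0)
    stop("tile_size must be divisible by 2^depth = ", 2^depth, call. = FALSE)
  img <- if (is.character(input)) load_image(input) else input
  d <- dim(img)
  pad_h <- max(0L, tile_size - d[1])
  pad_w <- max(0L, tile_size - d[2])
  if (pad_h > 0 || pad_w > 0) img <- reflect_pad(img, pad_h, pad_w)
  dp <- dim(img)

  grid <- plan_tiles(dp[1], dp[2], tile_size, overlap)
  acc <- array(0, dp)
  wacc <- matrix(0, dp[1], dp[2])
  for (i in seq_len(nrow(grid))) {
    r0 <- grid$row0[i]; c0 <- grid$col0[i]
    th <- grid$height[i]; tw <- grid$width[i]
    tile <- img[r0:(r0 + th - 1), c0:(c0 + tw - 1), , drop = FALSE]
    rest <- from_model(forward_restore(nets$g, nets$r, to_model(tile)))
    wr <- feather_profile(th, overlap, r0 == 1, r0 + th - 1 == dp[1])
    wc <- feather_profile(tw, overlap, c0 == 1, c0 + tw - 1 == dp[2])
    wmat <- outer(wr, wc)
    for (ch in 1:3)
      acc[r0:(r0 + th - 1), c0:(c0 + tw - 1), ch] <-
        acc[r0:(r0 + th - 1), c0:(c0 + tw - 1), ch] + rest[, , ch] * wmat
    wacc[r0:(r0 + th - 1), c0:(c0 + tw - 1)] <-
      wacc[r0:(r0 + th - 1), c0:(c0 + tw - 1)] + wmat
  }
  for (ch in 1:3) acc[, , ch] <- acc[, , ch] / wacc
  acc <- acc[seq_len(d[1]), seq_len(d[2]), , drop = FALSE]
  acc <- clamp(round(acc), 0, 255)
  if (!is.null(output)) save_image(acc, output)
  invisible(acc)
}

reflect_pad <- function(img, pad_h, pad_w) {
  d <- dim(img)
  ridx <- c(seq_len(d[1]), d[1] - seq_len(pad_h) %% d[1])
  cidx <- c(seq_len(d[2]), d[2] - seq_len(pad_w) %% d[2])
  img[ridx, cidx, , drop = FALSE]
}
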