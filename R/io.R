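# Image and dataset I/O. Images are 8-bit PNG (or TIFF) RGB; masks are
# single-channel 0/255 PNG. Dataset directories carry a manifest.yaml
# recording the generating configs and seeds.

#' Load an 8-bit image as an (H, W, 3) array
#'
#' PNG or TIFF, 8-bit, 1 or 3 channels; grayscale is replicated to 3
#' channels, an alpha channel is dropped. Values are returned on the
#' `[0, 255]` scale.
#'
#' @param path file path (.png, .tif/.tiff).
#' @return (H, W, 3) numeric array in `[0, 255]`.
#' @export
load_image <- function(path) {
  if (!file.exists(path)) stop("no such image file: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    img <- png::readPNG(path, info = TRUE)
    info <- attr(img, "info")
    if (!is.null(info$bit.depth) && info$bit.depth > 8)
      stop(sprintf("unsupported bit depth %d in %s (8-bit required)",
                   info$bit.depth, path), call. = FALSE)
  } else if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("the 'tiff' package is required to read TIFF files", call. = FALSE)
    img <- tiff::readTIFF(path, info = TRUE)
    info <- attr(img, "bits.per.sample")
    if (!is.null(info) && any(info > 8))
      stop(sprintf("unsupported bit depth %d in %s (8-bit required)",
                   max(info), path), call. = FALSE)
  } else {
    stop("unsupported image format '", ext, "' for ", path, call. = FALSE)
  }
  if (is.null(dim(img))) img <- matrix(img, nrow = NROW(img))
  d <- dim(img)
  if (length(d) == 2L) img <- array(rep(img, 3L), c(d, 3L))
  else if (d[3] == 1L) img <- array(rep(img[, , 1], 3L), c(d[1], d[2], 3L))
  else if (d[3] >= 4L) img <- img[, , 1:3, drop = FALSE]
  out <- round(img * 255)
  attributes(out) <- list(dim = dim(out))
  out
}

#' Save an (H, W, 3) array as an 8-bit image
#'
#' @param img numeric array in `[0, 255]`; values are rounded and clipped.
#' @param path destination path (.png or .tif/.tiff).
#' @return `path`, invisibly.
#' @export
save_image <- function(img, path) {
  check_image(img)
  x <- clamp(round(img), 0, 255) / 255
  ext <- tolower(tools::file_ext(path))
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  if (ext == "png") png::writePNG(x, path)
  else if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("the 'tiff' package is required to write TIFF files", call. = FALSE)
    tiff::writeTIFF(x, path, bits.per.sample = 8L)
  } else stop("unsupported image format '", ext, "' for ", path,
              call. = FALSE)
  invisible(path)
}

save_mask <- function(mask, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  png::writePNG(matrix(as.numeric(mask), nrow(mask), ncol(mask)), path)
  invisible(path)
}

load_mask <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  m > 0.5
}

#' Write a simulated dataset to a directory
#'
#' Layout: `paired/corrupted/NNNNN.png`, `paired/clean/NNNNN.png`,
#' `paired/mask/NNNNN.png` (8-bit 0/255), `unpaired/corrupted/...`,
#' `unpaired/clean/...`, plus `manifest.yaml` with the configs and seeds.
#'
#' @param dir destination directory.
#' @param paired list from [build_paired_dataset()], or `NULL`.
#' @param unpaired list from [build_unpaired_dataset()], or `NULL`.
#' @param phantom_cfg,eyelash_cfg,seed recorded in the manifest.
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dir, paired = NULL, unpaired = NULL,
                          phantom_cfg = NULL, eyelash_cfg = NULL,
                          seed = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (s in paired) {
    save_image(s$corrupted, file.path(dir, "paired", "corrupted",
                                      paste0(s$sample_id, ".png")))
    save_image(s$clean, file.path(dir, "paired", "clean",
                                  paste0(s$sample_id, ".png")))
    save_mask(s$mask, file.path(dir, "paired", "mask",
                                paste0(s$sample_id, ".png")))
  }
  for (s in unpaired$corrupted)
    save_image(s$corrupted, file.path(dir, "unpaired", "corrupted",
                                      paste0(s$sample_id, ".png")))
  for (s in unpaired$clean)
    save_image(s$clean, file.path(dir, "unpaired", "clean",
                                  paste0(s$sample_id, ".png")))
  manifest <- list(
    package = "lashgan",
    seed = seed,
    n_paired = length(paired),
    n_unpaired_corrupted = length(unpaired$corrupted),
    n_unpaired_clean = length(unpaired$clean),
    phantom_config = unclass(phantom_cfg),
    eyelash_config = unclass(eyelash_cfg)
  )
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  invisible(dir)
}

#' Load a dataset directory written by [write_dataset()]
#'
#' @param dir dataset directory.
#' @return list with `paired` (corrupted/clean/mask triplets), `unpaired`
#'   and the parsed `manifest`.
#' @export
load_dataset <- function(dir) {
  manifest_path <- file.path(dir, "manifest.yaml")
  manifest <- if (file.exists(manifest_path)) yaml::read_yaml(manifest_path)
  read_pool <- function(sub, with_mask = FALSE) {
    cdir <- file.path(dir, sub, "corrupted")
    if (!dir.exists(cdir)) return(list())
    ids <- sub("\\.png$", "", sort(list.files(cdir, pattern = "\\.png$")))
    lapply(ids, function(id) {
      out <- list(sample_id = id,
                  corrupted = load_image(file.path(cdir, paste0(id, ".png"))))
      cl <- file.path(dir, sub, "clean", paste0(id, ".png"))
      if (file.exists(cl)) out$clean <- load_image(cl)
      if (with_mask) {
        mp <- file.path(dir, sub, "mask", paste0(id, ".png"))
        if (file.exists(mp)) out$mask <- load_mask(mp)
      }
      out
    })
  }
  clean_dir <- file.path(dir, "unpaired", "clean")
  clean_pool <- if (dir.exists(clean_dir)) {
    ids <- sub("\\.png$", "", sort(list.files(clean_dir, pattern = "\\.png$")))
    lapply(ids, function(id)
      list(sample_id = id,
           clean = load_image(file.path(clean_dir, paste0(id, ".png")))))
  } else list()
  list(paired = read_pool("paired", with_mask = TRUE),
       unpaired = list(corrupted = read_pool("unpaired"), clean = clean_pool),
       manifest = manifest)
}
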