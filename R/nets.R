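# Network definitions: U-shaped generator / background refinement module and
# the two confidence-map discriminators, plus forward/backward drivers and
# parameter plumbing.

#' Generator / refiner architecture specification
#'
#' Describes the U-shaped encoder-decoder used both for the generator G and
#' the background refinement module. Every encoder layer is a 4x4 stride-2
#' convolution with batch normalization and Leaky ReLU, except the deepest
#' encoder which drops batch norm and uses ReLU; decoders are 4x4 stride-2
#' transposed convolutions with batch norm and ReLU, except the last, which
#' drops batch norm and squashes through tanh. Skip connections concatenate
#' encoder layer `i` with decoder layer `depth - i`.
#'
#' @param depth number of encoder (= decoder) layers; the input spatial size
#'   must be divisible by `2^depth`.
#' @param base_channels channels after the first encoder layer.
#' @param channel_cap maximum channel width; the schedule doubles per layer up
#'   to this cap (64, 128, 256, 512, 512, ... for the defaults).
#' @param in_channels,out_channels image channels (RGB in and out).
#' @param noise_mode how the stochastic input z is realised: `"dropout"`
#'   applies rate-0.5 dropout in the first decoder layers during training
#'   (the conditional-GAN convention); `"none"` disables it.
#' @return an object of class `generator_spec`.
#' @export
generator_spec <- function(depth = 8L, base_channels = 64L, channel_cap = 512L,
                           in_channels = 3L, out_channels = 3L,
                           noise_mode = c("dropout", "none")) {
  noise_mode <- match.arg(noise_mode)
  if (depth < 1) stop("depth must be >= 1", call. = FALSE)
  if (base_channels < 1 || channel_cap < base_channels)
    stop("need 1 <= base_channels <= channel_cap", call. = FALSE)
  structure(
    list(depth = as.integer(depth), base_channels = as.integer(base_channels),
         channel_cap = as.integer(channel_cap),
         in_channels = as.integer(in_channels),
         out_channels = as.integer(out_channels), noise_mode = noise_mode),
    class = "generator_spec"
  )
}

#' Discriminator architecture specification
#'
#' Five 4x4 convolutional layers with strides (2, 2, 2, 1, 1); batch
#' normalization in layers 2-4; Leaky ReLU everywhere except the last layer,
#' which emits a single-channel confidence map through a sigmoid. The
#' conditional discriminator (D1) takes the corrupted image concatenated with
#' a candidate restoration (6 channels); the unconditional discriminator (D2)
#' takes single images (3 channels).
#'
#' @param conditional logical; `TRUE` builds the 6-channel pair discriminator.
#' @param base_channels channels after the first layer (doubling up to 8x).
#' @param in_channels channels of one image (3 for RGB).
#' @return an object of class `discriminator_spec`.
#' @export
discriminator_spec <- function(conditional, base_channels = 64L,
                               in_channels = 3L) {
  stopifnot(is.logical(conditional), length(conditional) == 1L)
  structure(
    list(conditional = conditional, base_channels = as.integer(base_channels),
         in_channels = as.integer(if (conditional) 2L * in_channels else in_channels),
         layers = 5L, strides = c(2L, 2L, 2L, 1L, 1L), kernel = 4L),
    class = "discriminator_spec"
  )
}

unet_channels <- function(spec) {
  pmin(spec$base_channels * 2^(seq_len(spec$depth) - 1L), spec$channel_cap)
}

#' Build the generator network
#'
#' @param spec a [generator_spec()].
#' @return a network handle (class `lash_net`) holding layers, the spec and
#'   the parameter count; consumed by [net_forward()] and the trainer.
#' @export
build_generator <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  d <- spec$depth
  ch <- unet_channels(spec)
  enc <- vector("list", d)
  for (i in seq_len(d)) {
    enc[[i]] <- new_layer("conv",
      in_ch = if (i == 1L) spec$in_channels else ch[i - 1L],
      out_ch = ch[i],
      bn = i < d,
      act = if (i < d) "lrelu" else "relu"
    )
  }
  dec <- vector("list", d)
  for (j in seq_len(d)) {
    dec[[j]] <- new_layer("tconv",
      in_ch = if (j == 1L) ch[d] else 2L * ch[d - j + 1L],
      out_ch = if (j < d) ch[d - j] else spec$out_channels,
      bn = j < d,
      act = if (j < d) "relu" else "tanh",
      dropout = if (spec$noise_mode == "dropout" && j <= min(3L, d - 1L)) 0.5 else 0
    )
  }
  net <- structure(list(arch = "unet", spec = spec, enc = enc, dec = dec),
                   class = "lash_net")
  net$param_count <- net_param_count(net)
  net
}

#' Build the background refinement module
#'
#' The refinement module adopts the same U-shaped structure as the generator
#' (independent parameters); it polishes the generator output so that
#' background detail occluded by eyelashes is recovered.
#'
#' @inheritParams build_generator
#' @return a network handle, identical contracts to [build_generator()].
#' @export
build_refiner <- function(spec) build_generator(spec)

#' Build a confidence-map discriminator
#'
#' @param spec a [discriminator_spec()].
#' @return a network handle mapping (H, W, C) input to a single-channel
#'   confidence map with values in (0, 1).
#' @export
build_discriminator <- function(spec) {
  stopifnot(inherits(spec, "discriminator_spec"))
  ch <- c(spec$base_channels * c(1L, 2L, 4L, 8L), 1L)
  layers <- vector("list", spec$layers)
  for (i in seq_len(spec$layers)) {
    layers[[i]] <- new_layer("conv",
      in_ch = if (i == 1L) spec$in_channels else ch[i - 1L],
      out_ch = ch[i],
      stride = spec$strides[i],
      bn = i %in% 2:4,
      act = if (i < spec$layers) "lrelu" else "sigmoid"
    )
  }
  net <- structure(list(arch = "patchgan", spec = spec, layers = layers),
                   class = "lash_net")
  net$param_count <- net_param_count(net)
  net
}

check_divisible <- function(size, depth) {
  if (any(size %% 2^depth != 0))
    stop(sprintf(
      "input spatial size %s must be divisible by 2^depth = %d",
      paste(size, collapse = "x"), 2^depth), call. = FALSE)
}

#' Run a network forward
#'
#' @param net a network handle from [build_generator()],
#'   [build_refiner()] or [build_discriminator()].
#' @param x an (H, W, C) image or (H, W, C, N) batch on the model `[-1, 1]`
#'   scale.
#' @param training logical; training mode uses batch statistics for batch
#'   norm and activates decoder dropout, evaluation mode uses running
#'   statistics and is deterministic.
#' @param keep_cache keep intermediate activations for [net_backward()].
#' @return `list(out, cache)`; `cache` is `NULL` unless `keep_cache = TRUE`.
#' @export
net_forward <- function(net, x, training = FALSE, keep_cache = training) {
  x <- as_batch(x)
  if (net$arch == "unet") {
    check_divisible(dim(x)[1:2], net$spec$depth)
    d <- net$spec$depth
    enc_out <- vector("list", d)
    enc_cache <- vector("list", d)
    h <- x
    for (i in seq_len(d)) {
      fw <- layer_forward(net$enc[[i]], h, training)
      h <- fw$out
      enc_out[[i]] <- h
      if (keep_cache) enc_cache[[i]] <- fw$cache
    }
    dec_cache <- vector("list", d)
    for (j in seq_len(d)) {
      inp <- if (j == 1L) h else concat_channels(h, enc_out[[d - j + 1L]])
      fw <- layer_forward(net$dec[[j]], inp, training)
      h <- fw$out
      if (keep_cache) dec_cache[[j]] <- fw$cache
    }
    list(out = h,
         cache = if (keep_cache) list(enc = enc_cache, dec = dec_cache))
  } else {
    caches <- if (keep_cache) vector("list", length(net$layers))
    h <- x
    for (i in seq_along(net$layers)) {
      fw <- layer_forward(net$layers[[i]], h, training)
      h <- fw$out
      if (keep_cache) caches[[i]] <- fw$cache
    }
    list(out = h, cache = caches)
  }
}

#' Backpropagate a loss gradient through a network
#'
#' @param net network handle.
#' @param cache the cache from `net_forward(..., keep_cache = TRUE)`.
#' @param dout gradient of the loss with respect to the network output
#'   (same shape as the output batch).
#' @param need_dx also compute the gradient with respect to the input (needed
#'   when a frozen discriminator feeds gradients back into the generator).
#' @return `list(dx, grads)`; `grads` mirrors the layer structure.
#' @export
net_backward <- function(net, cache, dout, need_dx = FALSE) {
  if (net$arch == "unet") {
    d <- net$spec$depth
    dec_grads <- vector("list", d)
    denc <- vector("list", d) # gradients accumulated at encoder outputs
    g <- dout
    for (j in rev(seq_len(d))) {
      bw <- layer_backward(net$dec[[j]], cache$dec[[j]], g, need_dx = TRUE)
      dec_grads[[j]] <- bw$grads
      if (j == 1L) {
        denc[[d]] <- add_or_set(denc[[d]], bw$dx)
        g <- NULL
      } else {
        nch <- dim(bw$dx)[3]
        skip_ch <- dim(cache$enc[[d - j + 1L]]$y)[3]
        g <- bw$dx[, , seq_len(nch - skip_ch), , drop = FALSE]
        denc[[d - j + 1L]] <- add_or_set(
          denc[[d - j + 1L]],
          bw$dx[, , nch - skip_ch + seq_len(skip_ch), , drop = FALSE])
      }
    }
    enc_grads <- vector("list", d)
    g <- NULL
    for (i in rev(seq_len(d))) {
      gi <- add_or_set(denc[[i]], g)
      bw <- layer_backward(net$enc[[i]], cache$enc[[i]], gi,
                           need_dx = (i > 1L) || need_dx)
      enc_grads[[i]] <- bw$grads
      g <- bw$dx
    }
    list(dx = if (need_dx) g, grads = list(enc = enc_grads, dec = dec_grads))
  } else {
    n <- length(net$layers)
    grads <- vector("list", n)
    g <- dout
    for (i in rev(seq_len(n))) {
      bw <- layer_backward(net$layers[[i]], cache[[i]], g,
                           need_dx = (i > 1L) || need_dx)
      grads[[i]] <- bw$grads
      g <- bw$dx
    }
    list(dx = if (need_dx) g, grads = grads)
  }
}

add_or_set <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.null(b)) return(a)
  a + b
}

net_layer_groups <- function(net) {
  if (net$arch == "unet") list(enc = net$enc, dec = net$dec)
  else list(layers = net$layers)
}

#' Flat named list of all trainable parameters of a network
#'
#' Names follow `group<i>.<param>` (e.g. `enc3.W`, `dec1.gamma`).
#'
#' @param net network handle.
#' @return named list of numeric arrays.
#' @export
net_params <- function(net) {
  out <- list()
  for (gname in names(net_layer_groups(net))) {
    layers <- net[[gname]]
    for (i in seq_along(layers)) {
      for (p in layer_param_names(layers[[i]]))
        out[[sprintf("%s%d.%s", gname, i, p)]] <- layers[[i]][[p]]
    }
  }
  out
}

net_set_params <- function(net, params) {
  for (gname in names(net_layer_groups(net))) {
    for (i in seq_along(net[[gname]])) {
      for (p in layer_param_names(net[[gname]][[i]])) {
        key <- sprintf("%s%d.%s", gname, i, p)
        net[[gname]][[i]][[p]] <- params[[key]]
      }
    }
  }
  net
}

grads_as_params <- function(grads) {
  out <- list()
  for (gname in names(grads)) {
    for (i in seq_along(grads[[gname]])) {
      for (p in names(grads[[gname]][[i]]))
        out[[sprintf("%s%d.%s", gname, i, p)]] <- grads[[gname]][[i]][[p]]
    }
  }
  out
}

# discriminator grads come back as an unnamed list of layers
disc_grads_as_params <- function(grads) {
  out <- list()
  for (i in seq_along(grads)) {
    for (p in names(grads[[i]]))
      out[[sprintf("layers%d.%s", i, p)]] <- grads[[i]][[p]]
  }
  out
}

#' Number of trainable parameters
#' @param net network handle.
#' @return integer count over all weights, biases and batch-norm affines.
#' @export
net_param_count <- function(net) {
  sum(vapply(net_params(net), length, integer(1)))
}

# refresh BN running statistics after a training-mode forward
net_update_running <- function(net, cache) {
  if (net$arch == "unet") {
    for (i in seq_along(net$enc))
      net$enc[[i]] <- layer_update_running(net$enc[[i]], cache$enc[[i]])
    for (j in seq_along(net$dec))
      net$dec[[j]] <- layer_update_running(net$dec[[j]], cache$dec[[j]])
  } else {
    for (i in seq_along(net$layers))
      net$layers[[i]] <- layer_update_running(net$layers[[i]], cache[[i]])
  }
  net
}

#' Restore an image through the generator and refinement module
#'
#' The inference path: the generator removes eyelash artifacts, the
#' background refinement module (when present) polishes the result. Runs in
#' evaluation mode (deterministic).
#'
#' @param g generator handle.
#' @param r refinement-module handle, or `NULL` for generator-only variants.
#' @param x image or batch on the model `[-1, 1]` scale.
#' @return restored image/batch, same shape, values in (-1, 1).
#' @export
forward_restore <- function(g, r, x) {
  single <- length(dim(x)) == 3L
  y <- net_forward(g, x, training = FALSE, keep_cache = FALSE)$out
  if (!is.null(r)) y <- net_forward(r, y, training = FALSE, keep_cache = FALSE)$out
  if (single) drop_batch(y) else y
}

#' @export
print.lash_net <- function(x, ...) {
  cat(sprintf("<lash_net %s: %s parameters>\n", x$arch,
              format(x$param_count, big.mark = ",")))
  invisible(x)
}

# ---- checkpoints ------------------------------------------------------------

#' Save / load a training checkpoint
#'
#' The checkpoint bundles all network parameter sets, their specs, the
#' normalization convention and the training seed; loading verifies the
#' format version.
#'
#' @param nets named list of network handles (`g`, and optionally `r`, `d1`,
#'   `d2`).
#' @param path file path.
#' @param meta optional list of extra metadata (config, seed, epoch).
#' @return `save_checkpoint` returns `path` invisibly; `load_checkpoint`
#'   returns `list(nets, meta)`.
#' @export
save_checkpoint <- function(nets, path, meta = list()) {
  obj <- list(format = "lashgan-checkpoint", version = 1L,
              normalization = "x/127.5 - 1",
              specs = lapply(nets, function(n) n$spec),
              nets = nets, meta = meta)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stop("checkpoint not found: ", path, call. = FALSE)
  obj <- readRDS(path)
  if (!identical(obj$format, "lashgan-checkpoint"))
    stop("not a lashgan checkpoint: ", path, call. = FALSE)
  if (obj$version > 1L)
    stop("checkpoint version ", obj$version, " is newer than this package",
         call. = FALSE)
  list(nets = obj$nets, meta = obj$meta)
}
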