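# Joint adversarial training: the shared generator is optimized alternately
# on paired (conditional) and unpaired (unconditional) steps; the background
# refinement module is trained on paired steps only, where its L1 refinement
# loss is defined.

VARIANTS <- c("cgan_sub", "cgan_ref", "cgan_gan", "full")

variant_has_refiner <- function(variant) variant %in% c("cgan_ref", "full")
variant_has_d2 <- function(variant) variant %in% c("cgan_gan", "full")

#' Training configuration
#'
#' Defaults reproduce the reference training regime (Adam with learning rate
#' 0.0002, batch size 15, 200 epochs, random horizontal flipping, loss
#' weights lambda1 = 100 and lambda2 = 10, 1024-pixel patches). Desk-scale
#' runs override `image_size`, `depth`, `base_channels`, `epochs` and
#' `batch_size` downward.
#'
#' @param epochs training epochs.
#' @param learning_rate Adam learning rate.
#' @param batch_size samples per step.
#' @param flip_probability probability of horizontal flipping (applied
#'   identically to corrupted, clean and mask).
#' @param alternation_ratio integer pair: paired steps then unpaired steps
#'   per alternation cycle.
#' @param variant `"cgan_sub"` (generator + conditional discriminator),
#'   `"cgan_ref"` (+ refinement module), `"cgan_gan"` (+ unconditional
#'   discriminator), or `"full"` (all sub-networks).
#' @param weights a [loss_weights()].
#' @param rng_seed global training seed.
#' @param image_size training patch side length.
#' @param depth,base_channels,channel_cap,noise_mode generator architecture
#'   (see [generator_spec()]).
#' @param disc_base_channels first-layer width of both discriminators.
#' @param val_fraction fraction of the paired set held out for validation.
#' @param saturating use the saturating minimax generator term instead of
#'   the non-saturating surrogate.
#' @param verbose print per-epoch progress.
#' @return object of class `train_config`.
#' @export
train_config <- function(epochs = 200L, learning_rate = 2e-4,
                         batch_size = 15L, flip_probability = 0.5,
                         alternation_ratio = c(1L, 1L),
                         variant = c("full", "cgan_sub", "cgan_ref",
                                     "cgan_gan"),
                         weights = loss_weights(),
                         rng_seed = 1L, image_size = 1024L, depth = 8L,
                         base_channels = 64L, channel_cap = 512L,
                         noise_mode = "dropout", disc_base_channels = 64L,
                         val_fraction = 0.1, saturating = FALSE,
                         verbose = FALSE) {
  variant <- match.arg(variant)
  if (epochs < 1) stop("epochs must be >= 1", call. = FALSE)
  if (image_size %% 2^depth != 0)
    stop("image_size must be divisible by 2^depth", call. = FALSE)
  structure(list(
    epochs = as.integer(epochs), learning_rate = learning_rate,
    batch_size = as.integer(batch_size),
    flip_probability = flip_probability,
    alternation_ratio = as.integer(alternation_ratio), variant = variant,
    weights = weights, rng_seed = as.integer(rng_seed),
    image_size = as.integer(image_size), depth = as.integer(depth),
    base_channels = as.integer(base_channels),
    channel_cap = as.integer(channel_cap), noise_mode = noise_mode,
    disc_base_channels = as.integer(disc_base_channels),
    val_fraction = val_fraction, saturating = saturating,
    verbose = isTRUE(verbose)
  ), class = "train_config")
}

#' Build the networks of a model variant
#'
#' @param config a [train_config()].
#' @return named list `g`, `r` (or `NULL`), `d1`, `d2` (or `NULL`).
#' @export
build_jcgan <- function(config) {
  gspec <- generator_spec(depth = config$depth,
                          base_channels = config$base_channels,
                          channel_cap = config$channel_cap,
                          noise_mode = config$noise_mode)
  list(
    g = build_generator(gspec),
    r = if (variant_has_refiner(config$variant)) build_refiner(gspec),
    d1 = build_discriminator(
      discriminator_spec(TRUE, base_channels = config$disc_base_channels)),
    d2 = if (variant_has_d2(config$variant)) build_discriminator(
      discriminator_spec(FALSE, base_channels = config$disc_base_channels))
  )
}

#' Seed every RNG stream used in training
#'
#' Data order, augmentation, initialization and dropout all draw from R's
#' global RNG, so one seed makes a full run reproducible.
#'
#' @param seed integer seed.
#' @export
set_global_seed <- function(seed) {
  set.seed(as.integer(seed))
  invisible(NULL)
}

check_finite_losses <- function(report) {
  for (nm in names(report)) {
    v <- report[[nm]]
    if (length(v) == 1 && !is.na(v) && !is.finite(v))
      stop("non-finite loss component: ", nm, call. = FALSE)
  }
  invisible(report)
}

# gradient of the discriminator BCE with respect to its two output maps
d_bce_grads <- function(p_real, p_fake) {
  list(dreal = -0.5 / (pmax(p_real, .bce_eps) * length(p_real)),
       dfake = 0.5 / (pmax(1 - p_fake, .bce_eps) * length(p_fake)))
}

g_adv_grad <- function(p_fake, saturating) {
  M <- length(p_fake)
  if (saturating) -1 / (pmax(1 - p_fake, .bce_eps) * M)
  else -1 / (pmax(p_fake, .bce_eps) * M)
}

update_discriminator <- function(d, opt, real_in, fake_in, saturating) {
  fr <- net_forward(d, real_in, training = TRUE, keep_cache = TRUE)
  d <- net_update_running(d, fr$cache)
  ff <- net_forward(d, fake_in, training = TRUE, keep_cache = TRUE)
  d <- net_update_running(d, ff$cache)
  adv <- conditional_adversarial_terms(fr$out, ff$out, saturating)
  gr <- d_bce_grads(fr$out, ff$out)
  bw_r <- net_backward(d, fr$cache, array(gr$dreal, dim(fr$out)))
  bw_f <- net_backward(d, ff$cache, array(gr$dfake, dim(ff$out)))
  grads <- mapply(function(a, b) a + b,
                  disc_grads_as_params(bw_r$grads),
                  disc_grads_as_params(bw_f$grads), SIMPLIFY = FALSE)
  st <- adam_step(d, grads, opt)
  list(d = st$net, opt = st$opt, d_loss = adv$d_loss)
}

#' One paired (conditional) training step
#'
#' Updates the conditional discriminator D1 on real versus generated pairs,
#' then updates the generator (and refinement module, when active) on the
#' conditional adversarial term plus `lambda1 * L1` plus
#' `lambda2 * L_ref`.
#'
#' @param batch list with `x` and `y`: (H, W, 3, N) arrays on the model
#'   `[-1, 1]` scale (corrupted and clean).
#' @param nets network bundle from [build_jcgan()].
#' @param opts optimizer bundle (named like `nets`).
#' @param config a [train_config()].
#' @return `list(nets, opts, report)` where `report` is a [loss_report()].
#' @export
paired_step <- function(batch, nets, opts, config) {
  w <- config$weights
  x <- batch$x; y <- batch$y
  use_r <- variant_has_refiner(config$variant) && !is.null(nets$r)

  gf <- net_forward(nets$g, x, training = TRUE, keep_cache = TRUE)
  nets$g <- net_update_running(nets$g, gf$cache)
  yhat <- gf$out

  if (use_r) {
    rf <- net_forward(nets$r, yhat, training = TRUE, keep_cache = TRUE)
    nets$r <- net_update_running(nets$r, rf$cache)
    ytil <- rf$out
  }

  up <- update_discriminator(nets$d1, opts$d1,
                             real_in = concat_channels(x, y),
                             fake_in = concat_channels(x, yhat),
                             config$saturating)
  nets$d1 <- up$d; opts$d1 <- up$opt

  # generator (+ refiner) update against the refreshed discriminator
  df <- net_forward(nets$d1, concat_channels(x, yhat), training = TRUE,
                    keep_cache = TRUE)
  l_ca <- if (config$saturating) mean(safe_log(1 - df$out))
          else mean(-safe_log(df$out))
  dmap <- array(g_adv_grad(df$out, config$saturating), dim(df$out))
  bw_d <- net_backward(nets$d1, df$cache, dmap, need_dx = TRUE)
  dyhat <- bw_d$dx[, , 4:6, , drop = FALSE]

  M <- length(yhat)
  l_l1 <- l1_generation_loss(yhat, y)
  dyhat <- dyhat + w$lambda1 * sign(yhat - y) / M

  l_ref <- NA_real_
  r_grads <- NULL
  if (use_r) {
    l_ref <- refinement_loss(ytil, y)
    bw_rr <- net_backward(nets$r, rf$cache,
                          w$lambda2 * sign(ytil - y) / M, need_dx = TRUE)
    r_grads <- grads_as_params(bw_rr$grads)
    dyhat <- dyhat + bw_rr$dx
  }

  bw_g <- net_backward(nets$g, gf$cache, dyhat)
  st <- adam_step(nets$g, grads_as_params(bw_g$grads), opts$g)
  nets$g <- st$net; opts$g <- st$opt
  if (use_r) {
    st <- adam_step(nets$r, r_grads, opts$r)
    nets$r <- st$net; opts$r <- st$opt
  }

  report <- loss_report(
    l_ca = l_ca, l_l1 = l_l1, l_ref = l_ref, d1_loss = up$d_loss,
    total = total_generator_loss(
      list(l_ca = l_ca, l_l1 = l_l1, l_uca = NA_real_, l_ref = l_ref), w)
  )
  check_finite_losses(report)
  list(nets = nets, opts = opts, report = report)
}

#' One unpaired (unconditional) training step
#'
#' Updates the unconditional discriminator D2 on real artifact-free images
#' versus generated restorations of unpaired corrupted images, then updates
#' the generator (not the refinement module) on the unconditional
#' adversarial term. L1 and refinement losses are not evaluated: the step
#' has no pixel-aligned reference.
#'
#' @param batch list with `x` (unpaired corrupted batch) and `y_real`
#'   (clean-pool batch), both on the model scale; the two must come from
#'   disjoint pools.
#' @inheritParams paired_step
#' @return `list(nets, opts, report)`.
#' @export
unpaired_step <- function(batch, nets, opts, config) {
  if (!variant_has_d2(config$variant))
    stop("variant '", config$variant,
         "' has no unconditional discriminator; unpaired steps are not ",
         "part of its training schedule", call. = FALSE)
  x <- batch$x

  gf <- net_forward(nets$g, x, training = TRUE, keep_cache = TRUE)
  nets$g <- net_update_running(nets$g, gf$cache)
  yhat <- gf$out

  up <- update_discriminator(nets$d2, opts$d2, real_in = batch$y_real,
                             fake_in = yhat, config$saturating)
  nets$d2 <- up$d; opts$d2 <- up$opt

  df <- net_forward(nets$d2, yhat, training = TRUE, keep_cache = TRUE)
  l_uca <- if (config$saturating) mean(safe_log(1 - df$out))
           else mean(-safe_log(df$out))
  dmap <- array(g_adv_grad(df$out, config$saturating), dim(df$out))
  bw_d <- net_backward(nets$d2, df$cache, dmap, need_dx = TRUE)

  bw_g <- net_backward(nets$g, gf$cache, bw_d$dx)
  st <- adam_step(nets$g, grads_as_params(bw_g$grads), opts$g)
  nets$g <- st$net; opts$g <- st$opt

  report <- loss_report(
    l_uca = l_uca, d2_loss = up$d_loss,
    total = total_generator_loss(list(l_ca = NA_real_, l_l1 = NA_real_,
                                      l_uca = l_uca, l_ref = NA_real_),
                                 config$weights)
  )
  check_finite_losses(report)
  list(nets = nets, opts = opts, report = report)
}

# assemble a model-scale batch from paired samples, with seeded flips
paired_batch <- function(samples, flip_probability) {
  n <- length(samples)
  d <- dim(samples[[1]]$clean)
  x <- array(0, c(d[1], d[2], 3L, n))
  y <- array(0, c(d[1], d[2], 3L, n))
  for (i in seq_len(n)) {
    cor <- samples[[i]]$corrupted; cln <- samples[[i]]$clean
    if (runif(1) < flip_probability) {
      cor <- cor[, d[2]:1, , drop = FALSE]
      cln <- cln[, d[2]:1, , drop = FALSE]
    }
    x[, , , i] <- to_model(cor)
    y[, , , i] <- to_model(cln)
  }
  list(x = x, y = y)
}

image_batch <- function(imgs, flip_probability) {
  n <- length(imgs)
  d <- dim(imgs[[1]])
  x <- array(0, c(d[1], d[2], 3L, n))
  for (i in seq_len(n)) {
    im <- imgs[[i]]
    if (runif(1) < flip_probability) im <- im[, d[2]:1, , drop = FALSE]
    x[, , , i] <- to_model(im)
  }
  x
}

chunk_indices <- function(idx, size) {
  if (length(idx) == 0L) return(list())
  split(idx, ceiling(seq_along(idx) / size))
}

#' Train a model variant end-to-end
#'
#' Interleaves paired and unpaired steps per `alternation_ratio` (paired
#' first), shuffling per epoch with the seeded RNG, and tracks a per-epoch
#' history of loss components and held-out validation PSNR/SSIM. The epoch
#' with the best validation PSNR is kept as `best`.
#'
#' @param paired list of paired samples from [build_paired_dataset()].
#' @param unpaired `list(corrupted, clean)` from [build_unpaired_dataset()],
#'   or `NULL` for paired-only variants.
#' @param config a [train_config()].
#' @param nets optional pre-built network bundle (defaults to
#'   [build_jcgan()] under the config seed).
#' @param checkpoint_path optional path; the best-validation networks are
#'   saved there with [save_checkpoint()].
#' @return list with `nets` (final), `best` (best-validation), `history`
#'   (tibble, one row per epoch) and `val_idx`.
#' @export
fit <- function(paired, unpaired = NULL, config = train_config(),
                nets = NULL, checkpoint_path = NULL) {
  stopifnot(inherits(config, "train_config"))
  if (length(paired) < 2L)
    stop("need at least 2 paired samples (training + validation)",
         call. = FALSE)
  needs_unpaired <- variant_has_d2(config$variant)
  if (needs_unpaired &&
      (is.null(unpaired) || length(unpaired$corrupted) < 1L ||
       length(unpaired$clean) < 1L))
    stop("variant '", config$variant, "' requires unpaired pools",
         call. = FALSE)

  set_global_seed(config$rng_seed)
  if (is.null(nets)) nets <- build_jcgan(config)
  opts <- lapply(nets, function(n)
    if (!is.null(n)) adam_init(n, lr = config$learning_rate))

  n <- length(paired)
  val_n <- max(1L, min(n - 1L, round(config$val_fraction * n)))
  val_idx <- sort(sample(n, val_n))
  train_idx <- setdiff(seq_len(n), val_idx)

  history <- NULL
  best <- list(psnr = -Inf, nets = NULL, epoch = NA_integer_)
  ratio <- config$alternation_ratio

  for (epoch in seq_len(config$epochs)) {
    p_batches <- chunk_indices(train_idx[sample.int(length(train_idx))],
                               config$batch_size)
    u_batches <- list()
    if (needs_unpaired) {
      uc <- sample.int(length(unpaired$corrupted))
      ucl <- sample.int(length(unpaired$clean))
      u_batches <- chunk_indices(uc, config$batch_size)
      ucl_rep <- rep(ucl, length.out = length(uc))
      u_clean_batches <- chunk_indices(ucl_rep, config$batch_size)
    }
    reports <- list()
    pi <- 1L; ui <- 1L
    while (pi <= length(p_batches)) {
      for (k in seq_len(ratio[1])) {
        if (pi > length(p_batches)) break
        b <- paired_batch(paired[p_batches[[pi]]], config$flip_probability)
        st <- paired_step(b, nets, opts, config)
        nets <- st$nets; opts <- st$opts
        reports[[length(reports) + 1L]] <- st$report
        pi <- pi + 1L
      }
      if (needs_unpaired && length(u_batches) > 0L) {
        for (k in seq_len(ratio[2])) {
          if (ui > length(u_batches)) ui <- 1L
          xb <- image_batch(
            lapply(unpaired$corrupted[u_batches[[ui]]], `[[`, "corrupted"),
            config$flip_probability)
          yb <- image_batch(
            lapply(unpaired$clean[u_clean_batches[[ui]]], `[[`, "clean"),
            config$flip_probability)
          st <- unpaired_step(list(x = xb, y_real = yb), nets, opts, config)
          nets <- st$nets; opts <- st$opts
          reports[[length(reports) + 1L]] <- st$report
          ui <- ui + 1L
        }
      }
    }
    agg <- do.call(rbind, reports)
    mean_or_na <- function(v) if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
    eval_bundle <- list(g = nets$g,
                        r = if (variant_has_refiner(config$variant)) nets$r)
    val <- evaluate_pairs(eval_bundle, paired[val_idx])
    row <- tibble::tibble(
      epoch = epoch,
      l_ca = mean_or_na(agg$l_ca), l_l1 = mean_or_na(agg$l_l1),
      l_uca = mean_or_na(agg$l_uca), l_ref = mean_or_na(agg$l_ref),
      d1_loss = mean_or_na(agg$d1_loss), d2_loss = mean_or_na(agg$d2_loss),
      total = mean_or_na(agg$total),
      val_psnr = val$psnr, val_ssim = val$ssim
    )
    history <- if (is.null(history)) row else rbind(history, row)
    if (is.finite(val$psnr) && val$psnr > best$psnr)
      best <- list(psnr = val$psnr, nets = nets, epoch = epoch)
    if (config$verbose)
      message(sprintf(
        "epoch %3d | L1 %.4f | val PSNR %.2f dB | val SSIM %.4f",
        epoch, row$l_l1, val$psnr, val$ssim))
  }

  if (is.null(best$nets)) best$nets <- nets
  if (!is.null(checkpoint_path))
    save_checkpoint(best$nets, checkpoint_path,
                    meta = list(config = config, seed = config$rng_seed,
                                best_epoch = best$epoch))
  list(nets = nets, best = best$nets, history = history, val_idx = val_idx,
       config = config)
}

#' Mean restoration quality over paired samples
#'
#' Runs the inference path (generator then refinement module when present)
#' in evaluation mode and averages PSNR and SSIM against the clean
#' references on the 8-bit scale.
#'
#' @param nets network bundle.
#' @param pairs list of paired samples.
#' @return `list(psnr, ssim)`.
#' @export
evaluate_pairs <- function(nets, pairs) {
  ps <- numeric(length(pairs)); ss <- numeric(length(pairs))
  for (i in seq_along(pairs)) {
    xr <- forward_restore(nets$g, nets$r, to_model(pairs[[i]]$corrupted))
    restored <- from_model(xr)
    ps[i] <- psnr(restored, pairs[[i]]$clean)
    ss[i] <- ssim(restored, pairs[[i]]$clean)
  }
  list(psnr = mean(ps), ssim = mean(ss))
}
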