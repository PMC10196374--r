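# Training steps and the end-to-end fit loop (tiny problem sizes).

tiny_batch <- function(n = 2, size = 32) {
  pcfg <- desk_phantom(size)
  ecfg <- desk_eyelash(size, stroke_count_range = c(6, 10))
  samples <- build_paired_dataset(n, pcfg, ecfg, seed = 5)
  lashgan:::paired_batch(samples, flip_probability = 0)
}

test_that("a paired step updates the generator and only its own discriminator", {
  cfg <- tiny_train_config(variant = "full")
  set_global_seed(3)
  nets <- build_jcgan(cfg)
  opts <- lapply(nets, function(n) if (!is.null(n)) adam_init(n))
  b <- tiny_batch()

  g_before <- lashgan:::param_checksum(net_params(nets$g))
  d2_before <- lashgan:::param_checksum(net_params(nets$d2))
  st <- paired_step(b, nets, opts, cfg)
  expect_false(isTRUE(all.equal(
    g_before, lashgan:::param_checksum(net_params(st$nets$g)))))
  expect_identical(d2_before,
                   lashgan:::param_checksum(net_params(st$nets$d2)))
  expect_true(is.finite(st$report$total))
  expect_true(st$report$l_l1 >= 0 && st$report$l_ref >= 0)
})

test_that("an unpaired step trains D2 and G but never touches R or D1,
           and reports no pixel losses", {
  cfg <- tiny_train_config(variant = "full")
  set_global_seed(4)
  nets <- build_jcgan(cfg)
  opts <- lapply(nets, function(n) if (!is.null(n)) adam_init(n))
  b <- tiny_batch()
  batch <- list(x = b$x, y_real = b$y)

  r_before <- lashgan:::param_checksum(net_params(nets$r))
  d1_before <- lashgan:::param_checksum(net_params(nets$d1))
  st <- unpaired_step(batch, nets, opts, cfg)
  expect_identical(r_before, lashgan:::param_checksum(net_params(st$nets$r)))
  expect_identical(d1_before,
                   lashgan:::param_checksum(net_params(st$nets$d1)))
  expect_true(is.na(st$report$l_l1))
  expect_true(is.na(st$report$l_ref))
  expect_true(is.finite(st$report$l_uca))
})

test_that("paired-only variants reject unpaired steps", {
  cfg <- tiny_train_config(variant = "cgan_sub")
  set_global_seed(5)
  nets <- build_jcgan(cfg)
  opts <- lapply(nets, function(n) if (!is.null(n)) adam_init(n))
  b <- tiny_batch()
  expect_error(unpaired_step(list(x = b$x, y_real = b$y), nets, opts, cfg),
               "unconditional discriminator")
})

test_that("an untrained unconditional discriminator starts uninformative", {
  # symmetric small-weight init: confidence maps near 0.5, so the BCE sits
  # near log 2
  losses <- vapply(1:10, function(s) {
    set_global_seed(s)
    d <- build_discriminator(discriminator_spec(FALSE, base_channels = 8))
    x <- array(runif(32 * 32 * 3 * 2, -1, 1), c(32, 32, 3, 2))
    y <- array(runif(32 * 32 * 3 * 2, -1, 1), c(32, 32, 3, 2))
    pr <- net_forward(d, x)$out
    pf <- net_forward(d, y)$out
    unconditional_adversarial_terms(pr, pf)$d_loss
  }, numeric(1))
  expect_lt(abs(mean(losses) - log(2)), 0.3)
})

test_that("pure L1 training overfits a single pair (supervised sanity)", {
  # adversarial terms disabled: gradient descent on the L1 loss alone must
  # drive the reconstruction error of one memorized pair far down
  set_global_seed(6)
  g <- build_generator(generator_spec(depth = 4, base_channels = 8,
                                      channel_cap = 32, noise_mode = "none"))
  opt <- adam_init(g, lr = 2e-3)
  b <- tiny_batch(n = 1, size = 16)
  l1 <- NA
  for (i in 1:120) {
    fw <- net_forward(g, b$x, training = TRUE, keep_cache = TRUE)
    g <- lashgan:::net_update_running(g, fw$cache)
    l1 <- l1_generation_loss(fw$out, b$y)
    dout <- sign(fw$out - b$y) / length(fw$out)
    bw <- net_backward(g, fw$cache, dout)
    st <- adam_step(g, lashgan:::grads_as_params(bw$grads), opt)
    g <- st$net; opt <- st$opt
  }
  expect_lt(l1, 0.05)
})

test_that("fit records one history row per epoch and is seed-reproducible", {
  pcfg <- desk_phantom(32L)
  ecfg <- desk_eyelash(32L, stroke_count_range = c(5, 8))
  paired <- build_paired_dataset(6, pcfg, ecfg, seed = 41)
  unpaired <- build_unpaired_dataset(4, 4, pcfg, ecfg, seed = 42)
  cfg <- tiny_train_config(variant = "full", epochs = 2L, rng_seed = 9L,
                           flip_probability = 0)

  r1 <- fit(paired, unpaired, cfg)
  expect_equal(nrow(r1$history), 2)
  expect_true(all(c("l_ca", "l_l1", "l_uca", "l_ref", "d1_loss", "d2_loss",
                    "val_psnr", "val_ssim") %in% names(r1$history)))

  r2 <- fit(paired, unpaired, cfg)
  expect_identical(r1$history, r2$history)
  expect_identical(net_params(r1$nets$g), net_params(r2$nets$g))

  # different seed: different initialization, different trajectory
  cfg2 <- tiny_train_config(variant = "full", epochs = 2L, rng_seed = 10L,
                            flip_probability = 0)
  r3 <- fit(paired, unpaired, cfg2)
  expect_false(identical(r1$history, r3$history))
})

test_that("variant gating controls which sub-networks exist and train", {
  pcfg <- desk_phantom(32L)
  ecfg <- desk_eyelash(32L, stroke_count_range = c(5, 8))
  paired <- build_paired_dataset(4, pcfg, ecfg, seed = 51)

  cfg_sub <- tiny_train_config(variant = "cgan_sub", epochs = 1L)
  r_sub <- fit(paired, NULL, cfg_sub)
  expect_null(r_sub$nets$r)
  expect_null(r_sub$nets$d2)
  expect_true(all(is.na(r_sub$history$l_ref)))
  expect_true(all(is.na(r_sub$history$l_uca)))

  cfg_ref <- tiny_train_config(variant = "cgan_ref", epochs = 1L,
                               rng_seed = 7L)
  set_global_seed(7)
  nets0 <- build_jcgan(cfg_ref)
  r0_hash <- lashgan:::param_checksum(net_params(nets0$r))
  r_ref <- fit(paired, NULL, cfg_ref, nets = nets0)
  expect_false(isTRUE(all.equal(
    r0_hash, lashgan:::param_checksum(net_params(r_ref$nets$r)))))
  expect_true(all(r_ref$history$l_ref >= 0))

  # a refiner present in the bundle is ignored (left untouched) when the
  # variant does not train it
  cfg_sub2 <- tiny_train_config(variant = "cgan_sub", epochs = 1L,
                                rng_seed = 7L)
  set_global_seed(7)
  nets1 <- build_jcgan(cfg_ref) # same init, includes r
  r1_hash <- lashgan:::param_checksum(net_params(nets1$r))
  r_sub2 <- fit(paired, NULL, cfg_sub2, nets = nets1)
  expect_identical(r1_hash,
                   lashgan:::param_checksum(net_params(r_sub2$nets$r)))

  expect_error(fit(paired, NULL, tiny_train_config(variant = "full")),
               "unpaired")
})
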