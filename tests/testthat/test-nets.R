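# Architecture contracts of the generator, refinement module and
# discriminators.

test_that("generator preserves spatial size and squashes output range", {
  set.seed(1)
  g <- build_generator(tiny_gen_spec())
  x <- array(runif(32 * 32 * 3, -1, 1), c(32, 32, 3))
  out <- net_forward(g, x)$out
  expect_identical(dim(out), c(32L, 32L, 3L, 1L))
  expect_lte(max(abs(out)), 1) # tanh contract

  # depth-5 bottleneck of a 32-pixel input is 1x1: encoder halves per layer
  fw <- net_forward(g, x, keep_cache = TRUE, training = TRUE)
  expect_identical(dim(fw$cache$enc[[5]]$y)[1:2], c(1L, 1L))
})

test_that("indivisible input sizes raise a shape error naming the factor", {
  g <- build_generator(tiny_gen_spec(depth = 5))
  x <- array(0, c(48, 48, 3))
  expect_error(net_forward(g, x), "divisible by 2\\^depth = 32")
})

test_that("refiner mirrors the generator and evaluation mode is deterministic", {
  set.seed(2)
  spec <- tiny_gen_spec()
  g <- build_generator(spec)
  r <- build_refiner(spec)
  expect_equal(r$param_count, g$param_count)

  x <- array(runif(32 * 32 * 3, -1, 1), c(32, 32, 3))
  y <- forward_restore(g, r, x)
  expect_identical(dim(y), dim(x))
  expect_true(all(is.finite(y)))
  expect_identical(y, forward_restore(g, r, x)) # bitwise eval determinism

  # ablation variants without a refiner return G(x)
  expect_identical(forward_restore(g, NULL, x),
                   drop_batch <- lashgan:::drop_batch(net_forward(g, x)$out))
})

test_that("discriminator map size follows closed-form conv arithmetic", {
  set.seed(3)
  d <- build_discriminator(discriminator_spec(FALSE, base_channels = 4))
  for (s in c(64L, 96L)) {
    x <- array(runif(s * s * 3, -1, 1), c(s, s, 3))
    out <- net_forward(d, x)$out
    expected <- oracle_disc_map_size(s)
    expect_identical(dim(out)[1:3], c(expected, expected, 1L))
    expect_true(all(out > 0 & out < 1)) # sigmoid confidence map
  }
})

test_that("conditional discriminator takes 6 channels and rejects 3", {
  set.seed(4)
  d1 <- build_discriminator(discriminator_spec(TRUE, base_channels = 4))
  x <- array(runif(64 * 64 * 3, -1, 1), c(64, 64, 3))
  y <- array(runif(64 * 64 * 3, -1, 1), c(64, 64, 3))
  pair <- lashgan:::concat_channels(lashgan:::as_batch(x),
                                    lashgan:::as_batch(y))
  out <- net_forward(d1, pair)$out
  expect_identical(dim(out)[3], 1L)
  expect_error(net_forward(d1, x), "channel")
})

test_that("every layer receives nonzero gradients from a scalar loss", {
  set.seed(5)
  g <- build_generator(tiny_gen_spec(noise = "none"))
  x <- array(runif(32 * 32 * 3 * 2, -1, 1), c(32, 32, 3, 2))
  fw <- net_forward(g, x, training = TRUE, keep_cache = TRUE)
  bw <- net_backward(g, fw$cache, array(1 / length(fw$out), dim(fw$out)))
  flat <- lashgan:::grads_as_params(bw$grads)
  wnorms <- vapply(flat[grep("\\.W$", names(flat))],
                   function(gr) sqrt(sum(gr^2)), numeric(1))
  expect_true(all(wnorms > 0))

  d <- build_discriminator(discriminator_spec(FALSE, base_channels = 4))
  fwd <- net_forward(d, x, training = TRUE, keep_cache = TRUE)
  bwd <- net_backward(d, fwd$cache,
                      array(1 / length(fwd$out), dim(fwd$out)))
  dflat <- lashgan:::disc_grads_as_params(bwd$grads)
  dnorms <- vapply(dflat[grep("\\.W$", names(dflat))],
                   function(gr) sqrt(sum(gr^2)), numeric(1))
  expect_true(all(dnorms > 0))
})

test_that("checkpoints round-trip networks and reject foreign files", {
  set.seed(6)
  nets <- list(g = build_generator(tiny_gen_spec()))
  path <- tempfile(fileext = ".rds")
  save_checkpoint(nets, path, meta = list(seed = 42))
  loaded <- load_checkpoint(path)
  expect_identical(net_params(loaded$nets$g), net_params(nets$g))
  expect_identical(loaded$meta$seed, 42)

  bogus <- tempfile(fileext = ".rds")
  saveRDS(list(a = 1), bogus)
  expect_error(load_checkpoint(bogus), "not a lashgan checkpoint")
})
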