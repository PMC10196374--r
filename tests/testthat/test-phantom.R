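# Synthetic fundus phantoms and eyelash artifact simulation.

test_that("phantom generation is deterministic and vessel-free mode is a pure gradient", {
  cfg <- desk_phantom()
  a <- generate_fundus_phantom(cfg, seed = 7)
  b <- generate_fundus_phantom(cfg, seed = 7)
  expect_identical(a, b)
  expect_false(identical(a, generate_fundus_phantom(cfg, seed = 8)))
  expect_true(all(a >= 0 & a <= 255))

  # no vessels, no noise: nothing stochastic remains, so any seed yields the
  # same deterministic elliptical gradient
  cfg0 <- desk_phantom(vessel_root_count = 0, texture_noise_sigma = 0)
  g1 <- generate_fundus_phantom(cfg0, seed = 1)
  g2 <- generate_fundus_phantom(cfg0, seed = 99)
  expect_identical(g1, g2)
})

test_that("pixels outside the elliptical field of view are near-black", {
  cfg <- desk_phantom(size = 96L)
  img <- generate_fundus_phantom(cfg, seed = 3)
  s <- cfg$image_size
  ys <- matrix(seq_len(s), s, s); xs <- t(ys)
  cx <- (s + 1) / 2
  outside <- ((xs - cx) / cfg$fov_axes[1])^2 +
    ((ys - cx) / cfg$fov_axes[2])^2 > 1
  expect_lt(mean(img[, , 1][outside]), 5)
  expect_lt(mean(img[, , 2][outside]), 5)
})

test_that("vessel width follows the decay recursion to branch depth", {
  cfg <- desk_phantom(size = 128L, branch_depth = 3, vessel_width_root = 8,
                      vessel_width_decay = 0.7)
  tree <- sample_vessel_tree(cfg, seed = 5)
  expect_setequal(unique(tree$depth), 1:3)
  for (d in 1:3)
    expect_equal(unique(tree$width[tree$depth == d]), 8 * 0.7^(d - 1))
  expect_equal(min(tree$width), 8 * 0.7^2) # deepest segment: 3.92 px
})

test_that("stroke sampling respects count bounds, determinism and geometry", {
  cfg <- desk_eyelash(stroke_count_range = c(0, 0))
  expect_length(sample_eyelash_strokes(cfg, 64, seed = 1), 0)

  cfg <- desk_eyelash(stroke_count_range = c(20, 40))
  s1 <- sample_eyelash_strokes(cfg, 64, seed = 11)
  s2 <- sample_eyelash_strokes(cfg, 64, seed = 11)
  expect_identical(s1, s2)
  expect_gte(length(s1), 20)
  expect_lte(length(s1), 40)

  # every root lies on a border, strokes point inward
  for (st in s1) {
    root <- st$control_points[1, ]
    expect_true(any(root == 1 | root == 64))
    expect_true(all(st$control_points[3, ] != root))
  }

  # zero curvature: middle control point collinear with the endpoints
  cfg0 <- desk_eyelash(curvature_range = c(0, 0))
  for (st in sample_eyelash_strokes(cfg0, 64, seed = 2)) {
    p <- st$control_points
    cross <- (p[2, 1] - p[1, 1]) * (p[3, 2] - p[1, 2]) -
             (p[2, 2] - p[1, 2]) * (p[3, 1] - p[1, 1])
    expect_lt(abs(cross), 1e-8)
  }

  expect_error(eyelash_config(stroke_count_range = c(5, 2)), "range")
})

test_that("stroke width decreases strictly from root to tip when tapered", {
  cfg <- desk_eyelash(width_taper = 0.4)
  st <- sample_eyelash_strokes(cfg, 64, seed = 4)[[1]]
  t <- seq(0, 1, length.out = 10)
  w <- st$width_root * (1 - (1 - st$width_taper) * t)
  expect_true(all(diff(w) < 0))
  expect_equal(w[10], st$width_root * st$width_taper)
})

test_that("artifact layer rendering matches an independent rasterization oracle", {
  cfg <- desk_eyelash(blur_sigma = 0, halo_opacity = 0)

  empty <- render_artifact_layer(list(), 64, cfg)
  expect_true(all(empty$alpha == 0))
  expect_false(any(empty$mask))

  # one opaque straight stroke, no blur/halo: mask support equals the exact
  # capsule (point-to-segment distance) support
  p0 <- c(10, 1); p1 <- c(40, 55); w <- 3
  stroke <- list(control_points = rbind(p0, (p0 + p1) / 2, p1),
                 width_root = w, width_taper = 1, opacity = 1,
                 length = sqrt(sum((p1 - p0)^2)))
  layer <- render_artifact_layer(list(stroke), 64, cfg)
  expect_equal(sum(layer$mask),
               oracle_straight_stroke_support(p0, p1, w, 64,
                                              cfg$mask_threshold))

  # clipping contract under many overlapping opaque strokes
  cfgh <- desk_eyelash(halo_opacity = 0.5)
  strokes <- sample_eyelash_strokes(cfgh, 64, seed = 9)
  lay <- render_artifact_layer(strokes, 64, cfgh)
  expect_lte(max(lay$alpha), 1)
  expect_gte(min(lay$alpha), 0)
})

test_that("compositing follows the linear blend law and never brightens", {
  cfg <- desk_eyelash()
  clean <- random_image(32)

  expect_identical(composite_artifact(clean, matrix(0, 32, 32), cfg), clean)

  cfg_black <- desk_eyelash(shade_color = c(0, 0, 0))
  dark <- composite_artifact(clean, matrix(1, 32, 32), cfg_black)
  expect_true(all(dark == 0))

  # blend arithmetic: alpha 0.5, clean 200, shade 20 -> 110
  cfg20 <- desk_eyelash(shade_color = c(20, 20, 20))
  const <- array(200, c(8, 8, 3))
  out <- composite_artifact(const, matrix(0.5, 8, 8), cfg20)
  expect_equal(unique(as.numeric(out)), 110)

  # conservation: a dark shade can only darken
  a <- matrix(runif(32 * 32), 32, 32)
  shaded <- composite_artifact(clean, a, cfg_black)
  expect_true(all(shaded <= clean + 1e-12))

  expect_error(composite_artifact(clean, matrix(0, 8, 8), cfg), "mismatch")
})

test_that("paired datasets are reproducible and exact off-artifact", {
  pcfg <- desk_phantom(48L)
  # moderate density so that zero-alpha pixels exist and the off-artifact
  # identity is exercised non-vacuously
  ecfg <- desk_eyelash(48L, stroke_count_range = c(5, 9))
  d1 <- build_paired_dataset(3, pcfg, ecfg, seed = 21)
  d2 <- build_paired_dataset(3, pcfg, ecfg, seed = 21)
  expect_identical(d1, d2)
  expect_identical(vapply(d1, `[[`, "", "sample_id"),
                   c("00001", "00002", "00003"))

  for (s in d1) {
    off <- s$alpha == 0
    expect_gt(sum(off), 0)
    for (ch in 1:3)
      expect_identical(s$corrupted[, , ch][off], s$clean[, , ch][off])
  }

  # growing the dataset preserves earlier samples (per-sample derived seeds)
  d5 <- build_paired_dataset(5, pcfg, ecfg, seed = 21)
  expect_identical(d5[1:3], d1)

  expect_error(build_paired_dataset(0, pcfg, ecfg), ">= 1")
})

test_that("mask coverage is controlled by the stroke count", {
  pcfg <- desk_phantom(48L)
  frac_for <- function(count_range, seed) {
    ecfg <- desk_eyelash(48L, stroke_count_range = count_range)
    strokes <- sample_eyelash_strokes(ecfg, 48, seed = seed)
    mean(render_artifact_layer(strokes, 48, ecfg)$mask)
  }
  seeds <- 1:20
  low <- mean(vapply(seeds, function(s) frac_for(c(3, 6), s), numeric(1)))
  mid <- mean(vapply(seeds, function(s) frac_for(c(10, 16), s), numeric(1)))
  high <- mean(vapply(seeds, function(s) frac_for(c(24, 32), s), numeric(1)))
  expect_true(low < mid && mid < high)
})

test_that("unpaired pools are disjoint from each other and reproducible", {
  pcfg <- desk_phantom(48L)
  ecfg <- desk_eyelash(48L)
  up1 <- build_unpaired_dataset(3, 3, pcfg, ecfg, seed = 31)
  up2 <- build_unpaired_dataset(3, 3, pcfg, ecfg, seed = 31)
  expect_identical(up1, up2)

  cseeds <- vapply(up1$corrupted, `[[`, integer(1), "phantom_seed")
  clseeds <- vapply(up1$clean, `[[`, integer(1), "phantom_seed")
  expect_length(intersect(cseeds, clseeds), 0)

  # the clean pool is artifact-free by construction: regenerating the
  # phantom from its recorded seed reproduces it exactly
  s <- up1$clean[[1]]
  expect_identical(s$clean, generate_fundus_phantom(pcfg, s$phantom_seed))

  expect_error(build_unpaired_dataset(0, 1, pcfg, ecfg), ">= 1")
})
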