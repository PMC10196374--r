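# Image-quality metrics: MSE/PSNR, SSIM, ENL.

test_that("mse satisfies its anchors and matches the brute-force oracle", {
  a <- random_image(16)
  expect_equal(mse(a, a), 0)
  expect_equal(mse(array(0, c(4, 4, 3)), array(255, c(4, 4, 3))), 65025)
  set.seed(20)
  b <- random_image(16)
  expect_equal(mse(a, b), oracle_mse(a, b), tolerance = 1e-9)
  expect_equal(mse(a, b), mse(b, a))
  expect_error(mse(a, random_image(8)), "mismatch")
})

test_that("psnr follows the 10*log10(peak^2/MSE) form", {
  a <- random_image(16)
  expect_identical(psnr(a, a), Inf)

  # unit difference everywhere: MSE 1, PSNR = 20 log10(255)
  b <- a + 1
  expect_equal(psnr(a, b), 20 * log10(255), tolerance = 1e-12)

  # halving the MSE raises PSNR by 10 log10 2
  expect_equal(psnr(a, a + sqrt(0.5)) - psnr(a, b), 10 * log10(2),
               tolerance = 1e-9)

  # monotone decreasing in MSE
  ps <- vapply(c(1, 2, 5, 10), function(d) psnr(a, a + d), numeric(1))
  expect_true(all(diff(ps) < 0))
})

test_that("ssim identity, range, symmetry and zero-variance closed form", {
  set.seed(21)
  a <- random_image(32)
  expect_equal(ssim(a, a), 1)

  for (i in 1:10) {
    x <- random_image(16); y <- random_image(16)
    v <- ssim(x, y)
    expect_gte(v, -1); expect_lte(v, 1)
    expect_identical(v, ssim(y, x))
  }

  # two constant images: variances vanish, formula reduces to the luminance
  # term (hand arithmetic with c1 = (0.01*255)^2, c2 = (0.02*255)^2)
  mu_a <- 100; mu_b <- 140
  ca <- array(mu_a, c(8, 8, 3)); cb <- array(mu_b, c(8, 8, 3))
  c1 <- (0.01 * 255)^2; c2 <- (0.02 * 255)^2
  expected <- ((2 * mu_a * mu_b + c1) * c2) /
    ((mu_a^2 + mu_b^2 + c1) * c2)
  expect_equal(ssim(ca, cb), expected, tolerance = 1e-12)
})

test_that("global ssim matches the independent oracle; windowed mode matches
           a direct sliding-window computation", {
  set.seed(22)
  for (i in 1:5) {
    a <- random_image(24); b <- random_image(24)
    expect_equal(ssim(a, b), oracle_ssim_global(a, b), tolerance = 1e-9)
  }

  a <- random_image(16, 1); b <- random_image(16, 1)
  w <- 5L
  c1 <- (0.01 * 255)^2; c2 <- (0.02 * 255)^2
  direct <- c()
  for (i in 1:(16 - w + 1)) for (j in 1:(16 - w + 1)) {
    x <- a[i:(i + w - 1), j:(j + w - 1), 1]
    y <- b[i:(i + w - 1), j:(j + w - 1), 1]
    direct <- c(direct, oracle_ssim_global(array(x, c(w, w, 1)),
                                           array(y, c(w, w, 1))))
  }
  expect_equal(ssim(a, b, mode = "windowed", window = w), mean(direct),
               tolerance = 1e-9)
})

test_that("enl anchors: zero-variance sentinel, two-value region, smoothing", {
  img <- array(50, c(16, 16, 3))
  region <- matrix(TRUE, 16, 16)
  expect_identical(enl(img, region), Inf)

  # region of {8, 12} equally frequent: mu = 10, population var = 4, ENL = 25
  vals <- matrix(rep(c(8, 12), 128), 16, 16)
  img2 <- array(rep(vals, 3), c(16, 16, 3))
  expect_equal(enl(img2, region), 25)

  # smoothing a noisy region raises ENL
  set.seed(23)
  noisy <- array(100 + rnorm(32 * 32 * 3, sd = 20), c(32, 32, 3))
  smooth <- noisy
  for (ch in 1:3) smooth[, , ch] <- gaussian_blur(noisy[, , ch], 2)
  reg <- matrix(FALSE, 32, 32); reg[8:25, 8:25] <- TRUE
  expect_gt(enl(smooth, reg), enl(noisy, reg))

  # scale invariance: both mu and sigma scale by c
  expect_equal(enl(noisy * 3.7, reg), enl(noisy, reg), tolerance = 1e-12)

  small <- matrix(FALSE, 32, 32); small[1:4, 1:4] <- TRUE
  expect_error(enl(noisy, small), "min_region_pixels")
})

test_that("enl_delta_report tabulates per-region deltas plus a summary row", {
  set.seed(24)
  before <- array(100 + rnorm(32 * 32 * 3, sd = 15), c(32, 32, 3))
  after <- before
  for (ch in 1:3) after[, , ch] <- gaussian_blur(before[, , ch], 2)
  r1 <- matrix(FALSE, 32, 32); r1[4:15, 4:15] <- TRUE
  r2 <- matrix(FALSE, 32, 32); r2[18:30, 18:30] <- TRUE

  same <- enl_delta_report(before, before, list(r1, r2))
  expect_equal(nrow(same), 3) # 2 regions + summary
  expect_true(all(same$delta[1:2] == 0))

  rep2 <- enl_delta_report(before, after, list(r1, r2))
  expect_true(all(rep2$delta[1:2] > 0))
  expect_equal(rep2$delta[3], 2) # both regions improved
})
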