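# Shared fixtures: small configs, tiny networks, and independent brute-force
# metric oracles (direct formula transcriptions kept deliberately separate
# from the package's implementation paths).

desk_phantom <- function(size = 64L, ...) phantom_config(image_size = size, ...)
desk_eyelash <- function(size = 64L, ...) eyelash_config(image_size = size, ...)

tiny_gen_spec <- function(depth = 5L, base = 4L, cap = 16L,
                          noise = "dropout") {
  generator_spec(depth = depth, base_channels = base, channel_cap = cap,
                 noise_mode = noise)
}

tiny_train_config <- function(..., epochs = 2L) {
  train_config(image_size = 32L, depth = 5L, base_channels = 4L,
               channel_cap = 16L, disc_base_channels = 8L, batch_size = 2L,
               epochs = epochs, ...)
}

random_image <- function(size = 64L, channels = 3L) {
  array(runif(size * size * channels, 0, 255), c(size, size, channels))
}

# ---- independent metric oracles (explicit elementwise transcriptions) ------

oracle_mse <- function(a, b) {
  s <- 0
  av <- as.numeric(a); bv <- as.numeric(b)
  for (i in seq_along(av)) s <- s + (av[i] - bv[i])^2
  s / length(av)
}

oracle_psnr <- function(a, b, bit_depth = 8) {
  m <- oracle_mse(a, b)
  if (m == 0) return(Inf)
  10 * log10((2^bit_depth - 1)^2 / m)
}

oracle_ssim_global <- function(a, b, k1 = 0.01, k2 = 0.02, L = 255) {
  per_channel <- function(x, y) {
    n <- length(x)
    mx <- sum(x) / n; my <- sum(y) / n
    vx <- sum((x - mx)^2) / n
    vy <- sum((y - my)^2) / n
    cxy <- sum((x - mx) * (y - my)) / n
    c1 <- (k1 * L)^2; c2 <- (k2 * L)^2
    ((2 * mx * my + c1) * (2 * cxy + c2)) /
      ((mx^2 + my^2 + c1) * (vx + vy + c2))
  }
  vals <- vapply(seq_len(dim(a)[3]), function(ch)
    per_channel(as.numeric(a[, , ch]), as.numeric(b[, , ch])), numeric(1))
  mean(vals)
}

oracle_bce_d <- function(p_real, p_fake) {
  0.5 * (mean(-log(p_real)) + mean(-log(1 - p_fake)))
}

# closed-form convolution output-size arithmetic
oracle_conv_size <- function(s, k, stride, pad) floor((s + 2 * pad - k) / stride) + 1

oracle_disc_map_size <- function(s, strides = c(2, 2, 2, 1, 1), k = 4, pad = 1) {
  for (st in strides) s <- oracle_conv_size(s, k, st, pad)
  as.integer(s)
}

# exact point-to-segment-distance rasterization of a straight constant-width
# stroke (independent of the package's bounding-box polyline path)
oracle_straight_stroke_support <- function(p0, p1, width, size, threshold) {
  ys <- matrix(seq_len(size), size, size)
  xs <- matrix(seq_len(size), size, size, byrow = TRUE)
  dx <- p1[1] - p0[1]; dy <- p1[2] - p0[2]
  len2 <- dx^2 + dy^2
  t <- pmin(pmax(((xs - p0[1]) * dx + (ys - p0[2]) * dy) / len2, 0), 1)
  dist <- sqrt((xs - (p0[1] + t * dx))^2 + (ys - (p0[2] + t * dy))^2)
  cov <- pmin(pmax(width / 2 + 0.5 - dist, 0), 1)
  sum(cov > threshold)
}
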