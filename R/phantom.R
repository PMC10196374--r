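# Synthetic UWF fundus phantoms and eyelash artifact simulation.
#
# Real paired corrupted/clean UWF data are not redistributable, so the
# package generates its own study material: elliptical bright fields with a
# radial gradient and a recursively branching dark vessel tree stand in for
# the fundus, and dark, curved, semi-transparent strokes entering from the
# image borders stand in for eyelash shadows. Every sample carries an exact
# ground-truth artifact mask, which also provides the local regions for ENL
# evaluation.

#' Fundus phantom configuration
#'
#' @param image_size side length in pixels of the square phantom. The full
#'   regime uses 1024 (the training patch size for 3900 x 3072 UWF frames);
#'   the small desk regime defaults to 256. Any size divisible by `2^depth`
#'   of the network that will consume it is admissible.
#' @param fov_axes semi-axes (pixels) of the elliptical field of view;
#'   defaults to 47% of the image size. Pixels outside the ellipse are
#'   near-black.
#' @param background_base_color RGB triple in `[0, 255]`; the warm orange of
#'   scanning-laser fundus composites.
#' @param background_gradient_strength radial darkening toward the FOV rim,
#'   in `[0, 1]`.
#' @param vessel_root_count number of vessel trees rooted near the optic
#'   disc.
#' @param branch_depth recursion depth of the vessel tree.
#' @param vessel_width_root root vessel width in pixels.
#' @param vessel_width_decay child width = parent width x decay, in (0, 1).
#' @param vessel_darkening multiplicative darkening of vessel pixels, (0, 1).
#' @param texture_noise_sigma sd (intensity units) of additive texture noise.
#' @param rng_seed default seed used when an operation is not given one.
#' @return object of class `phantom_config`.
#' @export
phantom_config <- function(image_size = 256L,
                           fov_axes = NULL,
                           background_base_color = c(205, 120, 55),
                           background_gradient_strength = 0.35,
                           vessel_root_count = 4L,
                           branch_depth = 4L,
                           vessel_width_root = NULL,
                           vessel_width_decay = 0.65,
                           vessel_darkening = 0.55,
                           texture_noise_sigma = 4,
                           rng_seed = 1L) {
  image_size <- as.integer(image_size)
  if (image_size < 8L) stop("image_size too small", call. = FALSE)
  if (is.null(fov_axes)) fov_axes <- rep(round(0.47 * image_size), 2L)
  if (any(fov_axes > image_size / 2))
    stop("fov_axes must not exceed image_size/2", call. = FALSE)
  if (is.null(vessel_width_root))
    vessel_width_root <- max(2, round(8 * image_size / 1024))
  if (branch_depth < 1L) stop("branch_depth must be >= 1", call. = FALSE)
  if (vessel_width_decay <= 0 || vessel_width_decay >= 1)
    stop("vessel_width_decay must lie in (0, 1)", call. = FALSE)
  structure(list(
    image_size = image_size, fov_axes = fov_axes,
    background_base_color = background_base_color,
    background_gradient_strength = background_gradient_strength,
    vessel_root_count = as.integer(vessel_root_count),
    branch_depth = as.integer(branch_depth),
    vessel_width_root = vessel_width_root,
    vessel_width_decay = vessel_width_decay,
    vessel_darkening = vessel_darkening,
    texture_noise_sigma = texture_noise_sigma,
    rng_seed = as.integer(rng_seed)
  ), class = "phantom_config")
}

#' Eyelash stroke configuration
#'
#' Eyelash shadows are modeled as quadratic Bezier strokes rooted on the
#' image border (mostly top and bottom, since eyelids are superior/inferior),
#' pointing inward, with tapering width, partial opacity, a Gaussian-blurred
#' soft edge and a faint halo. The stroke model is an invented stand-in with
#' declared parameters, not a reproduction of any published eyelash-growth
#' model.
#'
#' @param image_size reference size in pixels; pixel-valued defaults below
#'   scale with it.
#' @param stroke_count_range inclusive integer range of strokes per image.
#' @param root_edge_weights probability of rooting a stroke on the
#'   top/bottom/left/right border (length 4, normalized internally).
#' @param length_range stroke arc length range in pixels.
#' @param curvature_range bend of the Bezier as a fraction of stroke length.
#' @param width_root_range stroke root width range in pixels.
#' @param width_taper tip width as a fraction of root width, in (0, 1].
#' @param opacity_range per-stroke opacity range in `[0, 1]`.
#' @param shade_color dark RGB triple composited over the fundus.
#' @param blur_sigma Gaussian blur (pixels) of the stroke alpha map.
#' @param halo_opacity strength of the blurred halo added around strokes.
#' @param mask_threshold alpha level above which a pixel belongs to the
#'   ground-truth artifact mask.
#' @param rng_seed default seed.
#' @return object of class `eyelash_config`.
#' @export
eyelash_config <- function(image_size = 256L,
                           stroke_count_range = c(20L, 40L),
                           root_edge_weights = c(0.45, 0.45, 0.05, 0.05),
                           length_range = round(c(0.35, 0.85) * image_size),
                           curvature_range = c(0.05, 0.25),
                           width_root_range = pmax(c(3, 10) * image_size / 1024,
                                                   c(1.2, 2.5)),
                           width_taper = 0.35,
                           opacity_range = c(0.55, 0.95),
                           shade_color = c(12, 8, 8),
                           blur_sigma = max(0.6, 1.5 * image_size / 1024),
                           halo_opacity = 0.12,
                           mask_threshold = 0.05,
                           rng_seed = 1L) {
  chk_range <- function(r, name, lo = -Inf, hi = Inf) {
    if (length(r) != 2L || any(is.na(r)) || r[1] > r[2])
      stop("invalid (empty or unordered) range for ", name, call. = FALSE)
    if (r[1] < lo || r[2] > hi)
      stop(name, " out of admissible bounds", call. = FALSE)
    r
  }
  chk_range(stroke_count_range, "stroke_count_range", lo = 0)
  chk_range(length_range, "length_range", lo = 1)
  chk_range(curvature_range, "curvature_range", lo = 0)
  chk_range(width_root_range, "width_root_range", lo = 0.1)
  chk_range(opacity_range, "opacity_range", lo = 0, hi = 1)
  if (width_taper <= 0 || width_taper > 1)
    stop("width_taper must lie in (0, 1]", call. = FALSE)
  if (length(root_edge_weights) != 4L || any(root_edge_weights < 0) ||
      sum(root_edge_weights) <= 0)
    stop("root_edge_weights must be 4 non-negative weights", call. = FALSE)
  structure(list(
    image_size = as.integer(image_size),
    stroke_count_range = as.integer(stroke_count_range),
    root_edge_weights = root_edge_weights / sum(root_edge_weights),
    length_range = length_range, curvature_range = curvature_range,
    width_root_range = width_root_range, width_taper = width_taper,
    opacity_range = opacity_range, shade_color = shade_color,
    blur_sigma = blur_sigma, halo_opacity = halo_opacity,
    mask_threshold = mask_threshold, rng_seed = as.integer(rng_seed)
  ), class = "eyelash_config")
}

# ---- vessel tree ------------------------------------------------------------

#' Sample a branching vessel tree
#'
#' Recursive binary branching from roots placed around a virtual optic disc:
#' each child's width is the parent's width times `vessel_width_decay`, down
#' to `branch_depth` levels.
#'
#' @param config a [phantom_config()].
#' @param seed integer seed.
#' @return tibble of segments with columns `x0, y0, x1, y1, width, depth`.
#' @export
sample_vessel_tree <- function(config, seed = config$rng_seed) {
  stopifnot(inherits(config, "phantom_config"))
  with_seed(seed, {
    s <- config$image_size
    cx <- s / 2 + runif(1, -0.15, 0.15) * s
    cy <- s / 2 + runif(1, -0.1, 0.1) * s
    segs <- list()
    grow <- function(x, y, angle, width, depth) {
      len <- runif(1, 0.10, 0.18) * s * (0.8 + 0.4 / depth)
      x1 <- x + len * cos(angle)
      y1 <- y + len * sin(angle)
      segs[[length(segs) + 1L]] <<-
        c(x, y, x1, y1, width, depth)
      if (depth < config$branch_depth) {
        dw <- width * config$vessel_width_decay
        grow(x1, y1, angle + runif(1, 0.25, 0.7), dw, depth + 1L)
        grow(x1, y1, angle - runif(1, 0.25, 0.7), dw, depth + 1L)
      }
    }
    if (config$vessel_root_count > 0) {
      for (i in seq_len(config$vessel_root_count)) {
        ang <- 2 * pi * (i - 1) / config$vessel_root_count +
          runif(1, -0.3, 0.3)
        grow(cx, cy, ang, config$vessel_width_root, 1L)
      }
    }
    if (length(segs) == 0L)
      return(tibble::tibble(x0 = numeric(), y0 = numeric(), x1 = numeric(),
                            y1 = numeric(), width = numeric(),
                            depth = integer()))
    m <- do.call(rbind, segs)
    tibble::tibble(x0 = m[, 1], y0 = m[, 2], x1 = m[, 3], y1 = m[, 4],
                   width = m[, 5], depth = as.integer(m[, 6]))
  })
}

# soft coverage (0..1) of thick segments over an image plane
rasterize_segments <- function(segments, size) {
  cov <- matrix(0, size, size)
  if (nrow(segments) == 0L) return(cov)
  for (i in seq_len(nrow(segments))) {
    x0 <- segments$x0[i]; y0 <- segments$y0[i]
    x1 <- segments$x1[i]; y1 <- segments$y1[i]
    w <- segments$width[i]
    r <- w / 2 + 1
    rlo <- clamp(floor(min(y0, y1) - r), 1, size)
    rhi <- clamp(ceiling(max(y0, y1) + r), 1, size)
    clo <- clamp(floor(min(x0, x1) - r), 1, size)
    chi <- clamp(ceiling(max(x0, x1) + r), 1, size)
    if (rlo > rhi || clo > chi) next
    ys <- rlo:rhi; xs <- clo:chi
    py <- matrix(ys, length(ys), length(xs))
    px <- matrix(xs, length(ys), length(xs), byrow = TRUE)
    dx <- x1 - x0; dy <- y1 - y0
    len2 <- dx * dx + dy * dy
    t <- if (len2 > 0) clamp(((px - x0) * dx + (py - y0) * dy) / len2, 0, 1)
         else 0 * px
    dist <- sqrt((px - (x0 + t * dx))^2 + (py - (y0 + t * dy))^2)
    c_local <- clamp(w / 2 + 0.5 - dist, 0, 1)
    cov[ys, xs] <- pmax(cov[ys, xs], c_local)
  }
  cov
}

# ---- phantom ----------------------------------------------------------------

#' Generate a clean fundus phantom
#'
#' Deterministic for fixed `(config, seed)`: an elliptical bright field with
#' a radial gradient, additive texture noise, and a branching dark vessel
#' tree; pixels outside the field of view are near-black.
#'
#' @param config a [phantom_config()].
#' @param seed integer seed.
#' @return (H, W, 3) numeric array with values in `[0, 255]`.
#' @export
generate_fundus_phantom <- function(config, seed = config$rng_seed) {
  stopifnot(inherits(config, "phantom_config"))
  s <- config$image_size
  cx <- (s + 1) / 2; cy <- (s + 1) / 2
  ys <- matrix(seq_len(s), s, s)          # row = y
  xs <- matrix(seq_len(s), s, s, byrow = TRUE)
  rr <- ((xs - cx) / config$fov_axes[1])^2 + ((ys - cy) / config$fov_axes[2])^2
  fov <- clamp((1 - sqrt(rr)) * config$fov_axes[1] * 0.5 + 0.5, 0, 1)
  grad <- 1 - config$background_gradient_strength * clamp(rr, 0, 1)

  tree <- sample_vessel_tree(config, seed)
  vcov <- rasterize_segments(tree, s)
  vessel_factor <- 1 - config$vessel_darkening * vcov

  noise <- if (config$texture_noise_sigma > 0)
    with_seed(derive_seed(seed, 2L, stream = 11L),
              matrix(rnorm(s * s, sd = config$texture_noise_sigma), s, s))
  else matrix(0, s, s)

  img <- array(0, c(s, s, 3L))
  floor_level <- 2 # near-black surround
  for (ch in 1:3) {
    base <- config$background_base_color[ch] * grad * vessel_factor + noise
    img[, , ch] <- clamp(base * fov + floor_level * (1 - fov), 0, 255)
  }
  img
}

# ---- eyelash strokes --------------------------------------------------------

#' Sample eyelash strokes
#'
#' Draws a seeded set of quadratic Bezier strokes rooted on image borders
#' and pointing inward.
#'
#' @param config an [eyelash_config()].
#' @param image_size image side length in pixels.
#' @param seed integer seed.
#' @return list of strokes; each stroke has `control_points` (3 x 2 matrix
#'   of (x, y)), `width_root`, `width_taper`, `opacity`, `length`.
#' @export
sample_eyelash_strokes <- function(config, image_size = config$image_size,
                                   seed = config$rng_seed) {
  stopifnot(inherits(config, "eyelash_config"))
  with_seed(seed, {
    n <- if (diff(config$stroke_count_range) == 0) config$stroke_count_range[1]
         else sample(config$stroke_count_range[1]:config$stroke_count_range[2], 1)
    strokes <- vector("list", n)
    if (n == 0L) return(strokes)
    s <- image_size
    for (i in seq_len(n)) {
      edge <- sample(1:4, 1, prob = config$root_edge_weights)
      u <- runif(1, 0.05, 0.95) * s
      # root point on the border and the inward normal direction
      root <- switch(edge, c(u, 1), c(u, s), c(1, u), c(s, u))
      normal <- switch(edge, c(0, 1), c(0, -1), c(1, 0), c(-1, 0))
      ang <- atan2(normal[2], normal[1]) + runif(1, -0.9, 0.9)
      len <- runif(1, config$length_range[1], config$length_range[2])
      tip <- root + len * c(cos(ang), sin(ang))
      curv <- runif(1, config$curvature_range[1], config$curvature_range[2]) *
        sample(c(-1, 1), 1)
      perp <- c(-sin(ang), cos(ang))
      mid <- (root + tip) / 2 + curv * len * perp
      strokes[[i]] <- list(
        control_points = rbind(root, mid, tip),
        width_root = runif(1, config$width_root_range[1],
                           config$width_root_range[2]),
        width_taper = config$width_taper,
        opacity = runif(1, config$opacity_range[1], config$opacity_range[2]),
        length = len
      )
    }
    strokes
  })
}

bezier_points <- function(P, n) {
  t <- seq(0, 1, length.out = n)
  b0 <- (1 - t)^2; b1 <- 2 * t * (1 - t); b2 <- t^2
  cbind(b0 * P[1, 1] + b1 * P[2, 1] + b2 * P[3, 1],
        b0 * P[1, 2] + b1 * P[2, 2] + b2 * P[3, 2])
}

# coverage map of a single tapered stroke (exact distance to the sampled
# polyline within a bounding box)
rasterize_stroke <- function(stroke, size) {
  P <- stroke$control_points
  n <- max(8L, as.integer(ceiling(stroke$length)))
  pts <- bezier_points(P, n)
  t <- seq(0, 1, length.out = n)
  widths <- stroke$width_root * (1 - (1 - stroke$width_taper) * t)
  segs <- tibble::tibble(
    x0 = pts[-n, 1], y0 = pts[-n, 2], x1 = pts[-1, 1], y1 = pts[-1, 2],
    width = (widths[-n] + widths[-1]) / 2, depth = 1L
  )
  rasterize_segments(segs, size)
}

#' Render the artifact alpha layer and ground-truth mask
#'
#' Rasterizes each stroke with its tapering width, scales by per-stroke
#' opacity, combines strokes with over-compositing, optionally blurs the
#' union, and adds a faint blurred halo. The ground-truth artifact mask is
#' `alpha > mask_threshold`.
#'
#' @param strokes list from [sample_eyelash_strokes()].
#' @param image_size side length in pixels.
#' @param config an [eyelash_config()].
#' @return `list(alpha, mask)`: alpha a matrix in `[0, 1]`, mask logical.
#' @export
render_artifact_layer <- function(strokes, image_size, config) {
  stopifnot(inherits(config, "eyelash_config"))
  alpha <- matrix(0, image_size, image_size)
  one_minus <- matrix(1, image_size, image_size)
  for (st in strokes) {
    a <- rasterize_stroke(st, image_size) * st$opacity
    one_minus <- one_minus * (1 - a)
  }
  alpha <- 1 - one_minus
  if (length(strokes) > 0 && config$blur_sigma > 0)
    alpha <- gaussian_blur(alpha, config$blur_sigma)
  if (length(strokes) > 0 && config$halo_opacity > 0) {
    halo <- config$halo_opacity *
      gaussian_blur(alpha, max(2, 3 * config$blur_sigma))
    alpha <- alpha + halo * (1 - alpha)
  }
  alpha <- clamp(alpha, 0, 1)
  list(alpha = alpha, mask = alpha > config$mask_threshold)
}

#' Composite an artifact layer over a clean image
#'
#' Linear alpha compositing with a dark shade:
#' `corrupted = (1 - alpha) * clean + alpha * shade_color`, per pixel and
#' channel, on the 8-bit scale. Wherever `alpha = 0` the clean image passes
#' through bitwise.
#'
#' @param clean (H, W, 3) array in `[0, 255]`.
#' @param alpha (H, W) matrix in `[0, 1]`.
#' @param config an [eyelash_config()] (supplies `shade_color`).
#' @return corrupted image, same shape as `clean`, values in `[0, 255]`.
#' @export
composite_artifact <- function(clean, alpha, config) {
  check_image(clean, "clean")
  if (!identical(dim(clean)[1:2], dim(alpha)))
    stop("shape mismatch: alpha must match the image plane", call. = FALSE)
  out <- clean
  for (ch in seq_len(dim(clean)[3]))
    out[, , ch] <- (1 - alpha) * clean[, , ch] + alpha * config$shade_color[ch]
  clamp(out, 0, 255)
}

# ---- datasets ---------------------------------------------------------------

make_one_pair <- function(phantom_cfg, eyelash_cfg, phantom_seed, lash_seed,
                          sample_id) {
  clean <- generate_fundus_phantom(phantom_cfg, phantom_seed)
  strokes <- sample_eyelash_strokes(eyelash_cfg, phantom_cfg$image_size,
                                    lash_seed)
  layer <- render_artifact_layer(strokes, phantom_cfg$image_size, eyelash_cfg)
  corrupted <- composite_artifact(clean, layer$alpha, eyelash_cfg)
  list(corrupted = corrupted, clean = clean, mask = layer$mask,
       alpha = layer$alpha, sample_id = sample_id,
       phantom_seed = phantom_seed, lash_seed = lash_seed)
}

#' Build a paired corrupted/clean dataset
#'
#' Each sample couples a clean phantom, its eyelash-corrupted version and the
#' ground-truth artifact mask. Per-sample seeds are derived from the master
#' seed and the sample index, so the dataset is extensible without
#' reshuffling existing samples.
#'
#' @param n number of pairs (>= 1).
#' @param phantom_cfg a [phantom_config()].
#' @param eyelash_cfg an [eyelash_config()].
#' @param seed master seed.
#' @return list of paired samples (fields `corrupted`, `clean`, `mask`,
#'   `alpha`, `sample_id`, and the derived seeds).
#' @export
build_paired_dataset <- function(n, phantom_cfg, eyelash_cfg, seed = 1L) {
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  lapply(seq_len(n), function(i) {
    make_one_pair(phantom_cfg, eyelash_cfg,
                  phantom_seed = derive_seed(seed, i, stream = 1L),
                  lash_seed = derive_seed(seed, i, stream = 2L),
                  sample_id = sprintf("%05d", i))
  })
}

#' Build unpaired corrupted and clean pools
#'
#' The corrupted pool and the clean pool are generated from disjoint phantom
#' seed streams, so no clean image is the underlying phantom of any
#' corrupted image: there is no hidden pairing.
#'
#' @param n_corrupted,n_clean pool sizes (>= 1).
#' @inheritParams build_paired_dataset
#' @return `list(corrupted, clean)`: the corrupted pool holds full paired
#'   sample structures (its masks are available for evaluation); the clean
#'   pool holds artifact-free images with their phantom seeds.
#' @export
build_unpaired_dataset <- function(n_corrupted, n_clean, phantom_cfg,
                                   eyelash_cfg, seed = 1L) {
  if (n_corrupted < 1 || n_clean < 1)
    stop("pool sizes must be >= 1", call. = FALSE)
  corrupted <- lapply(seq_len(n_corrupted), function(i) {
    make_one_pair(phantom_cfg, eyelash_cfg,
                  phantom_seed = derive_seed(seed, i, stream = 3L),
                  lash_seed = derive_seed(seed, i, stream = 4L),
                  sample_id = sprintf("u%05d", i))
  })
  clean <- lapply(seq_len(n_clean), function(i) {
    ps <- derive_seed(seed, i, stream = 5L)
    list(clean = generate_fundus_phantom(phantom_cfg, ps),
         sample_id = sprintf("c%05d", i), phantom_seed = ps)
  })
  list(corrupted = corrupted, clean = clean)
}
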