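# Synthetic SWI-like phantom slices with ground-truth lesion masks.
#
# A phantom emulates what makes micro-lesion segmentation hard on real
# susceptibility-weighted slices: small ovoid hypointense lesions (< 10 mm
# equivalent diameter) on a smoothly textured brain-like background, plus
# thin dark curvilinear structures that mimic veins and are NOT part of the
# ground truth. It does not simulate MR susceptibility physics; geometry and
# contrast are the emulated properties.

#' Phantom generator configuration
#'
#' Defaults describe the desk-scale study conditions used throughout the
#' package: 96x128 slices at 0.5 mm/pixel, 1-4 lesions per slice with
#' equivalent diameters of 2-6 mm (clinical microbleeds are < 10 mm, mostly
#' 2-5 mm), mild eccentricity, strong hypointense contrast, and up to three
#' vein-like mimics.
#'
#' @param image_height,image_width Slice size in pixels.
#' @param pixel_spacing_mm In-plane pixel spacing (mm/pixel).
#' @param lesions_per_image_range Integer interval (inclusive) of lesion
#'   counts per slice.
#' @param lesion_diameter_range_mm Interval of lesion *equivalent* diameters
#'   in mm; the upper bound must be strictly below 10 mm.
#' @param lesion_eccentricity_range Interval in `[0, 1)` of ellipse
#'   eccentricities.
#' @param lesion_contrast_range Interval of negative intensity offsets
#'   (fraction of the intensity scale) applied at the lesion core.
#' @param n_mimics_range Integer interval of vein-like dark curves per slice;
#'   mimics darken the image but contribute nothing to the mask.
#' @param noise_sd Gaussian pixel noise standard deviation.
#' @param seed Integer; fully determines the generated dataset.
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(image_height = 96L, image_width = 128L,
                           pixel_spacing_mm = 0.5,
                           lesions_per_image_range = c(1L, 4L),
                           lesion_diameter_range_mm = c(2, 6),
                           lesion_eccentricity_range = c(0, 0.5),
                           lesion_contrast_range = c(0.25, 0.5),
                           n_mimics_range = c(0L, 3L),
                           noise_sd = 0.02,
                           seed = 1L) {
  cfg <- list(image_height = as.integer(image_height),
              image_width = as.integer(image_width),
              pixel_spacing_mm = pixel_spacing_mm,
              lesions_per_image_range = as.integer(lesions_per_image_range),
              lesion_diameter_range_mm = lesion_diameter_range_mm,
              lesion_eccentricity_range = lesion_eccentricity_range,
              lesion_contrast_range = lesion_contrast_range,
              n_mimics_range = as.integer(n_mimics_range),
              noise_sd = noise_sd,
              seed = as.integer(seed))
  rng_ok <- function(r, lo_ok = TRUE) length(r) == 2 && r[1] <= r[2]
  if (cfg$image_height < 16 || cfg$image_width < 16) {
    stop("phantom_config: image must be at least 16x16")
  }
  if (!rng_ok(cfg$lesions_per_image_range) || cfg$lesions_per_image_range[1] < 0) {
    stop("phantom_config: invalid lesions_per_image_range")
  }
  if (!rng_ok(cfg$lesion_diameter_range_mm) ||
      cfg$lesion_diameter_range_mm[1] <= 0 ||
      cfg$lesion_diameter_range_mm[2] >= 10) {
    stop("phantom_config: lesion diameters must lie in (0, 10) mm (microbleed definition)")
  }
  if (!rng_ok(cfg$lesion_eccentricity_range) ||
      cfg$lesion_eccentricity_range[1] < 0 ||
      cfg$lesion_eccentricity_range[2] >= 1) {
    stop("phantom_config: eccentricity range must lie in [0, 1)")
  }
  if (!rng_ok(cfg$lesion_contrast_range) || cfg$lesion_contrast_range[1] < 0) {
    stop("phantom_config: invalid lesion_contrast_range")
  }
  if (!rng_ok(cfg$n_mimics_range) || cfg$n_mimics_range[1] < 0) {
    stop("phantom_config: invalid n_mimics_range")
  }
  if (cfg$noise_sd < 0) stop("phantom_config: noise_sd must be >= 0")
  if (cfg$pixel_spacing_mm <= 0) stop("phantom_config: spacing must be > 0")
  structure(cfg, class = "phantom_config")
}

rand_int <- function(range) {
  if (range[1] == range[2]) range[1] else sample(range[1]:range[2], 1L)
}

# Smooth brain-like background: constant base + bilinearly upsampled low
# resolution Gaussian field (texture) in roughly [0.4, 0.7].
phantom_background <- function(H, W) {
  hl <- max(2L, H %/% 8L)
  wl <- max(2L, W %/% 8L)
  low <- matrix(rnorm(hl * wl), hl, wl)
  tex <- cpp_resize_bilinear(array(low, c(hl, wl, 1L)), H, W)
  0.55 + 0.08 * matrix(tex, H, W)
}

# Rasterize one ellipse; returns the binary pixel set and an anti-aliased
# coverage field (soft ~1px edge) used to darken the image.
rasterize_ellipse <- function(H, W, cy, cx, a, b, theta) {
  rows <- matrix(seq_len(H) - 1, H, W) - cy
  cols <- matrix(rep(seq_len(W) - 1, each = H), H, W) - cx
  u <- (rows * cos(theta) + cols * sin(theta)) / a
  v <- (-rows * sin(theta) + cols * cos(theta)) / b
  q <- sqrt(u^2 + v^2)
  inside <- q <= 1
  cov <- pmin(1, pmax(0, 0.5 + (1 - q) * min(a, b)))
  list(inside = inside, coverage = cov)
}

# Thin dark random-walk curve (vein mimic); returns pixel indices.
mimic_path <- function(H, W) {
  len <- sample(10:30, 1L)
  pos <- c(runif(1, 1, H - 2), runif(1, 1, W - 2))
  ang <- runif(1, 0, 2 * pi)
  px <- integer(0)
  for (s in seq_len(len)) {
    ang <- ang + rnorm(1, sd = 0.35)
    pos <- pos + c(sin(ang), cos(ang))
    r <- round(pos[1]) + 1L
    c <- round(pos[2]) + 1L
    if (r < 1 || r > H || c < 1 || c > W) break
    px <- c(px, r + (c - 1L) * H)
  }
  unique(px)
}

generate_phantom_image <- function(cfg, id) {
  H <- cfg$image_height
  W <- cfg$image_width
  img <- phantom_background(H, W)
  mask <- matrix(0L, H, W)

  d_px <- cfg$lesion_diameter_range_mm / cfg$pixel_spacing_mm
  n_lesions <- rand_int(cfg$lesions_per_image_range)
  placed <- list()  # (cy, cx, a)
  for (k in seq_len(n_lesions)) {
    for (try in 1:200) {
      d_eq <- runif(1, d_px[1], d_px[2])
      e <- runif(1, cfg$lesion_eccentricity_range[1], cfg$lesion_eccentricity_range[2])
      shape <- (1 - e^2)^0.25
      a <- (d_eq / 2) / shape
      b <- (d_eq / 2) * shape
      theta <- runif(1, 0, pi)
      m <- a + 2
      if (2 * m >= H || 2 * m >= W) next
      cy <- runif(1, m, H - 1 - m)
      cx <- runif(1, m, W - 1 - m)
      clear <- all(vapply(placed, function(p) {
        sqrt((p[1] - cy)^2 + (p[2] - cx)^2) > p[3] + a + 3
      }, logical(1)))
      if (!clear) next
      ras <- rasterize_ellipse(H, W, cy, cx, a, b, theta)
      area <- sum(ras$inside)
      eqd <- 2 * sqrt(area / pi)
      # hard guarantee: the rasterized component's equivalent diameter stays
      # inside the configured range despite pixelation
      if (eqd < d_px[1] || eqd > d_px[2]) next
      contrast <- runif(1, cfg$lesion_contrast_range[1], cfg$lesion_contrast_range[2])
      img <- img - contrast * ras$coverage
      mask[ras$inside] <- 1L
      placed[[length(placed) + 1L]] <- c(cy, cx, a)
      break
    }
    if (length(placed) < k) {
      stop("phantom: could not place lesion ", k, " after 200 attempts; ",
           "image too small for the configured lesion geometry")
    }
  }

  n_mim <- rand_int(cfg$n_mimics_range)
  for (m in seq_len(n_mim)) {
    px <- mimic_path(H, W)
    if (length(px)) img[px] <- img[px] - runif(1, 0.15, 0.35)
  }

  if (cfg$noise_sd > 0) img <- img + rnorm(H * W, sd = cfg$noise_sd)

  list(image = min_max_normalize(img), mask = mask,
       id = sprintf("phantom_%04d", id), n_lesions = n_lesions,
       spacing_mm = cfg$pixel_spacing_mm, seed = cfg$seed)
}

#' Generate a seedable synthetic phantom dataset
#'
#' @param config A [phantom_config()]; `config$seed` fully determines the
#'   output (identical seed, bit-identical dataset).
#' @param n_images Number of image/mask pairs to generate.
#' @return List of samples; each sample is a list with `image` (matrix in
#'   `[0, 1]`, min-max normalized), `mask` (0/1 integer matrix with exactly
#'   as many 8-connected components as placed lesions), `id`, `n_lesions`,
#'   `spacing_mm`.
#' @export
generate_phantom_dataset <- function(config, n_images) {
  stopifnot(inherits(config, "phantom_config"), n_images >= 1)
  with_seed(config$seed,
            lapply(seq_len(n_images), function(i) generate_phantom_image(config, i)))
}

#' Min-max intensity normalization
#'
#' Affine rescaling to `[0, 1]`; a non-constant input attains both 0 and 1
#' and the pixel intensity ordering is preserved. A constant image maps to
#' all zeros (the divide-by-zero convention).
#'
#' @param x Numeric matrix or array of finite intensities.
#' @return Object of the same shape with values in `[0, 1]`.
#' @export
min_max_normalize <- function(x) {
  if (any(!is.finite(x))) stop("min_max_normalize: image has non-finite values")
  lo <- min(x)
  hi <- max(x)
  if (hi == lo) return(x * 0)
  (x - lo) / (hi - lo)
}

#' Data augmentation policy
#'
#' Defaults follow the training protocol: random intensity translation and
#' scaling supported on (-0.2, 0.2) (shift ~ U(-0.2, 0.2), scale ~
#' U(0.8, 1.2), applied as `x * scale + shift`), rotation with 30%
#' probability up to 180 degrees, horizontal and vertical flips each with
#' 30% probability, and additive Gaussian noise.
#'
#' @param intensity_shift_scale Half-width of the shift interval and of the
#'   scale deviation from 1.
#' @param rotation_probability,max_rotation_deg Rotation gate and bound.
#' @param flip_probability Per-axis flip probability.
#' @param noise_on,noise_sd Gaussian noise gate and standard deviation.
#' @return An object of class `augmentation_policy`.
#' @export
augmentation_policy <- function(intensity_shift_scale = 0.2,
                                rotation_probability = 0.30,
                                max_rotation_deg = 180,
                                flip_probability = 0.30,
                                noise_on = TRUE,
                                noise_sd = 0.02) {
  stopifnot(rotation_probability >= 0, rotation_probability <= 1,
            flip_probability >= 0, flip_probability <= 1,
            max_rotation_deg >= 0, intensity_shift_scale >= 0, noise_sd >= 0)
  structure(list(intensity_shift_scale = intensity_shift_scale,
                 rotation_probability = rotation_probability,
                 max_rotation_deg = max_rotation_deg,
                 flip_probability = flip_probability,
                 noise_on = noise_on, noise_sd = noise_sd),
            class = "augmentation_policy")
}

#' Jointly augment an image/mask pair
#'
#' Geometric transforms (rotation, flips) are applied identically to the
#' image (bilinear interpolation, constant padding at the image median) and the mask
#' (nearest-neighbour, so labels stay binary); intensity shift/scale and
#' noise touch the image only. Every stochastic transform is gated by its
#' policy probability.
#'
#' @param image Numeric matrix.
#' @param mask 0/1 matrix congruent with `image`.
#' @param policy An [augmentation_policy()].
#' @param seed Optional seed making the draw reproducible; if `NULL` the
#'   current RNG stream is used.
#' @return List with `image`, `mask`, and `applied` (the realized draws).
#' @export
augment_pair <- function(image, mask, policy = augmentation_policy(),
                         seed = NULL) {
  stopifnot(inherits(policy, "augmentation_policy"))
  if (!all(dim(image) == dim(mask))) {
    stop("augment_pair: image and mask shapes differ")
  }
  run <- function() {
    do_rot <- runif(1) < policy$rotation_probability
    angle <- runif(1, -policy$max_rotation_deg, policy$max_rotation_deg)
    do_h <- runif(1) < policy$flip_probability
    do_v <- runif(1) < policy$flip_probability
    shift <- runif(1, -policy$intensity_shift_scale, policy$intensity_shift_scale)
    scale <- runif(1, 1 - policy$intensity_shift_scale,
                   1 + policy$intensity_shift_scale)
    img <- image
    msk <- mask
    if (do_rot && angle != 0) {
      # pad the image with its median so rotation corners do not masquerade
      # as giant hypointense structures; mask corners stay background
      img <- cpp_rotate(img, angle, 0L, stats::median(img))
      msk <- cpp_rotate(msk * 1.0, angle, 1L, 0)
    }
    if (do_h) {  # horizontal flip: reverse columns
      img <- img[, rev(seq_len(ncol(img))), drop = FALSE]
      msk <- msk[, rev(seq_len(ncol(msk))), drop = FALSE]
    }
    if (do_v) {  # vertical flip: reverse rows
      img <- img[rev(seq_len(nrow(img))), , drop = FALSE]
      msk <- msk[rev(seq_len(nrow(msk))), , drop = FALSE]
    }
    img <- img * scale + shift
    if (policy$noise_on && policy$noise_sd > 0) {
      img <- img + rnorm(length(img), sd = policy$noise_sd)
    }
    storage.mode(msk) <- "integer"
    list(image = img, mask = msk,
         applied = list(rotation = do_rot, angle = if (do_rot) angle else 0,
                        hflip = do_h, vflip = do_v, shift = shift,
                        scale = scale))
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}
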