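# Stage glue: coarse probability map -> candidate components -> centred ROI
# crops -> fine per-ROI segmentation -> stitched full-size mask.
#
# Coordinate convention (package-wide): (row, col), 0-based, half-open
# windows. An ROI with origin (r0, c0) and size s covers rows r0..r0+s-1.

#' Cascade configuration
#'
#' @param roi_size Square ROI side in pixels; the supported sizes are 16, 32,
#'   64 and 128, with 32 the default (the size found to segment best).
#' @param coarse_threshold,fine_threshold Probability thresholds used to
#'   binarize the stage outputs.
#' @param min_component_area Candidate components smaller than this many
#'   pixels are discarded.
#' @param overlap_rule How fine probabilities are fused where ROIs overlap:
#'   `"max"` (default, favours sensitivity) or `"mean"`.
#' @return An object of class `cascade_config`.
#' @export
cascade_config <- function(roi_size = 32L, coarse_threshold = 0.5,
                           fine_threshold = 0.5, min_component_area = 1L,
                           overlap_rule = c("max", "mean")) {
  overlap_rule <- match.arg(overlap_rule)
  if (!roi_size %in% c(16L, 32L, 64L, 128L)) {
    stop("cascade_config: roi_size must be one of 16, 32, 64, 128")
  }
  stopifnot(coarse_threshold > 0, coarse_threshold < 1,
            fine_threshold > 0, fine_threshold < 1, min_component_area >= 1)
  structure(list(roi_size = as.integer(roi_size),
                 coarse_threshold = coarse_threshold,
                 fine_threshold = fine_threshold,
                 min_component_area = as.integer(min_component_area),
                 overlap_rule = overlap_rule),
            class = "cascade_config")
}

#' Threshold a probability map into a binary mask
#'
#' A pixel is foreground iff its probability is `>= threshold`.
#'
#' @param prob Numeric matrix with values in `[0, 1]`.
#' @param threshold Decision threshold.
#' @return 0/1 integer matrix.
#' @export
binarize <- function(prob, threshold = 0.5) {
  m <- matrix(as.integer(prob >= threshold), nrow(prob), ncol(prob))
  m
}

#' Extract 8-connected lesion components from a binary mask
#'
#' @param mask 0/1 matrix.
#' @param min_area Components with fewer pixels are dropped.
#' @return A tibble with one row per surviving component: `component` (label),
#'   `area`, `centroid_row`, `centroid_col` (0-based arithmetic means of
#'   member coordinates), `eq_diameter` (`2*sqrt(area/pi)` pixels), and
#'   `pixels` (list-column of n x 2 matrices of 0-based (row, col)
#'   coordinates). The full label matrix is attached as attribute `labels`.
#' @export
extract_components <- function(mask, min_area = 1L) {
  storage.mode(mask) <- "integer"
  lab <- cpp_label8(mask)
  ids <- sort(unique(lab[lab > 0L]))
  rows <- lapply(ids, function(k) {
    idx <- which(lab == k, arr.ind = TRUE) - 1L  # 0-based
    if (nrow(idx) < min_area) return(NULL)
    list(component = k, area = nrow(idx),
         centroid_row = mean(idx[, 1]), centroid_col = mean(idx[, 2]),
         eq_diameter = 2 * sqrt(nrow(idx) / pi), pixels = idx)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  tibble::tibble(
    component = vapply(rows, `[[`, integer(1), "component"),
    area = vapply(rows, `[[`, integer(1), "area"),
    centroid_row = vapply(rows, `[[`, numeric(1), "centroid_row"),
    centroid_col = vapply(rows, `[[`, numeric(1), "centroid_col"),
    eq_diameter = vapply(rows, `[[`, numeric(1), "eq_diameter"),
    pixels = lapply(rows, `[[`, "pixels")
  ) -> out
  attr(out, "labels") <- lab
  out
}

#' Crop a square ROI centred on a candidate component
#'
#' The window is centred at the rounded centroid and translated minimally so
#' it lies fully inside the image (never zero-padded).
#'
#' @param image Numeric matrix.
#' @param centroid Numeric `(row, col)` centroid, 0-based; a component row
#'   from [extract_components()] is also accepted.
#' @param size ROI side in pixels; must not exceed either image dimension.
#' @return List with `origin` (0-based top-left `(row, col)`), `size`, and
#'   `crop` (`size` x `size` matrix).
#' @export
crop_roi <- function(image, centroid, size) {
  if (is.list(centroid) || is.data.frame(centroid)) {
    centroid <- c(centroid$centroid_row[1], centroid$centroid_col[1])
  }
  H <- nrow(image)
  W <- ncol(image)
  size <- as.integer(size)
  if (size > H || size > W) {
    stop("crop_roi: ROI size exceeds the image dimensions")
  }
  r0 <- round(centroid[1]) - size %/% 2L
  c0 <- round(centroid[2]) - size %/% 2L
  r0 <- min(max(r0, 0L), H - size)
  c0 <- min(max(c0, 0L), W - size)
  list(origin = c(as.integer(r0), as.integer(c0)), size = size,
       crop = image[r0 + seq_len(size), c0 + seq_len(size), drop = FALSE])
}

# Fuse per-ROI probability patches onto a full-size canvas. Pixels outside
# every window stay 0 (background). rule "max" takes the elementwise maximum
# over covering windows, "mean" their average.
fuse_patches <- function(shape, patches, origins, rule = c("max", "mean")) {
  rule <- match.arg(rule)
  canvas <- matrix(0, shape[1], shape[2])
  counts <- matrix(0, shape[1], shape[2])
  for (i in seq_along(patches)) {
    p <- patches[[i]]
    r <- origins[[i]][1] + seq_len(nrow(p))
    c <- origins[[i]][2] + seq_len(ncol(p))
    if (rule == "max") {
      canvas[r, c] <- pmax(canvas[r, c], p)
    } else {
      canvas[r, c] <- canvas[r, c] + p
    }
    counts[r, c] <- counts[r, c] + 1
  }
  if (rule == "mean") {
    nz <- counts > 0
    canvas[nz] <- canvas[nz] / counts[nz]
  }
  list(prob = canvas, covered = counts > 0)
}

#' Run the full two-stage cascade on one slice
#'
#' The coarse network scores the whole slice; candidates are the 8-connected
#' components of the thresholded coarse map (minus those below
#' `min_component_area`); a fixed-size ROI is cropped around each candidate
#' centroid and segmented by the fine network; the per-ROI probabilities are
#' fused (overlaps resolved by `overlap_rule`), thresholded, and restricted
#' to the union of ROI windows — so background far from any coarse candidate
#' is always 0.
#'
#' @param image Normalized slice matrix (dimensions divisible by 16).
#' @param coarse_params,coarse_spec Stage-1 weights and [res_unet_spec()].
#' @param fine_params,fine_spec Stage-2 weights and [frn_spec()].
#' @param config A [cascade_config()].
#' @return List with `mask` (final 0/1 matrix), `prob` (fused fine
#'   probability map, 0 outside all ROIs), `coarse_prob`, and `rois`
#'   (tibble of ROI origins/sizes and source-component stats).
#' @export
run_cascade <- function(image, coarse_params, coarse_spec, fine_params,
                        fine_spec, config = cascade_config()) {
  stopifnot(inherits(config, "cascade_config"))
  coarse_prob <- res_unet_forward(image, coarse_params, coarse_spec)
  comps <- extract_components(binarize(coarse_prob, config$coarse_threshold),
                              min_area = config$min_component_area)
  empty_rois <- tibble::tibble(origin_row = integer(0), origin_col = integer(0),
                               size = integer(0), component = integer(0),
                               centroid_row = numeric(0),
                               centroid_col = numeric(0), area = integer(0))
  if (nrow(comps) == 0L) {
    return(list(mask = matrix(0L, nrow(image), ncol(image)),
                prob = matrix(0, nrow(image), ncol(image)),
                coarse_prob = coarse_prob, rois = empty_rois))
  }
  patches <- vector("list", nrow(comps))
  origins <- vector("list", nrow(comps))
  for (i in seq_len(nrow(comps))) {
    roi <- crop_roi(image, c(comps$centroid_row[i], comps$centroid_col[i]),
                    config$roi_size)
    patches[[i]] <- frn_forward(roi$crop, fine_params, fine_spec)
    origins[[i]] <- roi$origin
  }
  fused <- fuse_patches(dim(image), patches, origins, config$overlap_rule)
  mask <- binarize(fused$prob, config$fine_threshold)
  mask[!fused$covered] <- 0L
  rois <- tibble::tibble(
    origin_row = vapply(origins, `[`, integer(1), 1L),
    origin_col = vapply(origins, `[`, integer(1), 2L),
    size = config$roi_size,
    component = comps$component,
    centroid_row = comps$centroid_row,
    centroid_col = comps$centroid_col,
    area = comps$area
  )
  list(mask = mask, prob = fused$prob, coarse_prob = coarse_prob, rois = rois)
}
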