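# Image and mask I/O (NIfTI and PNG) and run configuration loading.
#
# Convention: pixel arrays are (row, col) matrices, 0-based coordinates in
# all window/centroid arithmetic. NIfTI volumes are taken as stored (no
# reorientation); intensities are never silently rescaled on read.

is_nifti_path <- function(path) grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)
is_png_path <- function(path) grepl("\\.png$", path, ignore.case = TRUE)

#' Read a 2D grayscale image slice
#'
#' NIfTI (`.nii`/`.nii.gz`): returns the stored values as a matrix; for a 3D
#' volume the first slice is returned with a warning. Pixel spacing comes
#' from the header. PNG (8- or 16-bit): values are returned on the original
#' integer scale (`0..255` or `0..65535`), never silently rescaled; spacing
#' falls back to `default_spacing`.
#'
#' @param path Input file.
#' @param default_spacing Spacing (mm/pixel) used for formats without a
#'   header (PNG).
#' @return List with `pixels` (numeric matrix), `spacing_mm`, `id` (file
#'   basename without extension).
#' @export
read_image <- function(path, default_spacing = 0.5) {
  if (!file.exists(path)) stop("read_image: no such file: ", path)
  if (is_nifti_path(path)) {
    img <- RNifti::readNifti(path)
    arr <- as.array(img)
    pd <- RNifti::pixdim(img)
    if (length(dim(arr)) == 3L) {
      if (dim(arr)[3] > 1L) {
        warning("read_image: 3D volume with ", dim(arr)[3],
                " slices; returning slice 1")
      }
      arr <- arr[, , 1L]
    } else if (length(dim(arr)) != 2L) {
      stop("read_image: unsupported NIfTI dimensionality")
    }
    pixels <- matrix(as.numeric(arr), dim(arr)[1], dim(arr)[2])
    spacing <- if (length(pd) >= 1 && pd[1] > 0) pd[1] else default_spacing
  } else if (is_png_path(path)) {
    x <- png::readPNG(path, info = TRUE)
    depth <- attr(x, "info")$bit.depth
    if (is.null(depth)) depth <- 8L
    if (length(dim(x)) == 3L) {
      if (dim(x)[3] > 1L) warning("read_image: multi-channel PNG; using channel 1")
      x <- x[, , 1L]
    }
    pixels <- x * (2^depth - 1)  # undo readPNG's [0,1] scaling: raw values
    spacing <- default_spacing
  } else {
    stop("read_image: unsupported format (expect .nii, .nii.gz or .png): ", path)
  }
  if (any(!is.finite(pixels))) stop("read_image: non-finite pixel values in ", path)
  id <- sub("\\.(nii(\\.gz)?|png)$", "", basename(path), ignore.case = TRUE)
  list(pixels = pixels, spacing_mm = spacing, id = id)
}

#' Write a 2D image slice
#'
#' NIfTI: float32 with the spacing in the header. PNG: 8-bit; values are
#' min-max normalized to use the full 0-255 range.
#'
#' @param pixels Numeric matrix.
#' @param path Output path (`.nii`, `.nii.gz` or `.png`).
#' @param spacing_mm Pixel spacing stored in NIfTI headers.
#' @return `path`, invisibly.
#' @export
write_image <- function(pixels, path, spacing_mm = 0.5) {
  if (is_nifti_path(path)) {
    arr <- array(pixels, c(dim(pixels), 1L))
    attr(arr, "pixdim") <- c(spacing_mm, spacing_mm, 1)
    RNifti::writeNifti(RNifti::asNifti(arr, datatype = "float",
                                       internal = FALSE), path)
  } else if (is_png_path(path)) {
    png::writePNG(min_max_normalize(pixels), path)
  } else {
    stop("write_image: unsupported format: ", path)
  }
  invisible(path)
}

#' Read a binary lesion mask
#'
#' NIfTI masks must contain only values 0 and 1; PNG masks only 0 and 255
#' (mapped to 1). Anything else is a validation error.
#'
#' @param path Mask file.
#' @return 0/1 integer matrix.
#' @export
read_mask <- function(path) {
  if (is_nifti_path(path)) {
    arr <- as.array(RNifti::readNifti(path))
    if (length(dim(arr)) == 3L) arr <- arr[, , 1L]
    vals <- unique(as.vector(arr))
    if (!all(vals %in% c(0, 1))) {
      stop("read_mask: non-binary NIfTI mask (values beyond {0,1}): ", path)
    }
    m <- matrix(as.integer(arr != 0), dim(arr)[1], dim(arr)[2])
  } else if (is_png_path(path)) {
    x <- png::readPNG(path)
    if (length(dim(x)) == 3L) x <- x[, , 1L]
    vals <- unique(as.vector(round(x * 255)))
    if (!all(vals %in% c(0, 1, 255))) {
      stop("read_mask: non-binary PNG mask (values beyond {0,1,255}): ", path)
    }
    m <- matrix(as.integer(x > 0), dim(x)[1], dim(x)[2])
  } else {
    stop("read_mask: unsupported format: ", path)
  }
  m
}

#' Write a binary lesion mask
#'
#' NIfTI: uint8 with values 0/1. PNG: 8-bit with values 0/255.
#'
#' @param mask 0/1 matrix.
#' @param path Output path.
#' @param spacing_mm Pixel spacing for NIfTI headers.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path, spacing_mm = 0.5) {
  if (any(!(mask %in% c(0, 1)))) stop("write_mask: mask must be binary {0,1}")
  if (is_nifti_path(path)) {
    arr <- array(as.integer(mask), c(dim(mask), 1L))
    attr(arr, "pixdim") <- c(spacing_mm, spacing_mm, 1)
    RNifti::writeNifti(RNifti::asNifti(arr, datatype = "uint8",
                                       internal = FALSE), path)
  } else if (is_png_path(path)) {
    png::writePNG(matrix(as.numeric(mask), nrow(mask), ncol(mask)), path)
  } else {
    stop("write_mask: unsupported format: ", path)
  }
  invisible(path)
}

#' Write a phantom dataset to disk with a manifest
#'
#' Each sample is written as an image/mask pair with identical basenames
#' (`<id>.png` + `<id>_mask.png`, or `.nii.gz`), plus a `manifest.csv` with
#' columns id, image_path, mask_path, n_lesions, seed.
#'
#' @param samples Output of [generate_phantom_dataset()].
#' @param dir Output directory (created if missing).
#' @param format `"png"` or `"nifti"`.
#' @return Path of the manifest CSV, invisibly.
#' @export
write_phantom_dataset <- function(samples, dir, format = c("png", "nifti")) {
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ext <- if (format == "png") ".png" else ".nii.gz"
  rows <- lapply(samples, function(s) {
    ip <- file.path(dir, paste0(s$id, ext))
    mp <- file.path(dir, paste0(s$id, "_mask", ext))
    write_image(s$image, ip, spacing_mm = s$spacing_mm)
    write_mask(s$mask, mp, spacing_mm = s$spacing_mm)
    data.frame(id = s$id, image_path = ip, mask_path = mp,
               n_lesions = s$n_lesions, seed = s$seed)
  })
  manifest <- file.path(dir, "manifest.csv")
  utils::write.csv(do.call(rbind, rows), manifest, row.names = FALSE)
  invisible(manifest)
}

# --- run configuration -------------------------------------------------------

#' Load a YAML run configuration
#'
#' Recognized sections: `phantom` ([phantom_config()] fields), `train`
#' ([train_config()] fields), `cascade` ([cascade_config()] fields), plus
#' top-level `run_dir` and `log_level`. Unknown sections or keys are
#' rejected rather than ignored.
#'
#' @param path YAML file.
#' @return List with `phantom`, `train`, `cascade` (constructed config
#'   objects; defaults where a section is absent), `run_dir`, `log_level`.
#' @export
load_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known_sections <- c("phantom", "train", "cascade", "run_dir", "log_level")
  unknown <- setdiff(names(raw), known_sections)
  if (length(unknown)) {
    stop("load_run_config: unknown keys: ", paste(unknown, collapse = ", "))
  }
  check_args <- function(args, fn, section) {
    bad <- setdiff(names(args), names(formals(fn)))
    if (length(bad)) {
      stop("load_run_config: unknown ", section, " keys: ",
           paste(bad, collapse = ", "))
    }
    args
  }
  ph <- do.call(phantom_config, check_args(raw$phantom %||% list(),
                                           phantom_config, "phantom"))
  tr <- do.call(train_config, check_args(raw$train %||% list(),
                                         train_config, "train"))
  ca <- do.call(cascade_config, check_args(raw$cascade %||% list(),
                                           cascade_config, "cascade"))
  list(phantom = ph, train = tr, cascade = ca,
       run_dir = raw$run_dir %||% ".", log_level = raw$log_level %||% "info")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
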