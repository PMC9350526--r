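# Network architectures: stage-1 residual U-Net and stage-2 full-resolution
# network (FRN) with residual atrous spatial pyramid pooling (R-ASPP).
#
# A residual unit computes y = f(h(x) + F(x, W)) where F is a two-convolution
# residual branch, h is the identity (variant S1) or a 1x1 projection that
# may change channels/stride (variant S2), and f is the ReLU.

# --- residual blocks --------------------------------------------------------

init_res_block <- function(variant = c("S1", "S2"), cin, cout = cin,
                           prefix = "blk") {
  variant <- match.arg(variant)
  p <- list()
  p[[paste0(prefix, "_c1")]] <- conv_param(3L, cin, cout)
  p[[paste0(prefix, "_c2")]] <- conv_param(3L, cout, cout, zero = TRUE)
  if (variant == "S2") p[[paste0(prefix, "_p")]] <- conv_param(1L, cin, cout)
  p
}

tp_s1_block <- function(tp, a, params, prefix) {
  h1 <- tp_relu(tp, tp_conv(tp, a, params, paste0(prefix, "_c1")))
  f <- tp_conv(tp, h1, params, paste0(prefix, "_c2"))
  tp_relu(tp, tp_add(tp, f, a))
}

tp_s2_block <- function(tp, a, params, prefix, stride = 1L) {
  h1 <- tp_relu(tp, tp_conv(tp, a, params, paste0(prefix, "_c1"),
                            stride = stride))
  f <- tp_conv(tp, h1, params, paste0(prefix, "_c2"))
  p <- tp_conv(tp, a, params, paste0(prefix, "_p"), stride = stride)
  tp_relu(tp, tp_add(tp, f, p))
}

tp_s1_chain <- function(tp, a, params, prefix, n) {
  for (i in seq_len(n)) a <- tp_s1_block(tp, a, params, paste0(prefix, "_b", i))
  a
}

#' Forward pass through a single residual block
#'
#' Computes `ReLU(h(x) + F(x, W))` where the residual branch `F` is
#' conv-ReLU-conv and the shortcut `h` is the identity (variant `"S1"`,
#' channel- and size-preserving) or a learned 1x1 projection (variant `"S2"`,
#' which may change the channel count and/or spatial stride).
#'
#' @param x Feature map: `(H, W, C)` array (a matrix is treated as 1 channel).
#' @param weights Named parameter list as produced by
#'   [init_res_block()] with `prefix = "blk"`.
#' @param variant `"S1"` or `"S2"`.
#' @param stride Spatial stride of the block (S2 only).
#' @return Feature map array.
#' @export
res_block_forward <- function(x, weights, variant = c("S1", "S2"),
                              stride = 1L) {
  variant <- match.arg(variant)
  tp <- new_tape()
  a <- tp_input(tp, x)
  out <- if (variant == "S1") {
    if (stride != 1L) stop("S1 blocks are stride-1")
    tp_s1_block(tp, a, weights, "blk")
  } else {
    tp_s2_block(tp, a, weights, "blk", stride = stride)
  }
  tp_value(tp, out)
}

# --- residual U-Net (coarse stage) -----------------------------------------

#' Residual U-Net specification
#'
#' Five-stage encoder/decoder. Stage 1 is a single 3x3 convolution to
#' `channels[1]`; stage 2 is a stride-2 transition convolution followed by
#' three S1 blocks; stages 3 and 4 open with a stride-2 S2 block (projection
#' shortcut) followed by three S1 blocks; stage 5 runs two S1 blocks and
#' closes with a stride-2 S2 block, giving a /16 bottleneck. The decoder
#' upsamples by bilinear interpolation (no transposed convolutions), fuses
#' each encoder stage through a skip concatenation + 3x3 convolution, and a
#' final 1x1 convolution + logistic sigmoid yields the per-pixel foreground
#' probability.
#'
#' @param input_channels Number of image channels (1 for grayscale slices).
#' @param channels Per-stage encoder output channels.
#' @param width_factor Integer divisor applied to `channels` so the same
#'   topology can be trained at desk scale (channels never drop below 1).
#' @return An object of class `res_unet_spec`.
#' @export
res_unet_spec <- function(input_channels = 1L,
                          channels = c(32L, 64L, 128L, 256L, 512L),
                          width_factor = 1L) {
  stopifnot(length(channels) == 5L, width_factor >= 1L)
  structure(list(input_channels = as.integer(input_channels),
                 channels = pmax(1L, as.integer(channels %/% width_factor)),
                 width_factor = as.integer(width_factor)),
            class = "res_unet_spec")
}

#' Initialize residual U-Net weights (He initialization)
#'
#' @param spec A [res_unet_spec()].
#' @param seed Optional integer seed for reproducible initialization.
#' @return Named list of convolution parameters.
#' @export
init_res_unet <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "res_unet_spec"))
  build <- function() {
    cc <- spec$channels
    p <- list()
    p$enc1 <- conv_param(3L, spec$input_channels, cc[1])
    p$down2 <- conv_param(3L, cc[1], cc[2])
    for (i in 1:3) p <- c(p, init_res_block("S1", cc[2], prefix = paste0("enc2_b", i)))
    p <- c(p, init_res_block("S2", cc[2], cc[3], prefix = "enc3_s2"))
    for (i in 1:3) p <- c(p, init_res_block("S1", cc[3], prefix = paste0("enc3_b", i)))
    p <- c(p, init_res_block("S2", cc[3], cc[4], prefix = "enc4_s2"))
    for (i in 1:3) p <- c(p, init_res_block("S1", cc[4], prefix = paste0("enc4_b", i)))
    for (i in 1:2) p <- c(p, init_res_block("S1", cc[4], prefix = paste0("enc5_b", i)))
    p <- c(p, init_res_block("S2", cc[4], cc[5], prefix = "enc5_s2"))
    p$dec4 <- conv_param(3L, cc[5] + cc[4], cc[4])
    p$dec3 <- conv_param(3L, cc[4] + cc[3], cc[3])
    p$dec2 <- conv_param(3L, cc[3] + cc[2], cc[2])
    p$dec1 <- conv_param(3L, cc[2] + cc[1], cc[1])
    p$out <- conv_param(1L, cc[1], 1L)
    p
  }
  if (is.null(seed)) build() else with_seed(seed, build())
}

res_unet_tape <- function(params, spec, x) {
  x <- as_fmap(x)
  d <- dim(x)
  if (d[1] %% 16L != 0L || d[2] %% 16L != 0L) {
    stop(sprintf(paste0("res_unet_forward: input %dx%d is not divisible by 16; ",
                        "pad the image before inference"), d[1], d[2]))
  }
  tp <- new_tape()
  a <- tp_input(tp, x)
  s1 <- tp_relu(tp, tp_conv(tp, a, params, "enc1"))
  d2 <- tp_relu(tp, tp_conv(tp, s1, params, "down2", stride = 2L))
  s2 <- tp_s1_chain(tp, d2, params, "enc2", 3L)
  s3 <- tp_s1_chain(tp, tp_s2_block(tp, s2, params, "enc3_s2", stride = 2L),
                    params, "enc3", 3L)
  s4 <- tp_s1_chain(tp, tp_s2_block(tp, s3, params, "enc4_s2", stride = 2L),
                    params, "enc4", 3L)
  s5 <- tp_s2_block(tp, tp_s1_chain(tp, s4, params, "enc5", 2L),
                    params, "enc5_s2", stride = 2L)
  up <- function(from, skip, name) {
    ds <- dim(tp_value(tp, skip))
    u <- tp_resize(tp, from, ds[1], ds[2])
    tp_relu(tp, tp_conv(tp, tp_concat(tp, u, skip), params, name))
  }
  u4 <- up(s5, s4, "dec4")
  u3 <- up(u4, s3, "dec3")
  u2 <- up(u3, s2, "dec2")
  u1 <- up(u2, s1, "dec1")
  out <- tp_sigmoid(tp, tp_conv(tp, u1, params, "out"))
  list(tp = tp, out = out)
}

#' Coarse-stage forward pass: whole-slice probability map
#'
#' @param image `(H, W)` matrix or `(H, W, 1)` array with `H` and `W`
#'   divisible by 16 (values normally min-max normalized to `[0, 1]`).
#' @param params Weights from [init_res_unet()] or a loaded checkpoint.
#' @param spec The matching [res_unet_spec()].
#' @return `(H, W)` matrix of foreground probabilities in `(0, 1)`.
#' @export
res_unet_forward <- function(image, params, spec) {
  r <- res_unet_tape(params, spec, image)
  v <- tp_value(r$tp, r$out)
  matrix(v, dim(v)[1], dim(v)[2])
}

# --- R-ASPP and FRN (fine stage) -------------------------------------------

init_r_aspp <- function(channels, dilations = c(6L, 8L, 12L), prefix = "aspp") {
  p <- list()
  for (i in seq_along(dilations)) {
    p[[paste0(prefix, "_d", i)]] <- conv_param(3L, channels, channels)
  }
  p[[paste0(prefix, "_fuse")]] <- conv_param(1L, channels, channels, zero = TRUE)
  p
}

tp_r_aspp <- function(tp, a, params, dilations, prefix = "aspp") {
  branches <- lapply(seq_along(dilations), function(i) {
    tp_conv(tp, a, params, paste0(prefix, "_d", i), dil = dilations[i])
  })
  s <- branches[[1]]
  for (i in seq_along(branches)[-1]) s <- tp_add(tp, s, branches[[i]])
  s <- tp_add(tp, s, tp_gap_broadcast(tp, a))
  fused <- tp_conv(tp, s, params, paste0(prefix, "_fuse"))
  tp_add(tp, fused, a)  # identity shortcut
}

#' Residual atrous spatial pyramid pooling forward pass
#'
#' Three parallel 3x3 dilated convolutions plus a global-average-pooling
#' branch are summed, fused by a 1x1 convolution, and added back to the
#' input through an identity shortcut; channel count and spatial size are
#' preserved. With all convolution weights zero the block is exactly the
#' identity.
#'
#' @param f0 Input feature map `(H, W, C)`.
#' @param weights Parameters from `init_r_aspp(C, dilations)`.
#' @param dilations Dilation rates of the three parallel branches.
#' @return Feature map with the same shape as `f0`.
#' @export
r_aspp_forward <- function(f0, weights, dilations = c(6L, 8L, 12L)) {
  tp <- new_tape()
  a <- tp_input(tp, f0)
  tp_value(tp, tp_r_aspp(tp, a, weights, as.integer(dilations)))
}

#' Full-resolution network specification
#'
#' conv-in (to `width` channels) -> 3 S1 residual blocks -> R-ASPP ->
#' 3 S1 residual blocks -> 1x1 conv-out -> logistic sigmoid. No layer
#' changes the spatial size, so every feature map lives at the input
#' resolution of the ROI patch.
#'
#' @param input_channels Image channels (1).
#' @param width Feature width of the trunk (32 at clinical scale).
#' @param dilations Dilation rates of the R-ASPP branches. The prose and the
#'   figure of the source architecture use (6, 8, 12) while its equation
#'   lists (4, 8, 12); (6, 8, 12) is the default and the set is configurable.
#' @param width_factor Integer divisor for desk-scale training.
#' @return An object of class `frn_spec`.
#' @export
frn_spec <- function(input_channels = 1L, width = 32L,
                     dilations = c(6L, 8L, 12L), width_factor = 1L) {
  structure(list(input_channels = as.integer(input_channels),
                 width = max(1L, as.integer(width) %/% as.integer(width_factor)),
                 dilations = as.integer(dilations),
                 width_factor = as.integer(width_factor)),
            class = "frn_spec")
}

#' Initialize FRN weights
#' @param spec A [frn_spec()].
#' @param seed Optional integer seed.
#' @return Named list of convolution parameters.
#' @export
init_frn <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "frn_spec"))
  build <- function() {
    w <- spec$width
    p <- list()
    p$conv_in <- conv_param(3L, spec$input_channels, w)
    for (i in 1:3) p <- c(p, init_res_block("S1", w, prefix = paste0("pre_b", i)))
    p <- c(p, init_r_aspp(w, spec$dilations))
    for (i in 1:3) p <- c(p, init_res_block("S1", w, prefix = paste0("post_b", i)))
    p$conv_out <- conv_param(1L, w, 1L)
    p
  }
  if (is.null(seed)) build() else with_seed(seed, build())
}

frn_tape <- function(params, spec, x) {
  x <- as_fmap(x)
  d <- dim(x)
  min_size <- 2L * min(spec$dilations) + 1L
  if (d[1] != d[2]) stop("frn_forward: ROI patch must be square")
  if (d[1] < min_size) {
    stop(sprintf("frn_forward: patch %dx%d below the receptive-field minimum %d",
                 d[1], d[2], min_size))
  }
  tp <- new_tape()
  a <- tp_input(tp, x)
  h <- tp_relu(tp, tp_conv(tp, a, params, "conv_in"))
  h <- tp_s1_chain(tp, h, params, "pre", 3L)
  h <- tp_r_aspp(tp, h, params, spec$dilations)
  h <- tp_s1_chain(tp, h, params, "post", 3L)
  out <- tp_sigmoid(tp, tp_conv(tp, h, params, "conv_out"))
  list(tp = tp, out = out)
}

#' Fine-stage forward pass: full-resolution ROI segmentation
#'
#' @param patch Square ROI image, `(s, s)` matrix, values in `[0, 1]`.
#' @param params Weights from [init_frn()] or a loaded checkpoint.
#' @param spec The matching [frn_spec()].
#' @return `(s, s)` matrix of foreground probabilities in `(0, 1)`.
#' @export
frn_forward <- function(patch, params, spec) {
  r <- frn_tape(params, spec, patch)
  v <- tp_value(r$tp, r$out)
  matrix(v, dim(v)[1], dim(v)[2])
}

#' Count trainable parameters
#' @param params Named parameter list of either network.
#' @return Integer count of scalar weights and biases.
#' @export
count_parameters <- function(params) n_parameters(params)

# --- checkpoints ------------------------------------------------------------

#' Save network weights with their architecture fingerprint
#'
#' A checkpoint is a single `.rds` archive holding the spec and the named
#' parameter arrays; [load_checkpoint()] refuses to load weights whose spec
#' does not match the requested architecture.
#'
#' @param path Output file path.
#' @param params Named parameter list.
#' @param spec The spec the weights belong to.
#' @param stage `"coarse"` or `"fine"` (informational).
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(path, params, spec, stage = c("coarse", "fine")) {
  stage <- match.arg(stage)
  saveRDS(list(format = "microseg-checkpoint-1", stage = stage, spec = spec,
               params = params), path)
  invisible(path)
}

#' Load network weights, verifying the architecture
#' @param path Checkpoint written by [save_checkpoint()].
#' @param expected_spec If supplied, loading fails unless the stored spec is
#'   identical to it.
#' @return List with `params`, `spec`, `stage`.
#' @export
load_checkpoint <- function(path, expected_spec = NULL) {
  ck <- readRDS(path)
  if (!identical(ck$format, "microseg-checkpoint-1")) {
    stop("not a microseg checkpoint: ", path)
  }
  if (!is.null(expected_spec) && !identical(ck$spec, expected_spec)) {
    stop("checkpoint spec does not match the requested architecture")
  }
  ck[c("params", "spec", "stage")]
}
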