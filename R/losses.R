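# Joint segmentation loss: binary cross-entropy + Dice + lambda * sensitivity.
#
# The sensitivity term is a soft missed-diagnosis rate,
#   L_sen = 1 - sum(y_hat * y) / sum(y),
# and its weight lambda is the knob that trades precision for recall: the
# coarse stage uses lambda = 10 (find every candidate), the fine stage
# lambda = 1 (balance sensitivity and precision).

check_loss_inputs <- function(y_hat, y) {
  if (length(y_hat) != length(y)) {
    stop("loss: prediction and label shapes differ")
  }
  dp <- dim(y_hat)
  dl <- dim(y)
  if (!is.null(dp) && !is.null(dl) && length(dp) == length(dl) &&
      !all(dp == dl)) {
    stop("loss: prediction and label shapes differ")
  }
  if (any(!(y %in% c(0, 1)))) stop("loss: labels must be binary {0,1}")
}

#' Binary cross-entropy loss
#'
#' `-(1/N) * sum(y*log(y_hat) + (1-y)*log(1-y_hat))` with predictions clipped
#' to `[clip, 1-clip]` to keep the logs finite.
#'
#' @param y_hat Per-pixel foreground probabilities (any shape).
#' @param y Binary labels, congruent with `y_hat`.
#' @param clip Probability clipping bound.
#' @return Nonnegative scalar.
#' @export
bce_loss <- function(y_hat, y, clip = 1e-7) {
  check_loss_inputs(y_hat, y)
  p <- pmin(pmax(as.vector(y_hat), clip), 1 - clip)
  y <- as.vector(y)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Dice loss
#'
#' `1 - (2*sum(y_hat*y) + smooth) / (sum(y_hat) + sum(y) + smooth)`. With
#' `smooth = 0` this is the exact soft Dice complement; the default
#' `smooth = 1` keeps the loss defined (and equal to 0) when both the
#' prediction and the label are empty.
#'
#' @inheritParams bce_loss
#' @param smooth Additive smoothing on numerator and denominator.
#' @return Scalar in `[0, 1]`.
#' @export
dice_loss <- function(y_hat, y, smooth = 1) {
  check_loss_inputs(y_hat, y)
  y_hat <- as.vector(y_hat)
  y <- as.vector(y)
  num <- 2 * sum(y_hat * y) + smooth
  den <- sum(y_hat) + sum(y) + smooth
  if (den == 0) return(0)
  1 - num / den
}

#' Sensitivity (missed-diagnosis) loss
#'
#' `1 - (sum(y_hat*y) + smooth) / (sum(y) + smooth)`: the soft fraction of
#' true foreground the prediction fails to cover. Zero iff every foreground
#' pixel is predicted with probability 1.
#'
#' @inheritParams dice_loss
#' @return Scalar in `[0, 1]`.
#' @export
sen_loss <- function(y_hat, y, smooth = 1) {
  check_loss_inputs(y_hat, y)
  y_hat <- as.vector(y_hat)
  y <- as.vector(y)
  den <- sum(y) + smooth
  if (den == 0) return(0)
  1 - (sum(y_hat * y) + smooth) / den
}

#' Combined segmentation loss
#'
#' `L_bce + L_dice + lambda * L_sen`. Stage defaults for `lambda` are
#' provided by [lambda_default()].
#'
#' @inheritParams dice_loss
#' @param lambda Nonnegative weight of the sensitivity term.
#' @param clip Probability clipping bound for the cross-entropy term.
#' @return List with `total`, `bce`, `dice`, `sen`.
#' @export
total_loss <- function(y_hat, y, lambda = 1, smooth = 1, clip = 1e-7) {
  stopifnot(lambda >= 0)
  b <- bce_loss(y_hat, y, clip = clip)
  d <- dice_loss(y_hat, y, smooth = smooth)
  s <- sen_loss(y_hat, y, smooth = smooth)
  list(total = b + d + lambda * s, bce = b, dice = d, sen = s)
}

#' Stage default for the sensitivity-loss weight
#' @param stage `"coarse"` (returns 10) or `"fine"` (returns 1).
#' @return Numeric lambda.
#' @export
lambda_default <- function(stage = c("coarse", "fine")) {
  switch(match.arg(stage), coarse = 10, fine = 1)
}

# Analytic gradient of total_loss w.r.t. y_hat (used by the trainer; checked
# against finite differences in the test suite).
total_loss_grad <- function(y_hat, y, lambda = 1, smooth = 1, clip = 1e-7) {
  out_dim <- dim(as_fmap(y_hat))
  y_hat <- as.vector(y_hat)
  y <- as.vector(y)
  n <- length(y_hat)
  p <- pmin(pmax(y_hat, clip), 1 - clip)
  inside <- (y_hat > clip) & (y_hat < 1 - clip)
  g_bce <- -(y / p - (1 - y) / (1 - p)) / n * inside

  num <- 2 * sum(y_hat * y) + smooth
  den <- sum(y_hat) + sum(y) + smooth
  g_dice <- if (den == 0) 0 * y_hat else -(2 * y * den - num) / den^2

  den_s <- sum(y) + smooth
  g_sen <- if (den_s == 0) 0 * y_hat else -y / den_s

  g <- g_bce + g_dice + lambda * g_sen
  array(g, out_dim)
}

# Gradient of total_loss w.r.t. the PRE-sigmoid logits z (y_hat = sigmoid(z)).
# The cross-entropy term uses the exact fused form (y_hat - y)/N, which stays
# alive when the sigmoid saturates; Dice and sensitivity terms are chained
# through the sigmoid derivative.
total_loss_grad_logit <- function(y_hat, y, lambda = 1, smooth = 1) {
  out_dim <- dim(as_fmap(y_hat))
  y_hat <- as.vector(y_hat)
  y <- as.vector(y)
  n <- length(y_hat)
  g <- (y_hat - y) / n

  num <- 2 * sum(y_hat * y) + smooth
  den <- sum(y_hat) + sum(y) + smooth
  g_dice <- if (den == 0) 0 else -(2 * y * den - num) / den^2

  den_s <- sum(y) + smooth
  g_sen <- if (den_s == 0) 0 else -y / den_s

  g <- g + (g_dice + lambda * g_sen) * y_hat * (1 - y_hat)
  array(g, out_dim)
}
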