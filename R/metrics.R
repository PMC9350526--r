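# Evaluation suite: pixel-level confusion metrics (sensitivity, precision,
# Dice, F2, Jaccard, Matthews correlation), lesion-level detection matching
# with per-image false positives, and precision-recall curves / average
# precision. All metrics live on [0, 1] (MCC on [-1, 1]); reports can be
# printed as percentages.

#' Pixel confusion counts between two binary masks
#'
#' @param pred,truth Congruent 0/1 matrices.
#' @return Named list with `tp`, `tn`, `fp`, `fn` (their sum is the pixel
#'   count).
#' @export
confusion_counts <- function(pred, truth) {
  if (!all(dim(pred) == dim(truth))) {
    stop("confusion_counts: mask shapes differ")
  }
  if (any(!(pred %in% c(0, 1))) || any(!(truth %in% c(0, 1)))) {
    stop("confusion_counts: masks must be binary {0,1}")
  }
  p <- pred == 1
  t <- truth == 1
  list(tp = sum(p & t), tn = sum(!p & !t), fp = sum(p & !t), fn = sum(!p & t))
}

#' Pixel-level segmentation metrics from confusion counts
#'
#' SEN = tp/(tp+fn), PRE = tp/(tp+fp), DSC = 2tp/(2tp+fp+fn),
#' F2 = 5*PRE*SEN/(4*PRE+SEN), JSC = tp/(tp+fn+fp), and the Matthews
#' correlation coefficient. Zero-denominator policy: if truth and prediction
#' are both empty every metric is 1 (a correct empty prediction); otherwise
#' any undefined ratio is 0.
#'
#' @param counts Output of [confusion_counts()].
#' @return Named list `sen`, `pre`, `dsc`, `f2`, `jsc`, `mcc`.
#' @export
pixel_metrics <- function(counts) {
  tp <- as.numeric(counts$tp)
  tn <- as.numeric(counts$tn)
  fp <- as.numeric(counts$fp)
  fn <- as.numeric(counts$fn)
  if (tp + fn == 0 && tp + fp == 0) {
    return(list(sen = 1, pre = 1, dsc = 1, f2 = 1, jsc = 1, mcc = 1))
  }
  div <- function(num, den) if (den == 0) 0 else num / den
  sen <- div(tp, tp + fn)
  pre <- div(tp, tp + fp)
  dsc <- div(2 * tp, 2 * tp + fp + fn)
  f2 <- div(5 * pre * sen, 4 * pre + sen)
  jsc <- div(tp, tp + fn + fp)
  mden <- sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  mcc <- if (mden == 0) 0 else (tp * tn - fp * fn) / mden
  list(sen = sen, pre = pre, dsc = dsc, f2 = f2, jsc = jsc, mcc = mcc)
}

#' Lesion-level detection matching
#'
#' A truth component counts as detected iff at least one predicted
#' 8-connected component overlaps it by at least one pixel; a predicted
#' component overlapping no truth pixel counts as one false positive.
#'
#' @param pred,truth Congruent 0/1 masks.
#' @return Named list `matched_truth`, `missed_truth`,
#'   `false_positive_components` (`matched + missed` equals the truth
#'   component count).
#' @export
lesion_detection_stats <- function(pred, truth) {
  if (!all(dim(pred) == dim(truth))) {
    stop("lesion_detection_stats: mask shapes differ")
  }
  pm <- pred
  tm <- truth
  storage.mode(pm) <- "integer"
  storage.mode(tm) <- "integer"
  plab <- cpp_label8(pm)
  tlab <- cpp_label8(tm)
  tids <- setdiff(unique(as.vector(tlab)), 0L)
  pids <- setdiff(unique(as.vector(plab)), 0L)
  matched <- sum(vapply(tids, function(k) any(plab[tlab == k] > 0L), logical(1)))
  fpc <- sum(vapply(pids, function(k) all(tlab[plab == k] == 0L), logical(1)))
  list(matched_truth = matched, missed_truth = length(tids) - matched,
       false_positive_components = fpc)
}

#' Mean false-positive components per image
#'
#' @param preds,truths Lists of congruent binary mask pairs.
#' @return Mean over images of the per-image false-positive component count.
#' @export
fp_avg <- function(preds, truths) {
  stopifnot(length(preds) == length(truths), length(preds) >= 1)
  mean(vapply(seq_along(preds), function(i) {
    lesion_detection_stats(preds[[i]], truths[[i]])$false_positive_components
  }, numeric(1)))
}

#' Precision-recall curve and average precision over pooled pixels
#'
#' Precision and recall are computed at every distinct predicted probability
#' (treated as a decision threshold, pixels scoring `>=` it are positive);
#' AP is the area under the recall-sorted step curve,
#' `sum((R_i - R_{i-1}) * P_i)`.
#'
#' @param probs Probability map or list of maps.
#' @param truths Binary mask or list of masks, congruent with `probs`.
#' @return List with `precision`, `recall`, `thresholds` (descending) and
#'   `ap`. Errors if the pooled truth has no positive pixel.
#' @export
pr_curve <- function(probs, truths) {
  if (!is.list(probs)) probs <- list(probs)
  if (!is.list(truths)) truths <- list(truths)
  stopifnot(length(probs) == length(truths))
  s <- unlist(lapply(probs, as.vector))
  y <- unlist(lapply(truths, as.vector))
  if (any(s < 0 | s > 1)) stop("pr_curve: probabilities must lie in [0, 1]")
  npos <- sum(y == 1)
  if (npos == 0) stop("pr_curve: no positive truth pixels")
  ord <- order(s, decreasing = TRUE)
  s <- s[ord]
  y <- y[ord]
  cum_tp <- cumsum(y == 1)
  # last index of each run of equal scores = the threshold boundary
  keep <- c(s[-1] != s[-length(s)], TRUE)
  idx <- which(keep)
  precision <- cum_tp[idx] / idx
  recall <- cum_tp[idx] / npos
  ap <- sum(diff(c(0, recall)) * precision)
  list(precision = precision, recall = recall, thresholds = s[idx], ap = ap)
}

#' Per-image evaluation of predicted against truth masks
#'
#' @param preds,truths Lists of congruent binary mask pairs.
#' @param ids Optional image identifiers.
#' @return Tibble with one row per image: the six pixel metrics plus
#'   lesion-level `matched`, `missed`, `fp_components`.
#' @export
evaluate_segmentation <- function(preds, truths, ids = NULL) {
  stopifnot(length(preds) == length(truths), length(preds) >= 1)
  if (is.null(ids)) ids <- sprintf("image_%04d", seq_along(preds))
  rows <- lapply(seq_along(preds), function(i) {
    m <- pixel_metrics(confusion_counts(preds[[i]], truths[[i]]))
    d <- lesion_detection_stats(preds[[i]], truths[[i]])
    tibble::tibble(id = ids[i], sen = m$sen, pre = m$pre, dsc = m$dsc,
                   f2 = m$f2, jsc = m$jsc, mcc = m$mcc,
                   matched = d$matched_truth, missed = d$missed_truth,
                   fp_components = d$false_positive_components)
  })
  do.call(rbind, rows)
}

#' Mean and standard deviation summary of a per-image evaluation
#'
#' Metrics are aggregated per image then averaged (mean over images, SD of
#' the per-image values) — the per-case reporting convention. `fp_avg` is
#' the mean per-image false-positive component count.
#'
#' @param per_image Tibble from [evaluate_segmentation()].
#' @param percent Report the six pixel metrics multiplied by 100.
#' @return Tibble with columns `metric`, `mean`, `sd`, plus one `fp_avg` row
#'   (never scaled by 100).
#' @export
metric_summary <- function(per_image, percent = FALSE) {
  metrics <- c("sen", "pre", "dsc", "f2", "jsc", "mcc")
  scale <- if (percent) 100 else 1
  out <- tibble::tibble(
    metric = metrics,
    mean = unname(vapply(metrics, function(m) mean(per_image[[m]]) * scale,
                         numeric(1))),
    sd = unname(vapply(metrics, function(m) sd(per_image[[m]]) * scale,
                       numeric(1)))
  )
  rbind(out, tibble::tibble(metric = "fp_avg",
                            mean = mean(per_image$fp_components),
                            sd = sd(per_image$fp_components)))
}
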