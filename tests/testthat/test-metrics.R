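test_that("confusion counts enumerate pixels exactly", {
  a <- matrix(c(1, 0, 1, 0), 2, 2)
  expect_equal(confusion_counts(a, a), list(tp = 2, tn = 2, fp = 0, fn = 0))
  expect_equal(confusion_counts(a, 1 - a), list(tp = 0, tn = 0, fp = 2, fn = 2))
  pred <- matrix(c(1, 0, 1, 0), 2, 2, byrow = TRUE)  # ((1,1),(0,0)) rows
  pred <- rbind(c(1, 1), c(0, 0))
  truth <- rbind(c(1, 0), c(1, 0))
  expect_equal(confusion_counts(pred, truth),
               list(tp = 1, tn = 1, fp = 1, fn = 1))
  expect_error(confusion_counts(matrix(0, 2, 2), matrix(0, 3, 3)), "differ")
  expect_error(confusion_counts(matrix(2, 2, 2), matrix(0, 2, 2)), "binary")
})

test_that("pixel metrics reproduce the hand-worked confusion example", {
  m <- pixel_metrics(list(tp = 2, tn = 10, fp = 1, fn = 1))
  expect_equal(m$sen, 2 / 3, tolerance = 1e-12)
  expect_equal(m$pre, 2 / 3, tolerance = 1e-12)
  expect_equal(m$dsc, 2 / 3, tolerance = 1e-12)
  expect_equal(m$jsc, 1 / 2, tolerance = 1e-12)
  expect_equal(m$f2, 2 / 3, tolerance = 1e-12)
  expect_equal(m$mcc, 19 / 33, tolerance = 1e-12)
  perfect <- pixel_metrics(list(tp = 5, tn = 20, fp = 0, fn = 0))
  expect_true(all(unlist(perfect) == 1))
})

test_that("F2 equals precision when precision equals sensitivity and sits between them otherwise", {
  set.seed(3)
  for (rep in 1:50) {
    cc <- list(tp = sample(1:20, 1), tn = sample(1:50, 1),
               fp = sample(0:10, 1), fn = sample(0:10, 1))
    m <- pixel_metrics(cc)
    expect_gte(m$f2, min(m$pre, m$sen) - 1e-12)
    expect_lte(m$f2, max(m$pre, m$sen) + 1e-12)
    # F2 weighs sensitivity more than F1 does
    f1 <- if (m$pre + m$sen == 0) 0 else 2 * m$pre * m$sen / (m$pre + m$sen)
    if (m$pre != m$sen) {
      expect_lte(abs(m$f2 - m$sen), abs(f1 - m$sen) + 1e-12)
    } else {
      expect_equal(m$f2, m$pre, tolerance = 1e-12)
    }
  }
})

test_that("zero-denominator policy rewards correct empties and punishes misses", {
  both_empty <- pixel_metrics(confusion_counts(matrix(0, 4, 4), matrix(0, 4, 4)))
  expect_true(all(unlist(both_empty) == 1))
  pred_only <- pixel_metrics(confusion_counts(matrix(1, 2, 2), matrix(0, 2, 2)))
  expect_equal(pred_only$sen, 0)
  expect_equal(pred_only$dsc, 0)
  truth_only <- pixel_metrics(confusion_counts(matrix(0, 2, 2), matrix(1, 2, 2)))
  expect_equal(truth_only$sen, 0)
  expect_equal(truth_only$pre, 0)
})

test_that("metric symmetries hold", {
  set.seed(9)
  for (rep in 1:25) {
    a <- matrix(sample(0:1, 36, replace = TRUE), 6, 6)
    b <- matrix(sample(0:1, 36, replace = TRUE), 6, 6)
    mab <- pixel_metrics(confusion_counts(a, b))
    mba <- pixel_metrics(confusion_counts(b, a))
    expect_equal(mab$dsc, mba$dsc, tolerance = 1e-12)
    expect_equal(mab$jsc, mba$jsc, tolerance = 1e-12)
    expect_equal(mab$pre, mba$sen, tolerance = 1e-12)
  }
})

test_that("MCC flips sign when a balanced prediction is complemented", {
  pred <- rbind(c(1, 1, 0, 0), c(1, 1, 0, 0), c(0, 0, 1, 1), c(0, 0, 1, 1))
  truth <- pred
  m1 <- pixel_metrics(confusion_counts(pred, truth))
  m2 <- pixel_metrics(confusion_counts(1 - pred, truth))
  expect_equal(m1$mcc, 1)
  expect_equal(m2$mcc, -1)
})

test_that("Dice metric is the complement of the unsmoothed dice loss on binary masks", {
  set.seed(21)
  for (rep in 1:20) {
    a <- matrix(sample(0:1, 25, replace = TRUE), 5, 5)
    b <- matrix(sample(0:1, 25, replace = TRUE), 5, 5)
    if (sum(a) + sum(b) == 0) next
    m <- pixel_metrics(confusion_counts(a, b))
    expect_equal(m$dsc, 1 - dice_loss(a, b, smooth = 0), tolerance = 1e-12)
  }
})

test_that("lesion detection matching counts overlaps and false positives", {
  truth <- matrix(0, 10, 10)
  truth[2:3, 2:3] <- 1
  truth[7:8, 7:8] <- 1
  truth[2:3, 8:9] <- 1
  d <- lesion_detection_stats(truth, truth)
  expect_equal(d$matched_truth, 3)
  expect_equal(d$false_positive_components, 0)

  pred <- matrix(0, 10, 10)
  pred[2, 2] <- 1          # overlaps lesion 1
  pred[9:10, 1:2] <- 1     # overlaps nothing
  single <- matrix(0, 10, 10)
  single[2:3, 2:3] <- 1
  d2 <- lesion_detection_stats(pred, single)
  expect_equal(d2$matched_truth, 1)
  expect_equal(d2$false_positive_components, 1)
  expect_equal(fp_avg(list(pred), list(single)), 1.0)

  d3 <- lesion_detection_stats(matrix(0, 10, 10), truth)
  expect_equal(d3$matched_truth, 0)
  expect_equal(d3$missed_truth, 3)
  expect_equal(d3$false_positive_components, 0)
})

test_that("PR curve endpoints and degenerate scorers behave as defined", {
  truth <- matrix(c(1, 0, 0, 1, 0, 0, 1, 0), 2, 4)
  perfect <- pr_curve(truth * 1.0, truth)
  expect_equal(perfect$ap, 1)
  flat <- pr_curve(matrix(0.5, 2, 4), truth)
  expect_equal(flat$precision, sum(truth) / length(truth))
  expect_error(pr_curve(matrix(0.5, 2, 2), matrix(0, 2, 2)), "no positive")
})

test_that("AP equals exhaustive threshold enumeration on toy maps", {
  set.seed(5)
  for (rep in 1:25) {
    prob <- matrix(round(runif(8), 2), 2, 4)
    truth <- matrix(sample(0:1, 8, replace = TRUE, prob = c(0.5, 0.5)), 2, 4)
    if (sum(truth) == 0) truth[1, 1] <- 1
    expect_equal(pr_curve(prob, truth)$ap, bf_ap(prob, truth),
                 tolerance = 1e-12)
  }
})

test_that("random mask pairs agree with the brute-force metric oracle", {
  set.seed(13)
  for (rep in 1:100) {
    a <- matrix(sample(0:1, 64, replace = TRUE), 8, 8)
    b <- matrix(sample(0:1, 64, replace = TRUE), 8, 8)
    m <- pixel_metrics(confusion_counts(a, b))
    o <- bf_metrics(a, b)
    for (k in names(o)) expect_equal(m[[k]], o[[k]], tolerance = 1e-12)
  }
})

test_that("evaluation tables aggregate per image with mean and SD", {
  set.seed(2)
  preds <- lapply(1:4, function(i) matrix(sample(0:1, 36, TRUE), 6, 6))
  truths <- lapply(1:4, function(i) matrix(sample(0:1, 36, TRUE), 6, 6))
  per <- evaluate_segmentation(preds, truths)
  expect_equal(nrow(per), 4)
  sm <- metric_summary(per)
  expect_equal(sm$mean[sm$metric == "dsc"], mean(per$dsc))
  expect_equal(sm$sd[sm$metric == "sen"], sd(per$sen))
  smp <- metric_summary(per, percent = TRUE)
  expect_equal(smp$mean[smp$metric == "dsc"], 100 * mean(per$dsc))
  expect_equal(smp$mean[smp$metric == "fp_avg"], mean(per$fp_components))
})
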