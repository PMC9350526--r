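test_that("k-fold partitions are even, disjoint and exhaustive", {
  f10 <- make_folds(1:10, 5, seed = 1)
  expect_equal(vapply(f10, function(f) length(f$val), integer(1)),
               rep(2L, 5))
  f11 <- make_folds(paste0("s", 1:11), 5, seed = 2)
  sizes <- sort(vapply(f11, function(f) length(f$val), integer(1)))
  expect_equal(sizes, c(2L, 2L, 2L, 2L, 3L))
  for (folds in list(f10, f11)) {
    vals <- unlist(lapply(folds, `[[`, "val"))
    expect_equal(length(vals), length(unique(vals)))
    all_ids <- sort(unique(c(vals, unlist(lapply(folds, `[[`, "train")))))
    expect_setequal(vals, all_ids)
    for (f in folds) expect_length(intersect(f$train, f$val), 0)
  }
  expect_error(make_folds(1:3, 5), "fewer")
  # seeded determinism
  expect_identical(make_folds(1:20, 5, seed = 7), make_folds(1:20, 5, seed = 7))
})

test_that("train/validation split is seeded and 4:1 by default", {
  sp <- split_train_val(100, seed = 3)
  expect_equal(length(sp$val), 20)
  expect_equal(length(sp$train), 80)
  expect_length(intersect(sp$train, sp$val), 0)
  expect_identical(sp, split_train_val(100, seed = 3))
})

make_tiny_dataset <- function(n, seed, size = 32L) {
  cfg <- phantom_config(image_height = size, image_width = size,
                        lesions_per_image_range = c(1L, 2L),
                        lesion_diameter_range_mm = c(2, 4), seed = seed)
  generate_phantom_dataset(cfg, n)
}

test_that("early stopping halts after exactly `patience` non-improving epochs", {
  ds <- make_tiny_dataset(2, seed = 41)
  # a vanishing learning rate freezes the weights, so the validation loss
  # never improves after epoch 1 and the stopping rule fires exactly
  cfg <- train_config(stage = "coarse", learning_rate = 1e-12, max_epochs = 50,
                      batch_size = 2, early_stopping_patience = 3,
                      width_factor = 16, augment = FALSE, max_restarts = 0,
                      seed = 1)
  r <- train_stage(ds, cfg, validation = ds)
  expect_equal(nrow(r$history), 1 + 3)
  expect_equal(r$best_epoch, 1)
})

test_that("two runs with identical config and seed produce identical histories", {
  ds <- make_tiny_dataset(3, seed = 42)
  cfg <- train_config(stage = "coarse", learning_rate = 0.005, max_epochs = 3,
                      batch_size = 2, early_stopping_patience = 5,
                      width_factor = 16, augment = TRUE, max_restarts = 0,
                      seed = 9)
  r1 <- train_stage(ds, cfg, validation = ds)
  r2 <- train_stage(ds, cfg, validation = ds)
  expect_identical(r1$history, r2$history)
  expect_identical(r1$params, r2$params)
})

test_that("the running-minimum validation loss is non-increasing and best weights are kept", {
  ds <- make_tiny_dataset(2, seed = 43)
  cfg <- train_config(stage = "coarse", learning_rate = 0.005, max_epochs = 6,
                      batch_size = 2, early_stopping_patience = 10,
                      width_factor = 16, augment = FALSE, max_restarts = 0,
                      seed = 2, lambda_sen = 10)
  r <- train_stage(ds, cfg, validation = ds)
  runmin <- cummin(r$history$val_loss)
  expect_true(all(diff(runmin) <= 1e-12))
  expect_equal(r$best_epoch, which.min(r$history$val_loss))
})

test_that("per-epoch loss history can be logged to CSV", {
  ds <- make_tiny_dataset(2, seed = 44)
  cfg <- train_config(stage = "coarse", learning_rate = 0.005, max_epochs = 2,
                      batch_size = 2, early_stopping_patience = 5,
                      width_factor = 16, augment = FALSE, max_restarts = 0,
                      seed = 3)
  f <- tempfile(fileext = ".csv")
  r <- train_stage(ds, cfg, validation = ds, log_csv = f)
  logged <- utils::read.csv(f)
  expect_equal(nrow(logged), nrow(r$history))
  expect_true(all(c("epoch", "loss_total", "loss_bce", "loss_dice",
                    "loss_sen") %in% names(logged)))
  unlink(f)
})

test_that("fine-stage patch sampling centres positives on lesions", {
  ds <- make_tiny_dataset(4, seed = 45, size = 48L)
  set.seed(1)
  patches <- microseg:::build_fine_patches(ds, roi_size = 32L)
  n_lesions <- sum(vapply(ds, function(s) nrow(extract_components(s$mask)),
                          numeric(1)))
  expect_gte(length(patches), n_lesions)
  pos <- patches[seq_len(n_lesions)]
  for (p in pos) {
    expect_equal(dim(p$image), c(32L, 32L))
    expect_gt(sum(p$mask), 0)  # positive windows contain lesion pixels
  }
})

test_that("cross-validation bookkeeping: row shape, hand-averaged mean, zero SD on duplicated folds", {
  ds <- make_tiny_dataset(10, seed = 46, size = 48L)
  cfg <- train_config(stage = "coarse", n_folds = 5, seed = 4)
  # cheap stand-in model exercising only the bookkeeping: hypointense
  # thresholding of the (normalized) slice
  fit <- function(train_samples, config) NULL
  predict_fn <- function(model, image) binarize(1 - image, 0.65)
  tbl <- crossvalidate(ds, cfg, fit = fit, predict_fn = predict_fn)
  expect_equal(nrow(tbl), 6)
  expect_equal(tbl$fold, c(as.character(1:5), "mean"))
  for (m in c("sen", "pre", "dsc", "f2", "jsc", "mcc")) {
    expect_equal(tbl[[m]][6], mean(tbl[[m]][1:5]), tolerance = 1e-12)
    expect_equal(tbl[[paste0(m, "_sd")]][6], sd(tbl[[m]][1:5]),
                 tolerance = 1e-12)
  }

  dup <- rep(ds[1], 10)  # every fold sees identical data
  tbl2 <- crossvalidate(dup, cfg, fit = fit, predict_fn = predict_fn)
  expect_equal(tbl2$dsc_sd[6], 0, tolerance = 1e-12)
})
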