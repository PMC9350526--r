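# Training protocol: Adam, joint loss, early stopping on validation loss,
# k-fold cross-validation, and fine-stage ROI sampling (positives around
# ground-truth lesions, hard negatives around coarse false positives).

#' Training configuration
#'
#' Clinical-protocol defaults: Adam with initial learning rate 2e-4, up to
#' 500 epochs at batch size 6, early stopping (patience 25 epochs on the
#' validation total loss), five-fold cross-validation, coarse input
#' 352 x 448, ROI size 32, and the stage default sensitivity weight
#' (lambda = 10 coarse, 1 fine). Desk-scale runs shrink `max_epochs`,
#' `width_factor` and the learning rate; the topology is unchanged.
#'
#' @param stage `"coarse"` or `"fine"`.
#' @param learning_rate Adam step size.
#' @param max_epochs Upper bound on training epochs.
#' @param batch_size Images (or ROI patches) per gradient step.
#' @param early_stopping_patience Epochs without validation-loss improvement
#'   before halting.
#' @param n_folds Folds for [crossvalidate()].
#' @param lambda_sen Sensitivity-loss weight; `NULL` selects the stage
#'   default via [lambda_default()].
#' @param coarse_input_size Expected coarse-stage slice size (informational;
#'   any size divisible by 16 is accepted at run time).
#' @param roi_size Fine-stage ROI side in pixels.
#' @param width_factor Channel divisor passed to the network specs.
#' @param augment Apply the augmentation stack to training samples.
#' @param val_fraction Train/validation split when no validation set is
#'   supplied (4:1).
#' @param grad_clip Global L2-norm bound on each batch gradient (stabilizes
#'   the early sensitivity-dominated updates); `Inf` disables clipping.
#' @param max_restarts The heavily imbalance-weighted objective occasionally
#'   collapses from a random initialization into a degenerate solution
#'   (everything foreground, or nothing found at all). As with restarted
#'   k-means, such runs are detected on the validation set and retrained from
#'   a different derived initialization, at most this many times.
#' @param seed Seed governing initialization, shuffling and augmentation.
#' @return An object of class `train_config`.
#' @export
train_config <- function(stage = c("coarse", "fine"), learning_rate = 2e-4,
                         max_epochs = 500L, batch_size = 6L,
                         early_stopping_patience = 25L, n_folds = 5L,
                         lambda_sen = NULL, coarse_input_size = c(352L, 448L),
                         roi_size = 32L, width_factor = 1L, augment = TRUE,
                         val_fraction = 0.2, grad_clip = 5,
                         max_restarts = 2L, seed = 1L) {
  stage <- match.arg(stage)
  stopifnot(learning_rate > 0, max_epochs >= 1, batch_size >= 1,
            early_stopping_patience >= 1, n_folds >= 2,
            val_fraction > 0, val_fraction < 1, grad_clip > 0,
            max_restarts >= 0)
  if (is.null(lambda_sen)) lambda_sen <- lambda_default(stage)
  stopifnot(lambda_sen >= 0)
  structure(list(stage = stage, learning_rate = learning_rate,
                 max_epochs = as.integer(max_epochs),
                 batch_size = as.integer(batch_size),
                 early_stopping_patience = as.integer(early_stopping_patience),
                 n_folds = as.integer(n_folds), lambda_sen = lambda_sen,
                 coarse_input_size = as.integer(coarse_input_size),
                 roi_size = as.integer(roi_size),
                 width_factor = as.integer(width_factor),
                 augment = isTRUE(augment), val_fraction = val_fraction,
                 grad_clip = grad_clip, max_restarts = as.integer(max_restarts),
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Seeded k-fold partition
#'
#' @param ids Vector of dataset identifiers (or indices).
#' @param n_folds Number of folds.
#' @param seed Shuffle seed.
#' @return List of `n_folds` elements, each `list(train=, val=)`; the
#'   validation sets partition `ids` with sizes differing by at most one.
#' @export
make_folds <- function(ids, n_folds, seed = 1L) {
  n <- length(ids)
  if (n < n_folds) stop("make_folds: fewer items than folds")
  perm <- with_seed(seed, sample(n))
  sizes <- rep(n %/% n_folds, n_folds)
  extra <- n %% n_folds
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  ends <- cumsum(sizes)
  starts <- c(1L, ends[-n_folds] + 1L)
  lapply(seq_len(n_folds), function(k) {
    val_idx <- perm[starts[k]:ends[k]]
    list(train = ids[sort(setdiff(perm, val_idx))], val = ids[sort(val_idx)])
  })
}

#' Seeded train/validation split (4:1 by default)
#'
#' @param n_or_ids Item count or identifier vector.
#' @param val_fraction Fraction held out for validation.
#' @param seed Shuffle seed.
#' @return `list(train=, val=)` of ids/indices.
#' @export
split_train_val <- function(n_or_ids, val_fraction = 0.2, seed = 1L) {
  ids <- if (length(n_or_ids) == 1L && is.numeric(n_or_ids)) {
    seq_len(n_or_ids)
  } else {
    n_or_ids
  }
  n <- length(ids)
  n_val <- max(1L, round(n * val_fraction))
  if (n_val >= n) stop("split_train_val: validation split leaves no training data")
  perm <- with_seed(seed, sample(n))
  list(train = ids[sort(perm[-seq_len(n_val)])],
       val = ids[sort(perm[seq_len(n_val)])])
}

# --- fine-stage ROI sampling -------------------------------------------------

# Positives: ROIs centred on ground-truth component centroids with +-jitter
# pixel translation. Negatives: ROIs centred on coarse-stage false-positive
# components when coarse weights are supplied, otherwise random lesion-free
# windows; capped at a 1:1 ratio with positives.
build_fine_patches <- function(dataset, roi_size, coarse = NULL, jitter = 4L) {
  pos <- list()
  neg <- list()
  for (s in dataset) {
    comps <- extract_components(s$mask)
    for (i in seq_len(nrow(comps))) {
      ctr <- c(comps$centroid_row[i], comps$centroid_col[i]) +
        sample(-jitter:jitter, 2L, replace = TRUE)
      img_roi <- crop_roi(s$image, ctr, roi_size)
      r <- img_roi$origin[1] + seq_len(roi_size)
      c <- img_roi$origin[2] + seq_len(roi_size)
      pos[[length(pos) + 1L]] <- list(image = img_roi$crop,
                                      mask = s$mask[r, c, drop = FALSE])
    }
    if (!is.null(coarse)) {
      prob <- res_unet_forward(s$image, coarse$params, coarse$spec)
      cand <- extract_components(binarize(prob, 0.5))
      for (i in seq_len(nrow(cand))) {
        px <- cand$pixels[[i]] + 1L
        if (any(s$mask[px] == 1L)) next  # overlaps truth: not a false positive
        img_roi <- crop_roi(s$image, c(cand$centroid_row[i], cand$centroid_col[i]),
                            roi_size)
        r <- img_roi$origin[1] + seq_len(roi_size)
        c <- img_roi$origin[2] + seq_len(roi_size)
        neg[[length(neg) + 1L]] <- list(image = img_roi$crop,
                                        mask = s$mask[r, c, drop = FALSE])
      }
    } else {
      for (try in 1:10) {
        ctr <- c(runif(1, 0, nrow(s$image) - 1), runif(1, 0, ncol(s$image) - 1))
        img_roi <- crop_roi(s$image, ctr, roi_size)
        r <- img_roi$origin[1] + seq_len(roi_size)
        c <- img_roi$origin[2] + seq_len(roi_size)
        if (all(s$mask[r, c] == 0L)) {
          neg[[length(neg) + 1L]] <- list(image = img_roi$crop,
                                          mask = s$mask[r, c, drop = FALSE])
          break
        }
      }
    }
  }
  if (length(neg) > length(pos)) neg <- neg[sample(length(neg), length(pos))]
  c(pos, neg)
}

# --- single-stage trainer ----------------------------------------------------

stage_spec <- function(config) {
  if (config$stage == "coarse") {
    res_unet_spec(width_factor = config$width_factor)
  } else {
    frn_spec(width_factor = config$width_factor)
  }
}

stage_forward_tape <- function(stage, params, spec, x) {
  if (stage == "coarse") res_unet_tape(params, spec, x) else frn_tape(params, spec, x)
}

#' Train one cascade stage
#'
#' Runs seeded mini-batch Adam on the joint loss. Each epoch reshuffles the
#' training set, optionally augments every sample, and evaluates the
#' validation total loss plus validation sensitivity and Dice (at threshold
#' 0.5). Training halts at `max_epochs` or after
#' `early_stopping_patience` epochs without validation-loss improvement; the
#' weights with the best validation loss are returned.
#'
#' For the fine stage the dataset is converted to ROI patches
#' (ground-truth-centred positives with small jitter; hard negatives from
#' coarse false positives when `coarse` is given).
#'
#' @param dataset List of samples (`image`, `mask`), e.g. from
#'   [generate_phantom_dataset()].
#' @param config A [train_config()].
#' @param spec Optional network spec; defaults to the stage spec at
#'   `config$width_factor`.
#' @param validation Optional held-out sample list; if `NULL` a seeded 4:1
#'   split of `dataset` is used.
#' @param coarse Optional `list(params=, spec=)` of a trained coarse stage
#'   (fine-stage negative mining).
#' @param log_csv Optional path; the per-epoch loss history is written there
#'   as CSV.
#' @return List with `params` (best weights), `spec`, `history` (tibble:
#'   epoch, total/bce/dice/sen training losses, validation loss, validation
#'   sen and dsc), `best_epoch`, `degenerate` (whether the returned solution
#'   still fails the collapse check) and `restarts` (restarts consumed).
#' @export
train_stage <- function(dataset, config, spec = NULL, validation = NULL,
                        coarse = NULL, log_csv = NULL) {
  stopifnot(inherits(config, "train_config"))
  if (length(dataset) == 0L) stop("train_stage: empty dataset")
  if (is.null(spec)) spec <- stage_spec(config)

  prep <- with_seed(config$seed, {
    if (is.null(validation)) {
      if (length(dataset) >= 2L) {
        sp <- split_train_val(length(dataset), config$val_fraction, config$seed)
        validation <- dataset[sp$val]
        dataset <- dataset[sp$train]
      } else {
        validation <- dataset
      }
    }
    if (config$stage == "fine") {
      dataset <- build_fine_patches(dataset, config$roi_size, coarse)
      validation <- build_fine_patches(validation, config$roi_size, coarse,
                                       jitter = 0L)
      if (length(dataset) == 0L) stop("train_stage: no fine-stage patches")
    }
    list(train = dataset, val = validation)
  })

  attempt <- 0L
  repeat {
    run_seed <- (config$seed + 7919L * attempt) %% .Machine$integer.max
    res <- with_seed(run_seed, train_stage_once(prep$train, prep$val, config,
                                                spec))
    if (!res$degenerate || attempt >= config$max_restarts) break
    attempt <- attempt + 1L
  }
  if (!is.null(log_csv)) {
    utils::write.csv(res$history, log_csv, row.names = FALSE)
  }
  res$restarts <- attempt
  res
}

# one seeded optimization run; callers handle degeneracy restarts
train_stage_once <- function(dataset, validation, config, spec) {
  params <- if (config$stage == "coarse") {
    init_res_unet(spec)
  } else {
    init_frn(spec)
  }
  opt <- adam_new(params)
  lambda <- config$lambda_sen
  policy <- augmentation_policy()
  n <- length(dataset)
  best <- Inf
  best_params <- params
  best_epoch <- 0L
  wait <- 0L
  hist <- vector("list", config$max_epochs)

  for (epoch in seq_len(config$max_epochs)) {
    ord <- sample(n)
    ep <- c(total = 0, bce = 0, dice = 0, sen = 0)
    nb <- 0L
    for (start in seq(1L, n, by = config$batch_size)) {
      idx <- ord[start:min(start + config$batch_size - 1L, n)]
      grads <- NULL
      bl <- c(total = 0, bce = 0, dice = 0, sen = 0)
      for (i in idx) {
        s <- dataset[[i]]
        if (config$augment) {
          s <- augment_pair(s$image, s$mask, policy)
        }
        ft <- stage_forward_tape(config$stage, params, spec, s$image)
        y_hat <- tp_value(ft$tp, ft$out)
        l <- total_loss(y_hat, s$mask, lambda = lambda)
        # back-propagate from the logits (sigmoid + BCE fused) so a
        # saturated output never kills the cross-entropy gradient
        logit_id <- ft$tp$nodes[[ft$out]]$a
        g <- total_loss_grad_logit(y_hat, s$mask, lambda = lambda)
        bw <- tape_backward(ft$tp, params, logit_id, g)
        grads <- if (is.null(grads)) bw$params else {
          for (nm in names(bw$params)) {
            grads[[nm]]$W <- grads[[nm]]$W + bw$params[[nm]]$W
            grads[[nm]]$b <- grads[[nm]]$b + bw$params[[nm]]$b
          }
          grads
        }
        bl <- bl + c(total = l$total, bce = l$bce, dice = l$dice, sen = l$sen)
      }
      gnorm2 <- 0
      for (nm in names(grads)) {
        grads[[nm]]$W <- grads[[nm]]$W / length(idx)
        grads[[nm]]$b <- grads[[nm]]$b / length(idx)
        gnorm2 <- gnorm2 + sum(grads[[nm]]$W^2) + sum(grads[[nm]]$b^2)
      }
      if (is.finite(config$grad_clip) && sqrt(gnorm2) > config$grad_clip) {
        scale <- config$grad_clip / sqrt(gnorm2)
        for (nm in names(grads)) {
          grads[[nm]]$W <- grads[[nm]]$W * scale
          grads[[nm]]$b <- grads[[nm]]$b * scale
        }
      }
      st <- adam_step(params, grads, opt, lr = config$learning_rate)
      params <- st$params
      opt <- st$state
      ep <- ep + bl / length(idx)
      nb <- nb + 1L
    }
    ep <- ep / nb

    vl <- 0
    vsen <- 0
    vdsc <- 0
    for (s in validation) {
      pr <- if (config$stage == "coarse") {
        res_unet_forward(s$image, params, spec)
      } else {
        frn_forward(s$image, params, spec)
      }
      vl <- vl + total_loss(pr, s$mask, lambda = lambda)$total
      pm <- pixel_metrics(confusion_counts(binarize(pr, 0.5), s$mask))
      vsen <- vsen + pm$sen
      vdsc <- vdsc + pm$dsc
    }
    nv <- length(validation)
    vl <- vl / nv
    hist[[epoch]] <- tibble::tibble(
      epoch = epoch, loss_total = ep[["total"]], loss_bce = ep[["bce"]],
      loss_dice = ep[["dice"]], loss_sen = ep[["sen"]], val_loss = vl,
      val_sen = vsen / nv, val_dsc = vdsc / nv)

    if (vl < best - 1e-9) {
      best <- vl
      best_params <- params
      best_epoch <- epoch
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= config$early_stopping_patience) break
    }
  }
  history <- do.call(rbind, hist[!vapply(hist, is.null, logical(1))])

  # degeneracy check on the returned weights: predicting the majority of the
  # field as lesion, or detecting no true foreground pixel at all, is a
  # collapsed optimum, not a model
  fg <- 0
  dsen <- 0
  truth_nonempty <- FALSE
  for (s in validation) {
    pr <- if (config$stage == "coarse") {
      res_unet_forward(s$image, best_params, spec)
    } else {
      frn_forward(s$image, best_params, spec)
    }
    b <- binarize(pr, 0.5)
    fg <- fg + mean(b)
    if (any(s$mask == 1L)) {
      truth_nonempty <- TRUE
      dsen <- dsen + pixel_metrics(confusion_counts(b, s$mask))$sen
    }
  }
  fg <- fg / length(validation)
  degenerate <- fg > 0.5 || (truth_nonempty && dsen == 0)

  list(params = best_params, spec = spec, history = history,
       best_epoch = best_epoch, degenerate = degenerate)
}

#' Train the full two-stage cascade
#'
#' Trains the coarse residual U-Net, then the fine FRN on ROI patches with
#' hard negatives mined from the trained coarse stage.
#'
#' @param dataset Training samples.
#' @param coarse_config,fine_config [train_config()]s for the two stages.
#' @param validation Optional held-out samples (shared by both stages).
#' @param cascade A [cascade_config()] stored with the model.
#' @return List with `coarse`, `fine` (each `params`, `spec`, `history`) and
#'   `cascade_config`; usable with [predict_cascade()].
#' @export
train_cascade <- function(dataset, coarse_config, fine_config,
                          validation = NULL, cascade = cascade_config()) {
  co <- train_stage(dataset, coarse_config, validation = validation)
  fi <- train_stage(dataset, fine_config, validation = validation,
                    coarse = list(params = co$params, spec = co$spec))
  list(coarse = co, fine = fi, cascade_config = cascade)
}

#' Predict a final mask with a trained cascade model
#'
#' @param model Output of [train_cascade()].
#' @param image Normalized slice matrix.
#' @return The [run_cascade()] result list.
#' @export
predict_cascade <- function(model, image) {
  run_cascade(image, model$coarse$params, model$coarse$spec,
              model$fine$params, model$fine$spec, model$cascade_config)
}

# --- cross-validation --------------------------------------------------------

#' k-fold cross-validation with per-fold metric reporting
#'
#' Partitions the dataset with [make_folds()], fits a model on each training
#' split, predicts the held-out split, and reports the six pixel metrics
#' (per-image mean and SD within each fold). The final row is the unweighted
#' mean across folds with the across-fold SD.
#'
#' @param dataset List of samples.
#' @param config A [train_config()] (supplies `n_folds` and `seed`).
#' @param fit `function(train_samples, config)` returning a model; defaults
#'   to training the full cascade with `config` for both stages.
#' @param predict_fn `function(model, image)` returning a binary mask;
#'   defaults to [predict_cascade()].
#' @return Tibble with rows `fold 1..k` and `"mean"`; columns `fold`, the six
#'   metric means, their SDs (`*_sd`), and `fp_avg`.
#' @export
crossvalidate <- function(dataset, config, fit = NULL, predict_fn = NULL) {
  stopifnot(inherits(config, "train_config"))
  if (is.null(fit)) {
    fit <- function(train_samples, cfg) {
      fine_cfg <- cfg
      fine_cfg$stage <- "fine"
      fine_cfg$lambda_sen <- lambda_default("fine")
      train_cascade(train_samples, cfg, fine_cfg,
                    cascade = cascade_config(roi_size = cfg$roi_size))
    }
  }
  if (is.null(predict_fn)) predict_fn <- function(model, image) predict_cascade(model, image)$mask
  folds <- make_folds(seq_along(dataset), config$n_folds, config$seed)
  metrics <- c("sen", "pre", "dsc", "f2", "jsc", "mcc")
  fold_rows <- lapply(seq_along(folds), function(k) {
    model <- fit(dataset[folds[[k]]$train], config)
    val <- dataset[folds[[k]]$val]
    preds <- lapply(val, function(s) predict_fn(model, s$image))
    per <- evaluate_segmentation(preds, lapply(val, `[[`, "mask"))
    row <- tibble::tibble(fold = as.character(k))
    for (m in metrics) {
      row[[m]] <- mean(per[[m]])
      row[[paste0(m, "_sd")]] <- sd(per[[m]])
    }
    row$fp_avg <- mean(per$fp_components)
    row
  })
  tbl <- do.call(rbind, fold_rows)
  mean_row <- tibble::tibble(fold = "mean")
  for (m in metrics) {
    mean_row[[m]] <- mean(tbl[[m]])
    mean_row[[paste0(m, "_sd")]] <- sd(tbl[[m]])
  }
  mean_row$fp_avg <- mean(tbl$fp_avg)
  rbind(tbl, mean_row)
}
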