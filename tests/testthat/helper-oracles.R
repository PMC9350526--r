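# Independent brute-force oracles, deliberately written as plain pixel loops
# so they share no code path with the package implementations they check.

bf_bce <- function(y_hat, y, clip = 1e-7) {
  y_hat <- as.vector(y_hat)
  y <- as.vector(y)
  s <- 0
  for (i in seq_along(y_hat)) {
    p <- min(max(y_hat[i], clip), 1 - clip)
    s <- s - (y[i] * log(p) + (1 - y[i]) * log(1 - p))
  }
  s / length(y_hat)
}

bf_dice <- function(y_hat, y, smooth = 1) {
  y_hat <- as.vector(y_hat)
  y <- as.vector(y)
  num <- 0
  dp <- 0
  dt <- 0
  for (i in seq_along(y_hat)) {
    num <- num + y_hat[i] * y[i]
    dp <- dp + y_hat[i]
    dt <- dt + y[i]
  }
  if (dp + dt + smooth == 0) return(0)
  1 - (2 * num + smooth) / (dp + dt + smooth)
}

bf_sen <- function(y_hat, y, smooth = 1) {
  y_hat <- as.vector(y_hat)
  y <- as.vector(y)
  num <- 0
  dt <- 0
  for (i in seq_along(y_hat)) {
    num <- num + y_hat[i] * y[i]
    dt <- dt + y[i]
  }
  if (dt + smooth == 0) return(0)
  1 - (num + smooth) / (dt + smooth)
}

bf_confusion <- function(pred, truth) {
  tp <- 0; tn <- 0; fp <- 0; fn <- 0
  for (i in seq_along(pred)) {
    if (pred[i] == 1 && truth[i] == 1) tp <- tp + 1
    if (pred[i] == 0 && truth[i] == 0) tn <- tn + 1
    if (pred[i] == 1 && truth[i] == 0) fp <- fp + 1
    if (pred[i] == 0 && truth[i] == 1) fn <- fn + 1
  }
  list(tp = tp, tn = tn, fp = fp, fn = fn)
}

bf_metrics <- function(pred, truth) {
  cc <- bf_confusion(pred, truth)
  tp <- cc$tp; tn <- cc$tn; fp <- cc$fp; fn <- cc$fn
  if (tp + fn == 0 && tp + fp == 0) {
    return(list(sen = 1, pre = 1, dsc = 1, f2 = 1, jsc = 1, mcc = 1))
  }
  dv <- function(a, b) if (b == 0) 0 else a / b
  sen <- dv(tp, tp + fn)
  pre <- dv(tp, tp + fp)
  mden <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  list(sen = sen, pre = pre,
       dsc = dv(2 * tp, 2 * tp + fp + fn),
       f2 = dv(5 * pre * sen, 4 * pre + sen),
       jsc = dv(tp, tp + fn + fp),
       mcc = if (mden == 0) 0 else (tp * tn - fp * fn) / mden)
}

# 4/8-connected component labelling by repeated flooding (slow, independent
# of the C++ implementation).
bf_label8 <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  cur <- 0L
  for (j in seq_len(W)) for (i in seq_len(H)) {
    if (mask[i, j] == 1 && lab[i, j] == 0L) {
      cur <- cur + 1L
      queue <- list(c(i, j))
      lab[i, j] <- cur
      while (length(queue)) {
        p <- queue[[1]]
        queue <- queue[-1]
        for (di in -1:1) for (dj in -1:1) {
          ii <- p[1] + di; jj <- p[2] + dj
          if (ii >= 1 && ii <= H && jj >= 1 && jj <= W &&
              mask[ii, jj] == 1 && lab[ii, jj] == 0L) {
            lab[ii, jj] <- cur
            queue[[length(queue) + 1L]] <- c(ii, jj)
          }
        }
      }
    }
  }
  lab
}

# Direct 2D convolution oracle (dense loops) matching the package's weight
# layout: W[cout, c*k*k + ki*k + kj + 1].
bf_conv2d <- function(x, Wm, b, k, stride = 1, pad = 0, dil = 1) {
  d <- dim(x); H <- d[1]; W <- d[2]; C <- d[3]
  eff <- (k - 1) * dil + 1
  Ho <- (H + 2 * pad - eff) %/% stride + 1
  Wo <- (W + 2 * pad - eff) %/% stride + 1
  Cout <- nrow(Wm)
  y <- array(0, c(Ho, Wo, Cout))
  for (co in seq_len(Cout)) for (i in seq_len(Ho)) for (j in seq_len(Wo)) {
    acc <- b[co]
    for (c in seq_len(C)) for (ki in 0:(k - 1)) for (kj in 0:(k - 1)) {
      hi <- (i - 1) * stride - pad + ki * dil + 1
      wi <- (j - 1) * stride - pad + kj * dil + 1
      if (hi >= 1 && hi <= H && wi >= 1 && wi <= W) {
        acc <- acc + Wm[co, (c - 1) * k * k + ki * k + kj + 1] * x[hi, wi, c]
      }
    }
    y[i, j, co] <- acc
  }
  y
}

# Exhaustive-threshold average precision oracle on pooled pixels.
bf_ap <- function(prob, truth) {
  s <- as.vector(prob)
  y <- as.vector(truth)
  ths <- sort(unique(s), decreasing = TRUE)
  npos <- sum(y == 1)
  prev_r <- 0
  ap <- 0
  for (t in ths) {
    sel <- s >= t
    p <- sum(y[sel] == 1) / sum(sel)
    r <- sum(y[sel] == 1) / npos
    ap <- ap + (r - prev_r) * p
    prev_r <- r
  }
  ap
}

# Set every weight/bias of a parameter list to zero (identity-shortcut tests).
zero_params <- function(params, names = NULL) {
  nms <- if (is.null(names)) names(params) else names
  for (nm in nms) {
    params[[nm]]$W[] <- 0
    params[[nm]]$b[] <- 0
  }
  params
}
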