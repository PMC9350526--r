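#' @useDynLib microseg, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif sd
NULL

# ---------------------------------------------------------------------------
# Reverse-mode tape over (H, W, C) feature maps.
#
# Networks are built define-by-run: each tp_* call computes the value eagerly
# and records the node so tape_backward() can replay the chain rule.  This is
# the whole "framework" the two segmentation networks need: convolution,
# ReLU, logistic sigmoid, elementwise add, channel concat, bilinear resize
# and a global-average-pool broadcast.
# ---------------------------------------------------------------------------

new_tape <- function() {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- list()
  tp
}

tp_push <- function(tp, node) {
  id <- length(tp$nodes) + 1L
  tp$nodes[[id]] <- node
  id
}

tp_value <- function(tp, id) {
  force(id)
  tp$nodes[[id]]$value
}

as_fmap <- function(x) {
  if (is.null(dim(x))) dim(x) <- c(length(x), 1L, 1L)
  if (length(dim(x)) == 2L) dim(x) <- c(dim(x), 1L)
  stopifnot(length(dim(x)) == 3L)
  x
}

tp_input <- function(tp, x) tp_push(tp, list(op = "input", value = as_fmap(x)))

tp_conv <- function(tp, a, params, name, stride = 1L, pad = NULL, dil = 1L) {
  force(a)
  p <- params[[name]]
  if (is.null(p)) stop("unknown conv parameter: ", name)
  if (is.null(pad)) pad <- if (p$k == 1L) 0L else dil * ((p$k - 1L) %/% 2L)
  x <- tp$nodes[[a]]$value
  if (dim(x)[3] != p$cin) {
    stop(sprintf("conv '%s': expected %d input channels, got %d",
                 name, p$cin, dim(x)[3]))
  }
  y <- cpp_conv2d(x, p$W, p$b, p$k, as.integer(stride), as.integer(pad),
                  as.integer(dil))
  tp_push(tp, list(op = "conv", a = a, name = name, k = p$k,
                   stride = as.integer(stride), pad = as.integer(pad),
                   dil = as.integer(dil), value = y))
}

tp_relu <- function(tp, a) {
  force(a)
  x <- tp$nodes[[a]]$value
  tp_push(tp, list(op = "relu", a = a, value = x * (x > 0)))
}

tp_sigmoid <- function(tp, a) {
  force(a)
  x <- tp$nodes[[a]]$value
  tp_push(tp, list(op = "sigmoid", a = a, value = 1 / (1 + exp(-x))))
}

tp_add <- function(tp, a, b) {
  force(a)
  force(b)
  tp_push(tp, list(op = "add", a = a, b = b,
                   value = tp$nodes[[a]]$value + tp$nodes[[b]]$value))
}

tp_concat <- function(tp, a, b) {
  force(a)
  force(b)
  va <- tp$nodes[[a]]$value
  vb <- tp$nodes[[b]]$value
  stopifnot(all(dim(va)[1:2] == dim(vb)[1:2]))
  v <- array(0, c(dim(va)[1], dim(va)[2], dim(va)[3] + dim(vb)[3]))
  v[, , seq_len(dim(va)[3])] <- va
  v[, , dim(va)[3] + seq_len(dim(vb)[3])] <- vb
  tp_push(tp, list(op = "concat", a = a, b = b, ca = dim(va)[3], value = v))
}

tp_resize <- function(tp, a, h2, w2) {
  force(a)
  x <- tp$nodes[[a]]$value
  tp_push(tp, list(op = "resize", a = a, h = dim(x)[1], w = dim(x)[2],
                   value = cpp_resize_bilinear(x, as.integer(h2), as.integer(w2))))
}

# Global average pooling broadcast back to the input's spatial size:
# y[i, j, c] = mean over (i, j) of x[, , c].
tp_gap_broadcast <- function(tp, a) {
  force(a)
  x <- tp$nodes[[a]]$value
  mu <- apply(x, 3, mean)
  v <- array(rep(mu, each = dim(x)[1] * dim(x)[2]), dim(x))
  tp_push(tp, list(op = "gapb", a = a, value = v))
}

acc_grad <- function(cur, g) if (is.null(cur)) g else cur + g

#' @keywords internal
tape_backward <- function(tp, params, out, gout) {
  n <- length(tp$nodes)
  gnode <- vector("list", n)
  gnode[[out]] <- as_fmap(gout)
  pg <- list()
  for (id in seq.int(n, 1L)) {
    node <- tp$nodes[[id]]
    g <- gnode[[id]]
    if (is.null(g)) next
    switch(node$op,
      input = NULL,
      conv = {
        r <- cpp_conv2d_backward(tp$nodes[[node$a]]$value, params[[node$name]]$W,
                                 g, node$k, node$stride, node$pad, node$dil)
        gnode[[node$a]] <- acc_grad(gnode[[node$a]], r$gx)
        if (is.null(pg[[node$name]])) {
          pg[[node$name]] <- list(W = r$gw, b = r$gb)
        } else {
          pg[[node$name]]$W <- pg[[node$name]]$W + r$gw
          pg[[node$name]]$b <- pg[[node$name]]$b + r$gb
        }
      },
      relu = {
        x <- tp$nodes[[node$a]]$value
        gnode[[node$a]] <- acc_grad(gnode[[node$a]], g * (x > 0))
      },
      sigmoid = {
        y <- node$value
        gnode[[node$a]] <- acc_grad(gnode[[node$a]], g * y * (1 - y))
      },
      add = {
        gnode[[node$a]] <- acc_grad(gnode[[node$a]], g)
        gnode[[node$b]] <- acc_grad(gnode[[node$b]], g)
      },
      concat = {
        ca <- node$ca
        ga <- g[, , seq_len(ca), drop = FALSE]
        gb <- g[, , ca + seq_len(dim(g)[3] - ca), drop = FALSE]
        gnode[[node$a]] <- acc_grad(gnode[[node$a]], ga)
        gnode[[node$b]] <- acc_grad(gnode[[node$b]], gb)
      },
      resize = {
        gnode[[node$a]] <- acc_grad(
          gnode[[node$a]],
          cpp_resize_bilinear_backward(g, node$h, node$w))
      },
      gapb = {
        x <- tp$nodes[[node$a]]$value
        npix <- dim(x)[1] * dim(x)[2]
        gsum <- apply(g, 3, sum) / npix
        gnode[[node$a]] <- acc_grad(
          gnode[[node$a]],
          array(rep(gsum, each = npix), dim(x)))
      },
      stop("unknown op on tape: ", node$op)
    )
  }
  list(params = pg, input = gnode[[1L]])
}

# ---------------------------------------------------------------------------
# Parameters and optimizer
# ---------------------------------------------------------------------------

# He-initialized convolution parameters (matrix layout documented in
# src/kernels.cpp). zero = TRUE initializes weights at 0: used for the last
# convolution of every residual branch so each residual block starts as the
# identity and activation scale stays bounded at init (the usual substitute
# for normalization layers in unnormalized residual nets).
conv_param <- function(k, cin, cout, zero = FALSE) {
  fan_in <- cin * k * k
  W <- if (zero) {
    matrix(0, cout, fan_in)
  } else {
    matrix(rnorm(cout * fan_in, sd = sqrt(2 / fan_in)), cout, fan_in)
  }
  list(W = W, b = numeric(cout), k = as.integer(k), cin = as.integer(cin),
       cout = as.integer(cout))
}

n_parameters <- function(params) {
  sum(vapply(params, function(p) length(p$W) + length(p$b), numeric(1)))
}

adam_new <- function(params) {
  st <- lapply(params, function(p) {
    list(mW = p$W * 0, vW = p$W * 0, mb = p$b * 0, vb = p$b * 0)
  })
  list(t = 0L, s = st)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    s <- state$s[[nm]]
    s$mW <- beta1 * s$mW + (1 - beta1) * g$W
    s$vW <- beta2 * s$vW + (1 - beta2) * g$W^2
    s$mb <- beta1 * s$mb + (1 - beta1) * g$b
    s$vb <- beta2 * s$vb + (1 - beta2) * g$b^2
    params[[nm]]$W <- params[[nm]]$W - lr * (s$mW / bc1) / (sqrt(s$vW / bc2) + eps)
    params[[nm]]$b <- params[[nm]]$b - lr * (s$mb / bc1) / (sqrt(s$vb / bc2) + eps)
    state$s[[nm]] <- s
  }
  list(params = params, state = state)
}

# Evaluate code with a temporary RNG seed, restoring the caller's stream.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (!is.null(old)) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
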