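test_that("an S1 block with a zeroed residual branch is the identity on nonnegative input", {
  set.seed(1)
  w <- microseg:::init_res_block("S1", cin = 4L)
  w <- zero_params(w)
  x <- array(abs(rnorm(16 * 16 * 4)), c(16, 16, 4))
  expect_equal(res_block_forward(x, w, "S1"), x, tolerance = 1e-14)
})

test_that("S1 preserves shape at the stated feature size and S2 projects channels/stride", {
  set.seed(2)
  w64 <- microseg:::init_res_block("S1", cin = 64L)
  x <- array(rnorm(16 * 16 * 64), c(16, 16, 64))
  expect_equal(dim(res_block_forward(x, w64, "S1")), c(16L, 16L, 64L))
  w2 <- microseg:::init_res_block("S2", cin = 8L, cout = 16L)
  y <- res_block_forward(array(rnorm(12 * 12 * 8), c(12, 12, 8)), w2, "S2",
                         stride = 2L)
  expect_equal(dim(y), c(6L, 6L, 16L))
})

test_that("a single-pixel S1 block matches scalar arithmetic", {
  w <- microseg:::init_res_block("S1", cin = 1L)
  w <- zero_params(w)
  w1 <- 0.7
  w2 <- -0.3
  # only the centre tap (ki=kj=1 -> 0-based column index 1*3+1 = 4) touches a
  # 1x1 input under padding 1
  w$blk_c1$W[1, 5] <- w1
  w$blk_c2$W[1, 5] <- w2
  x <- array(2, c(1, 1, 1))
  expected <- max(0, 2 + w2 * max(0, w1 * 2))
  expect_equal(as.numeric(res_block_forward(x, w, "S1")), expected,
               tolerance = 1e-12)
})

test_that("the residual U-Net maps input resolution to identical output resolution", {
  spec <- res_unet_spec(width_factor = 16L)
  p <- init_res_unet(spec, seed = 4)
  small <- res_unet_forward(matrix(runif(96 * 128), 96, 128), p, spec)
  expect_equal(dim(small), c(96L, 128L))
  expect_true(all(small > 0 & small < 1))
  clinical <- res_unet_forward(matrix(runif(352 * 448), 352, 448), p, spec)
  expect_equal(dim(clinical), c(352L, 448L))
  expect_error(res_unet_forward(matrix(0.5, 100, 100), p, spec),
               "divisible by 16")
})

test_that("repeated forward passes are bit-identical for fixed weights", {
  spec <- res_unet_spec(width_factor = 16L)
  p <- init_res_unet(spec, seed = 5)
  x <- matrix(runif(96 * 128), 96, 128)
  expect_identical(res_unet_forward(x, p, spec), res_unet_forward(x, p, spec))
})

test_that("parameter counts are a pure function of the spec", {
  expect_equal(count_parameters(init_res_unet(res_unet_spec(width_factor = 16L),
                                              seed = 1)), 55885)
  expect_equal(count_parameters(init_res_unet(res_unet_spec(width_factor = 16L),
                                              seed = 99)), 55885)
  expect_equal(count_parameters(init_frn(frn_spec(width_factor = 16L),
                                         seed = 1)), 599)
  # widths scale quadratically: wf 8 has ~4x the parameters of wf 16
  p8 <- count_parameters(init_res_unet(res_unet_spec(width_factor = 8L), seed = 1))
  expect_gt(p8, 3.5 * 55885)
  expect_lt(p8, 4.5 * 55885)
})

test_that("R-ASPP with zeroed convolutions is the identity shortcut", {
  w <- microseg:::init_r_aspp(4L)
  w <- zero_params(w)
  x <- array(rnorm(20 * 20 * 4), c(20, 20, 4))
  expect_equal(r_aspp_forward(x, w), x, tolerance = 1e-14)
})

test_that("R-ASPP preserves channels and spatial size", {
  set.seed(6)
  w <- microseg:::init_r_aspp(32L)
  x <- array(rnorm(32 * 32 * 32), c(32, 32, 32))
  expect_equal(dim(r_aspp_forward(x, w)), c(32L, 32L, 32L))
})

test_that("a dilated convolution branch matches a hand-unrolled direct convolution", {
  set.seed(7)
  x <- array(rnorm(25), c(5, 5, 1))
  Wm <- matrix(rnorm(9), 1, 9)
  b <- 0.1
  for (d in c(1L, 2L)) {
    y <- microseg:::cpp_conv2d(x, Wm, b, 3L, 1L, d, d)
    expect_equal(y, bf_conv2d(x, Wm, b, 3, 1, d, d), tolerance = 1e-12)
  }
})

test_that("the FRN accepts all four ROI sizes and never changes resolution internally", {
  spec <- frn_spec(width_factor = 16L)
  p <- init_frn(spec, seed = 8)
  for (s in c(16L, 32L, 64L, 128L)) {
    ft <- microseg:::frn_tape(p, spec, matrix(runif(s * s), s, s))
    dims <- lapply(ft$tp$nodes, function(nd) dim(nd$value)[1:2])
    for (d in dims) expect_equal(d, c(s, s))
    out <- ft$tp$nodes[[ft$out]]$value
    expect_true(all(out > 0 & out < 1))
  }
  expect_error(frn_forward(matrix(0.5, 8, 8), p, spec), "receptive-field")
  expect_error(frn_forward(matrix(0.5, 16, 32), p, spec), "square")
})

test_that("gradients flow undamped through a chain of zero-residual S1 blocks", {
  # surrogate for the residual gradient identity: with residual branches
  # zeroed and strictly positive input, k stacked S1 blocks have identity
  # Jacobian, so the back-propagated gradient equals the output gradient
  p <- list()
  for (i in 1:4) p <- c(p, microseg:::init_res_block("S1", 2L,
                                                     prefix = paste0("b", i)))
  p <- zero_params(p)
  tp <- microseg:::new_tape()
  a <- microseg:::tp_input(tp, array(abs(rnorm(8 * 8 * 2)) + 0.1, c(8, 8, 2)))
  h <- a
  for (i in 1:4) h <- microseg:::tp_s1_block(tp, h, p, paste0("b", i))
  gout <- array(rnorm(8 * 8 * 2), c(8, 8, 2))
  bw <- microseg:::tape_backward(tp, p, h, gout)
  expect_equal(bw$input, gout, tolerance = 1e-14)
})

test_that("checkpoints round-trip and refuse mismatched architectures", {
  spec <- frn_spec(width_factor = 16L)
  p <- init_frn(spec, seed = 9)
  f <- tempfile(fileext = ".rds")
  save_checkpoint(f, p, spec, stage = "fine")
  ck <- load_checkpoint(f, expected_spec = spec)
  expect_equal(ck$params, p)
  expect_error(load_checkpoint(f, expected_spec = frn_spec(width_factor = 8L)),
               "does not match")
  x <- matrix(runif(32 * 32), 32, 32)
  expect_identical(frn_forward(x, ck$params, ck$spec), frn_forward(x, p, spec))
  unlink(f)
})
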