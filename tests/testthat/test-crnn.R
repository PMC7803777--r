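test_that("the shape cascade of the default architecture is as derived", {
  sp <- shape_plan(crnn_spec())
  get <- function(layer) sp$dims[[match(layer, sp$layer)]]
  expect_equal(get("input"), c(21, 200, 200, 1))
  expect_equal(get("pool1"), c(100, 100, 32))   # size-preserving conv, 2x pool
  expect_equal(get("pool2"), c(50, 50, 32))
  expect_equal(get("pool3"), c(25, 25, 32))
  expect_equal(get("flatten"), c(21, 20000))    # 25*25*32 per frame
  expect_equal(get("lstm2"), 256)
  expect_equal(get("fc5"), 1)                   # scalar output
})

test_that("parameter count matches an independent hand computation", {
  # conv: F*(k^2*Cin) + F per block; lstm: 4*((Din+U)*U + U); fc: out*in + out
  conv <- (32 * 9 * 1 + 32) + (32 * 9 * 32 + 32) + (32 * 9 * 32 + 32)
  lstm <- 4 * ((20000 + 256) * 256 + 256) + 4 * ((256 + 256) * 256 + 256)
  fc <- (256 * 128 + 128) + (128 * 128 + 128) + (128 * 32 + 32) + (32 * 8 + 8) + (8 * 1 + 1)
  expect_equal(n_params(crnn_spec()), conv + lstm + fc)  # 21,341,105
  expect_equal(conv + lstm + fc, 21341105)
})

test_that("invalid specifications are rejected naming the field", {
  expect_error(crnn_spec(fc_widths = c(128, 2)), "fc_widths")
  expect_error(crnn_spec(input_px = 201), "input_px")
  expect_error(crnn_spec(kernel = 4), "kernel")
  expect_error(crnn_spec(dropout = 1), "dropout")
})

test_that("weight initialisation is a pure function of the seed", {
  sp <- tiny_spec()
  m1 <- crnn_build(sp, seed = 42)
  m2 <- crnn_build(sp, seed = 42)
  m3 <- crnn_build(sp, seed = 43)
  expect_identical(m1$state$theta, m2$state$theta)
  expect_false(identical(m1$state$theta, m3$state$theta))
})

test_that("forward output is a probability, deterministic, order-preserving", {
  sp <- tiny_spec()
  model <- crnn_build(sp, seed = 1)
  x <- tiny_batch(sp, B = 6)
  p <- crnn_forward(model, x)
  expect_length(p, 6)
  expect_true(all(p > 0 & p < 1))                       # sigmoid range
  expect_identical(crnn_forward(model, x), p)           # inference is deterministic

  # permuting segments permutes outputs identically (batch independence)
  perm <- c(3, 1, 6, 2, 5, 4)
  cols <- as.vector(vapply(perm, function(s) (s - 1) * sp$n_frames + seq_len(sp$n_frames),
                           numeric(sp$n_frames)))
  expect_equal(crnn_forward(model, x[, cols]), p[perm], tolerance = 1e-6)

  expect_error(crnn_forward(model, x[1:10, ]), "image size")
})

test_that("the convolutional encoder is shared across time", {
  sp <- tiny_spec()
  model <- crnn_build(sp, seed = 2)
  x <- tiny_batch(sp, B = 2)
  feats <- crnn_encode(model, x)
  perm <- sample(ncol(x))
  expect_equal(crnn_encode(model, x[, perm]), feats[, perm])
})

test_that("one small gradient step decreases the loss of a single segment", {
  sp <- tiny_spec()
  model <- crnn_build(sp, seed = 5)
  x <- tiny_batch(sp, B = 1, seed = 11)
  y <- 1
  spec_l <- scratchdetect:::spec_as_list(sp)
  lg <- scratchdetect:::cpp_loss_grad(model$state$theta, spec_l, x, y, -1L)
  theta2 <- model$state$theta - 1e-3 * lg$grad
  lg2 <- scratchdetect:::cpp_loss_grad(theta2, spec_l, x, y, -1L)
  expect_lt(lg2$loss, lg$loss)
})

test_that("checkpoints round-trip and reject mismatched architectures", {
  sp <- tiny_spec()
  model <- crnn_build(sp, seed = 9)
  x <- tiny_batch(sp, B = 2)
  p <- crnn_forward(model, x)
  dir <- file.path(tempdir(), "ckpt")
  save_crnn(model, dir)
  back <- load_crnn(dir)
  expect_identical(back$state$theta, model$state$theta)
  expect_equal(crnn_forward(back, x), p)
  # weights from a different architecture are refused
  other <- crnn_build(crnn_spec(input_px = 16, n_frames = 5, conv_filters = c(4, 4),
                                lstm_units = c(4, 4), fc_widths = c(8, 4, 1)), seed = 1)
  writeBin(other$state$theta, file.path(dir, "weights.bin"))
  expect_error(load_crnn(dir), "parameters")
})
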