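test_that("epoch sampling draws n_random + n_scratch references, shuffled", {
  ss <- separable_segset()
  cfg <- train_control(n_random = 150, n_scratch = 10, resize_px = 16, epochs = 1)
  set.seed(1)
  refs <- sample_epoch(ss, cfg)
  expect_equal(nrow(refs), 160)
  expect_true(all(refs$row %in% seq_len(nrow(ss$index))))
  # the n_scratch extra draws come from scratch segments only: with an
  # all-scratch set every reference is labelled 1
  all1 <- tiny_segset(n_images = 40, labels = rep(1L, 41), half_window = 5)
  refs1 <- sample_epoch(all1, train_control(n_random = 50, n_scratch = 10,
                                            resize_px = 16, epochs = 1))
  expect_true(all(refs1$label == 1L))
  # scratch upsampling requires scratch segments
  none <- tiny_segset(n_images = 40, labels = integer(41), half_window = 5)
  expect_error(sample_epoch(none, cfg), "no scratch segments")
})

test_that("expected scratch count per epoch follows the binomial expectation", {
  # scratch fraction 0.02: E[scratch per epoch] = 100 + 1500 * 0.02 = 130
  n <- 2000
  labels <- integer(n + 1)
  labels[seq(20, by = 50, length.out = 40) + 1] <- 1L  # isolated 1s, 2%
  ss <- structure(list(
    index = data.frame(video = 1L, t = seq_len(n) - 1L, label = labels[seq_len(n)]),
    scratch_index = which(labels[seq_len(n)] == 1L),
    half_window = 10L, videos = list()), class = "segment_set")
  frac <- mean(ss$index$label)
  expect_equal(frac, 0.02)
  cfg <- train_control(n_random = 1500, n_scratch = 100, epochs = 1)
  set.seed(2)
  counts <- replicate(200, sum(sample_epoch(ss, cfg)$label))
  expect_equal(mean(counts), 100 + 1500 * frac, tolerance = 0.01) # ~130
})

test_that("augmentation applies one shared transform and preserves the label", {
  imgs <- random_motion_images(7, px = 20, seed = 3)
  seg <- structure(list(images = imgs, t = 4, label = 1L), class = "segment")
  cfg <- train_control(n_random = 1, n_scratch = 0, resize_px = 10, epochs = 1)
  set.seed(4)
  aug <- augment_segment(seg, cfg)
  expect_equal(dim(aug$images), c(100, 7))
  expect_identical(aug$label, 1L)
  expect_named(aug$transform, c("hflip", "vflip", "angle"))
  expect_true(all(aug$images >= 0 & aug$images <= 1))

  # identical input images must yield identical warped outputs: the
  # transform is shared across the whole segment
  seg2 <- structure(list(images = rep(imgs[1], 7), t = 4, label = 0L),
                    class = "segment")
  set.seed(5)
  aug2 <- augment_segment(seg2, cfg)
  for (k in 2:7) expect_identical(aug2$images[, k], aug2$images[, 1])

  # disabling augmentation gives pure resize
  cfg0 <- train_control(n_random = 1, n_scratch = 0, resize_px = 10, epochs = 1,
                        augment = list(flip = FALSE, rotate = FALSE))
  aug0 <- augment_segment(seg, cfg0)
  ref <- resize_bilinear(motion_to_matrix(imgs[[1]]), 10)
  expect_equal(matrix(aug0$images[, 1], 10, 10), ref, tolerance = 1e-6)
})

test_that("flips and rotations behave geometrically before resize", {
  img <- motion_to_matrix(random_motion_images(1, px = 15, seed = 6)[[1]])
  expect_identical(flip_image(flip_image(img, TRUE), TRUE), img)   # involution
  expect_identical(flip_image(flip_image(img, FALSE), FALSE), img)
  expect_identical(rotate_nn(img, 0), img)
  expect_identical(rotate_nn(rotate_nn(img, 180), 180), img)
  r90 <- rotate_nn(img, 90)
  expect_identical(rotate_nn(r90, -90), img)
  expect_true(all(rotate_nn(img, 37) %in% 0:1))                    # stays binary
})

test_that("training runs epochs reproducibly and learns separable data", {
  ss <- separable_segset()
  sp <- crnn_spec(input_px = 16, n_frames = 11, conv_filters = c(8, 8),
                  lstm_units = c(16, 16), fc_widths = c(16, 8, 1))
  cfg <- train_control(n_random = 40, n_scratch = 8, epochs = 12,
                       learning_rate = 1e-3, resize_px = 16, minibatch = 16,
                       seed = 7)
  model <- crnn_build(sp, seed = 7)
  fit0 <- crnn_train(model, ss, train_control(n_random = 1, n_scratch = 0,
                                              epochs = 0, resize_px = 16))
  expect_identical(fit0$state$theta, model$state$theta)  # epochs = 0: untouched
  expect_equal(nrow(fit0$history), 0)

  fit1 <- fit_crnn(ss, sp, cfg)
  expect_equal(nrow(fit1$history), 12)
  expect_equal(fit1$history$epoch, 1:12)
  expect_true(all(fit1$history$mean_loss >= 0))
  expect_lt(tail(fit1$history$mean_loss, 1), fit1$history$mean_loss[1])

  fit2 <- fit_crnn(ss, sp, cfg)
  expect_identical(fit1$history, fit2$history)           # same seed, same run
  expect_identical(fit1$state$theta, fit2$state$theta)

  # the fitted object responds to the standard generics
  expect_output(print(fit1), "scratch_crnn")
  expect_s3_class(summary(fit1), "summary.scratch_crnn")
  expect_named(coef(fit1)["conv1_W"], "conv1_W")
  p <- predict(fit1, ss, type = "prob")
  expect_equal(nrow(p), nrow(ss$index))
  cls <- predict(fit1, ss, type = "class")
  expect_true(all(cls$value %in% 0:1))
})

test_that("a model input size mismatch is rejected before training", {
  ss <- separable_segset()
  sp <- crnn_spec(input_px = 32, n_frames = 11, conv_filters = c(4, 4),
                  lstm_units = c(8, 8), fc_widths = c(8, 1))
  expect_error(crnn_train(crnn_build(sp, 1), ss,
                          train_control(n_random = 5, n_scratch = 0, epochs = 1,
                                        resize_px = 16)),
               "resize_px")
})
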