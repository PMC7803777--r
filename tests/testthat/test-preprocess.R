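test_that("frame differencing is an exact absolute difference", {
  a <- matrix(10L, 4, 4)
  b <- matrix(36L, 4, 4)
  d <- frame_difference(a, b)
  expect_true(all(d == 26L))
  expect_identical(frame_difference(a, a), matrix(0L, 4, 4))
  expect_identical(frame_difference(b, a), d) # symmetry of |.|
  expect_error(frame_difference(a, matrix(0L, 4, 5)), "mismatch")
})

test_that("centroid is the mean of above-threshold pixels, with fallback", {
  m <- matrix(0L, 100, 100)
  m[70, 40] <- 255L # (x = 40, y = 70)
  est <- estimate_centroid(m, threshold = 25, min_pixels = 1)
  expect_equal(c(est$x, est$y), c(40, 70))
  expect_true(est$valid)

  m2 <- matrix(0L, 100, 100)
  m2[10, 10] <- 255L; m2[50, 30] <- 255L # (10,10) and (30,50)
  est2 <- estimate_centroid(m2, threshold = 25, min_pixels = 1)
  expect_equal(c(est2$x, est2$y), c(20, 30))

  est3 <- estimate_centroid(matrix(0L, 100, 100), prev = c(100, 100))
  expect_equal(c(est3$x, est3$y), c(100, 100))
  expect_false(est3$valid)
  # no previous centroid: falls back to the image centre
  est4 <- estimate_centroid(matrix(0L, 101, 101))
  expect_equal(c(est4$x, est4$y), c(51, 51))
  expect_false(est4$valid)
})

test_that("crop_binarize zero-pads, binarizes strictly, and is always crop_px^2", {
  big <- matrix(0L, 1080, 1920)
  out <- crop_binarize(big, centre = c(5, 5))
  expect_identical(dim(out), c(300L, 300L))
  expect_true(all(out == as.raw(0)))

  m <- matrix(0L, 40, 40)
  m[20, 20] <- 25L  # exactly the threshold: strictly-greater rule gives 0
  m[20, 21] <- 26L
  out <- crop_binarize(m, centre = c(20, 20), crop_px = 10, threshold = 25)
  expect_equal(sum(out != as.raw(0)), 1L)
  expect_identical(motion_to_matrix(out)[6, 6], 0L)  # the ==25 pixel
  expect_identical(motion_to_matrix(out)[6, 7], 1L)  # the 26 pixel

  # off-centre crops near every border stay crop_px^2 and binary
  set.seed(4)
  src <- matrix(sample(0:255, 64 * 64, TRUE), 64, 64)
  for (centre in list(c(1, 1), c(64, 64), c(1, 64), c(32, 2), c(200, 200))) {
    o <- crop_binarize(src, centre, crop_px = 48)
    expect_identical(dim(o), c(48L, 48L))
    expect_true(all(o %in% as.raw(0:1)))
  }
})

test_that("crop_binarize matches a naive per-pixel loop on random input", {
  set.seed(5)
  for (rep in 1:10) {
    src <- matrix(sample(0:255, 64 * 64, TRUE), 64, 64)
    centre <- c(sample(-10:74, 1), sample(-10:74, 1))
    crop <- 32; thr <- sample(0:255, 1)
    got <- motion_to_matrix(crop_binarize(src, centre, crop, thr))
    want <- matrix(0L, crop, crop)
    cx <- round(centre[1]); cy <- round(centre[2]); half <- crop %/% 2
    for (i in seq_len(crop)) {     # row in crop
      for (j in seq_len(crop)) {   # col in crop
        sr <- cy - half + i - 1; sc <- cx - half + j - 1
        if (sr >= 1 && sr <= 64 && sc >= 1 && sc <= 64 && src[sr, sc] > thr)
          want[i, j] <- 1L
      }
    }
    expect_identical(got, want)
  }
})

test_that("preprocessing a sequence conserves length and tracks translation", {
  frames <- lapply(1:100, function(i) blob_frame(cx = 20 + i / 5, cy = 30))
  m <- preprocess_sequence(frames, crop_px = 64)
  expect_length(m$images, 99)            # N frames -> N-1 motion images
  expect_equal(m$times, 1:99)
  expect_true(all(vapply(m$images, function(im) all(im %in% as.raw(0:1)), TRUE)))
  expect_true(all(vapply(m$images, nrow, 1L) == 64))

  expect_error(preprocess_sequence(frames[1]), "at least 2")

  m2 <- preprocess_sequence(list(frames[[1]], frames[[1]]), crop_px = 64)
  expect_length(m2$images, 1)
  expect_true(all(m2$images[[1]] == as.raw(0))) # identical frames: no motion

  # translation equivariance of the centroid (interior case)
  f1 <- list(blob_frame(128, 40, 40), blob_frame(128, 44, 40))
  f2 <- lapply(f1, function(f) {       # shift both frames by (dx, dy) = (10, 7)
    g <- matrix(0L, 128, 128)
    g[8:128, 11:128] <- f[1:121, 1:118]
    g
  })
  c1 <- preprocess_sequence(f1, crop_px = 32)$centroids
  c2 <- preprocess_sequence(f2, crop_px = 32)$centroids
  expect_equal(c2$x - c1$x, 10, tolerance = 1e-6)
  expect_equal(c2$y - c1$y, 7, tolerance = 1e-6)

  # a translating blob leaves motion at its leading/trailing edges
  mm <- preprocess_sequence(list(blob_frame(cx = 24), blob_frame(cx = 30)), crop_px = 64)
  expect_gt(sum(mm$images[[1]] != as.raw(0)), 0)
})
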