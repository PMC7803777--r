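# Imbalance-aware training: each "epoch" is one sampled input batch of
# n_random segments drawn from all segments plus n_scratch drawn from the
# scratch segments (both with replacement), flip/rotation-augmented,
# resized, and optimised in minibatches with Adam on binary cross-entropy.

#' Training configuration
#'
#' Defaults are the working recipe: per epoch, 1500 segments sampled (with
#' replacement) from all segments and 100 from the scratch segments -- the
#' 1500/100 upsampling ratio that handles the < 2% scratch prevalence --
#' augmented by random flips and rotation, resized to 200 x 200 and
#' optimised with Adam at learning rate 1e-4 under binary cross-entropy
#' for 1000 epochs.  Optimisation proceeds in minibatches within each
#' epoch; gradients are clipped to a global norm bound for stability of
#' the ReLU-activated recurrent cells.
#'
#' @param n_random Segments sampled from all segments per epoch (default 1500).
#' @param n_scratch Additional segments sampled from the scratch segments
#'   per epoch (default 100).
#' @param epochs Number of epochs (default 1000).
#' @param learning_rate Adam learning rate (default 1e-4).
#' @param resize_px Augmented images are resized to this side; must equal
#'   the model's `input_px` (default 200).
#' @param minibatch Minibatch size within an epoch (default 32).
#' @param seed Master seed; fans out to weight-independent sampler,
#'   augmentation and dropout streams (default 1).
#' @param augment List of flags `flip` and `rotate` (both default TRUE).
#' @param clip Global gradient-norm bound; 0 disables (default 0.5).
#' @return Object of class `train_control`.
#' @export
train_control <- function(n_random = 1500, n_scratch = 100, epochs = 1000,
                          learning_rate = 1e-4, resize_px = 200, minibatch = 32,
                          seed = 1L, augment = list(flip = TRUE, rotate = TRUE),
                          clip = 0.5) {
  stopifnot(n_random + n_scratch > 0, learning_rate > 0, minibatch >= 1,
            epochs >= 0, clip >= 0)
  structure(list(n_random = as.integer(n_random), n_scratch = as.integer(n_scratch),
                 epochs = as.integer(epochs), learning_rate = learning_rate,
                 resize_px = as.integer(resize_px), minibatch = as.integer(minibatch),
                 seed = as.integer(seed),
                 augment = list(flip = isTRUE(augment$flip), rotate = isTRUE(augment$rotate)),
                 clip = clip),
            class = "train_control")
}

#' Sample one epoch's upsampled segment references
#'
#' Draws `n_random` segments (with replacement) from all segments of the
#' set plus `n_scratch` (with replacement) from the scratch-labelled
#' segments, and shuffles their order.  Uses the current R random state.
#'
#' @param segset A `segment_set`.
#' @param cfg A `train_control`.
#' @return data.frame of segment references (`video`, `t`, `label`), with
#'   `n_random + n_scratch` rows.
#' @export
sample_epoch <- function(segset, cfg) {
  n <- nrow(segset$index)
  if (n == 0) stop("empty segment set")
  if (cfg$n_scratch > 0 && length(segset$scratch_index) == 0)
    stop("n_scratch > 0 but the segment set has no scratch segments")
  rows <- c(sample.int(n, cfg$n_random, replace = TRUE),
            segset$scratch_index[sample.int(length(segset$scratch_index),
                                            cfg$n_scratch, replace = TRUE)])
  rows <- rows[sample.int(length(rows))]
  cbind(segset$index[rows, , drop = FALSE], row = rows)
}

#' Augment one segment with a shared random transform
#'
#' Draws ONE transform per segment -- horizontal flip with probability 0.5,
#' vertical flip with probability 0.5, rotation angle uniform on
#' [0, 360) degrees -- and applies it identically to all images of the
#' segment (nearest-neighbour rotation on the binary images, exposed
#' corners filled with 0), then resizes to `cfg$resize_px` by bilinear
#' interpolation (interpolated values are kept, preserving thin motion
#' traces).  The label is never changed.  Uses the current R random state.
#'
#' @param seg A `segment` with raw 0/1 image matrices.
#' @param cfg A `train_control` (fields `augment` and `resize_px`).
#' @return A list like a segment but with `images` replaced by a numeric
#'   matrix (`resize_px^2` rows, one column per image, values in `[0, 1]`)
#'   and a `transform` record (`hflip`, `vflip`, `angle`).
#' @export
augment_segment <- function(seg, cfg) {
  hflip <- isTRUE(cfg$augment$flip) && runif(1) < 0.5
  vflip <- isTRUE(cfg$augment$flip) && runif(1) < 0.5
  angle <- if (isTRUE(cfg$augment$rotate)) runif(1) * 360 else 0
  x <- cpp_warp_stack(seg$images, hflip, vflip, angle, cfg$resize_px)
  structure(list(images = x, t = seg$t, label = seg$label,
                 transform = list(hflip = hflip, vflip = vflip, angle = angle)),
            class = "augmented_segment")
}

#' Flip an image matrix
#'
#' @param img Matrix.
#' @param horizontal TRUE mirrors columns (left-right), FALSE mirrors rows.
#' @return Flipped matrix.
#' @export
flip_image <- function(img, horizontal = TRUE) {
  if (horizontal) img[, rev(seq_len(ncol(img))), drop = FALSE]
  else img[rev(seq_len(nrow(img))), , drop = FALSE]
}

#' Rotate an image by nearest-neighbour resampling
#'
#' Counter-clockwise rotation about the image centre; pixels rotated in
#' from outside the image are 0.  Binary images stay binary.
#'
#' @param img Integer/numeric matrix.
#' @param angle Degrees.
#' @return Rotated integer matrix.
#' @export
rotate_nn <- function(img, angle) {
  storage.mode(img) <- "integer"
  cpp_rotate_nn(img, angle)
}

#' Bilinear resize of an image
#'
#' @param img Numeric matrix.
#' @param out_px Output side length.
#' @return `out_px` x `out_px` numeric matrix.
#' @export
resize_bilinear <- function(img, out_px) {
  storage.mode(img) <- "double"
  cpp_resize_bilinear(img, out_px)
}

#' Train the segment classifier
#'
#' Runs `cfg$epochs` epochs.  Each epoch samples its upsampled batch
#' ([sample_epoch()]), augments every segment ([augment_segment()]), and
#' performs minibatched Adam steps on binary cross-entropy.  The run is
#' fully reproducible given `cfg$seed` on a fixed compute backend: the
#' master seed fans out to independent weight-initialisation (see
#' [crnn_build()]), sampling/augmentation and dropout streams.
#'
#' @param model A `scratch_crnn` (its `spec$input_px` must equal
#'   `cfg$resize_px`).
#' @param segset A `segment_set`.
#' @param cfg A `train_control`.
#' @param verbose Print a line every `verbose` epochs; 0 silences.
#' @return The model with updated weights and appended `history`
#'   (data.frame `epoch, mean_loss, scratch_fraction`).
#' @export
crnn_train <- function(model, segset, cfg = train_control(), verbose = 0) {
  stopifnot(inherits(model, "scratch_crnn"), inherits(segset, "segment_set"),
            inherits(cfg, "train_control"))
  if (model$spec$input_px != cfg$resize_px)
    stop(sprintf("model input_px (%d) must equal cfg$resize_px (%d)",
                 model$spec$input_px, cfg$resize_px))
  if (2L * segset$half_window + 1L != model$spec$n_frames)
    stop("segment length does not match model n_frames")
  if (cfg$epochs == 0L) return(model)
  set.seed(cfg$seed)
  dropout_seeds <- sample.int(.Machine$integer.max - 1L,
                              cfg$epochs * ceiling((cfg$n_random + cfg$n_scratch) / cfg$minibatch))
  spec_l <- spec_as_list(model$spec)
  st <- model$state
  hist_epoch <- integer(cfg$epochs); hist_loss <- numeric(cfg$epochs)
  hist_frac <- numeric(cfg$epochs)
  ds_i <- 1L
  nfr <- model$spec$n_frames
  for (ep in seq_len(cfg$epochs)) {
    refs <- sample_epoch(segset, cfg)
    loss_sum <- 0
    i <- 1L
    while (i <= nrow(refs)) {
      j <- min(i + cfg$minibatch - 1L, nrow(refs))
      b <- j - i + 1L
      x <- matrix(0, cfg$resize_px^2, nfr * b)
      y <- numeric(b)
      for (k in seq_len(b)) {
        seg <- get_segment(segset, refs$row[i + k - 1L])
        aug <- augment_segment(seg, cfg)
        x[, (k - 1L) * nfr + seq_len(nfr)] <- aug$images
        y[k] <- seg$label
      }
      st$step <- st$step + 1L
      l <- cpp_train_step(st$theta, st$adam_m, st$adam_v, st$step, spec_l,
                          x, y, cfg$learning_rate, cfg$clip, dropout_seeds[ds_i])
      ds_i <- ds_i + 1L
      if (!is.finite(l))
        stop(sprintf("divergent loss (non-finite) at epoch %d, step %d; try lstm_relu = FALSE or a lower learning rate",
                     ep, st$step))
      loss_sum <- loss_sum + l * b
      i <- j + 1L
    }
    hist_epoch[ep] <- nrow(model$history) + ep
    hist_loss[ep] <- loss_sum / nrow(refs)
    hist_frac[ep] <- mean(refs$label)
    if (verbose > 0 && ep %% verbose == 0)
      message(sprintf("epoch %d/%d mean loss %.4f (scratch fraction %.3f)",
                      ep, cfg$epochs, hist_loss[ep], hist_frac[ep]))
  }
  model$history <- rbind(model$history,
                         data.frame(epoch = hist_epoch, mean_loss = hist_loss,
                                    scratch_fraction = hist_frac))
  model$meta$epochs_trained <- model$meta$epochs_trained + cfg$epochs
  model$meta$train_seed <- cfg$seed
  model
}

#' Build and train a segment classifier in one call
#'
#' Convenience wrapper: [crnn_build()] with `spec` and the weight seed
#' derived from `cfg$seed`, then [crnn_train()].
#'
#' @param segset A `segment_set`.
#' @param spec A `crnn_spec`; its `input_px` must equal `cfg$resize_px`.
#' @param cfg A `train_control`.
#' @param verbose See [crnn_train()].
#' @return A fitted `scratch_crnn`.
#' @export
fit_crnn <- function(segset, spec = crnn_spec(), cfg = train_control(), verbose = 0) {
  set.seed(cfg$seed)
  init_seed <- sample.int(.Machine$integer.max - 1L, 1L)
  model <- crnn_build(spec, seed = init_seed)
  crnn_train(model, segset, cfg, verbose = verbose)
}
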