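# The segment classifier: a convolutional recurrent network.  Each of the
# 21 motion images of a segment passes through a shared convolutional
# encoder (3 x [conv 32@3x3 same, ReLU, maxpool 2x2]); the flattened
# per-frame features form a 21-step sequence integrated by two stacked
# LSTM layers (256 units); the last step's state feeds a dense head
# (128, 128, 32, 8, 1) ending in a sigmoid scratch probability.

#' Network specification for the segment classifier
#'
#' Defaults reproduce the working architecture: three convolution blocks of
#' 32 filters (3x3 kernel, stride 1, size-preserving padding, ReLU) each
#' followed by 2x2 max-pooling; two LSTM layers of 256 units (ReLU cell
#' activation, with `lstm_relu = FALSE` switching to conventional tanh as a
#' numerical-stability escape hatch); dense layers of widths 128, 128, 32,
#' 8 and 1 with ReLU activations and a final sigmoid; dropout 0.2 on the
#' first two dense layers during training; input segments of 21 images at
#' `input_px` x `input_px`.
#'
#' @param input_px Input image side; must be divisible by
#'   `2^length(conv_filters)` (default 200).
#' @param n_frames Images per segment (default 21).
#' @param conv_filters Filters per convolution block.
#' @param kernel Convolution kernel side (odd).
#' @param lstm_units Units per LSTM layer.
#' @param fc_widths Dense-head widths; the last must be 1.
#' @param lstm_relu Use ReLU inside the LSTM cells (default TRUE).
#' @param dropout Dropout rate on the first two dense layers (default 0.2).
#' @return Validated object of class `crnn_spec`.
#' @export
crnn_spec <- function(input_px = 200, n_frames = 21,
                      conv_filters = c(32, 32, 32), kernel = 3,
                      lstm_units = c(256, 256),
                      fc_widths = c(128, 128, 32, 8, 1),
                      lstm_relu = TRUE, dropout = 0.2) {
  fail <- function(field, why) stop(sprintf("invalid spec field '%s': %s", field, why))
  if (length(fc_widths) < 1 || fc_widths[length(fc_widths)] != 1)
    fail("fc_widths", "last width must be 1")
  if (any(fc_widths < 1)) fail("fc_widths", "widths must be positive")
  if (kernel %% 2 != 1 || kernel < 1) fail("kernel", "must be a positive odd number")
  if (length(conv_filters) < 1 || any(conv_filters < 1))
    fail("conv_filters", "need at least one block of >= 1 filters")
  if (length(lstm_units) < 1 || any(lstm_units < 1))
    fail("lstm_units", "need at least one layer of >= 1 units")
  if (input_px %% 2^length(conv_filters) != 0)
    fail("input_px", sprintf("must be divisible by 2^%d", length(conv_filters)))
  if (n_frames < 1) fail("n_frames", "must be >= 1")
  if (dropout < 0 || dropout >= 1) fail("dropout", "must be in [0, 1)")
  structure(list(input_px = as.integer(input_px), n_frames = as.integer(n_frames),
                 kernel = as.integer(kernel),
                 conv_filters = as.integer(conv_filters),
                 lstm_units = as.integer(lstm_units),
                 fc_widths = as.integer(fc_widths),
                 lstm_relu = isTRUE(lstm_relu), dropout = dropout),
            class = "crnn_spec")
}

#' Per-layer output shapes of a network specification
#'
#' Walks the shape cascade from the input tensor to the scalar output: with
#' size-preserving convolutions, each pooling halves the spatial side
#' (e.g. 200 -> 100 -> 50 -> 25), the final feature map is flattened per
#' frame, the LSTM stack reduces the sequence to its last state, and the
#' dense head converges to one unit.
#'
#' @param spec A `crnn_spec`.
#' @return data.frame with `layer` and `shape` (printable) plus a
#'   `dims` list column.
#' @export
shape_plan <- function(spec) {
  stopifnot(inherits(spec, "crnn_spec"))
  side <- spec$input_px
  rows <- list(list(layer = "input", dims = c(spec$n_frames, side, side, 1)))
  for (i in seq_along(spec$conv_filters)) {
    f <- spec$conv_filters[i]
    rows[[length(rows) + 1]] <- list(layer = sprintf("conv%d", i), dims = c(side, side, f))
    side <- side %/% 2L
    rows[[length(rows) + 1]] <- list(layer = sprintf("pool%d", i), dims = c(side, side, f))
  }
  d <- side * side * spec$conv_filters[length(spec$conv_filters)]
  rows[[length(rows) + 1]] <- list(layer = "flatten", dims = c(spec$n_frames, d))
  for (i in seq_along(spec$lstm_units)) {
    u <- spec$lstm_units[i]
    dims <- if (i < length(spec$lstm_units)) c(spec$n_frames, u) else u
    rows[[length(rows) + 1]] <- list(layer = sprintf("lstm%d", i), dims = dims)
  }
  for (i in seq_along(spec$fc_widths)) {
    rows[[length(rows) + 1]] <- list(layer = sprintf("fc%d", i), dims = spec$fc_widths[i])
  }
  data.frame(layer = vapply(rows, `[[`, "", "layer"),
             shape = vapply(rows, function(r) paste(r$dims, collapse = "x"), ""),
             dims = I(lapply(rows, `[[`, "dims")))
}

spec_as_list <- function(spec) {
  list(input_px = spec$input_px, n_frames = spec$n_frames, kernel = spec$kernel,
       conv_filters = spec$conv_filters, lstm_units = spec$lstm_units,
       fc_widths = spec$fc_widths, lstm_relu = spec$lstm_relu, dropout = spec$dropout)
}

crnn_layout <- function(spec) cpp_layout(spec_as_list(spec))

#' Number of learnable parameters of a specification
#'
#' @param spec A `crnn_spec`.
#' @return Total parameter count (weights + biases).
#' @export
n_params <- function(spec) {
  lay <- crnn_layout(spec)
  as.numeric(lay$offset[nrow(lay)] + lay$nrow[nrow(lay)] * lay$ncol[nrow(lay)])
}

#' @export
print.crnn_spec <- function(x, ...) {
  cat(sprintf("<crnn_spec> input %dx%dx%d | conv %s (k=%d) | lstm %s (%s) | fc %s | dropout %.2f\n",
              x$n_frames, x$input_px, x$input_px,
              paste(x$conv_filters, collapse = "-"), x$kernel,
              paste(x$lstm_units, collapse = "-"),
              if (x$lstm_relu) "relu" else "tanh",
              paste(x$fc_widths, collapse = "-"), x$dropout))
  cat(sprintf("  %s parameters\n", format(n_params(x), big.mark = ",")))
  invisible(x)
}

# Weight initialisation: He-normal for convolution and ReLU dense layers,
# Glorot for the output layer; LSTM input weights Glorot-uniform, recurrent
# weights orthogonal per gate, forget-gate bias 1.
init_theta <- function(spec) {
  lay <- crnn_layout(spec)
  theta <- numeric(n_params(spec))
  nfc <- length(spec$fc_widths)
  for (i in seq_len(nrow(lay))) {
    nm <- lay$name[i]; nr <- lay$nrow[i]; nc <- lay$ncol[i]
    off <- lay$offset[i]
    vals <- numeric(nr * nc)
    if (grepl("^conv\\d+_W$", nm)) {
      vals <- rnorm(nr * nc, sd = sqrt(2 / nc))
    } else if (grepl("^lstm\\d+_W$", nm)) {
      u <- nr / 4L
      din <- nc - u
      W <- matrix(0, nr, nc)
      lim <- sqrt(6 / (din + u))
      W[, seq_len(din)] <- runif(nr * din, -lim, lim)
      for (g in 1:4) {
        Q <- qr.Q(qr(matrix(rnorm(u * u), u, u)))
        W[((g - 1) * u + 1):(g * u), din + seq_len(u)] <- Q
      }
      vals <- as.vector(W)
    } else if (grepl("^lstm\\d+_b$", nm)) {
      u <- nr / 4L
      b <- numeric(nr)
      b[(u + 1):(2 * u)] <- 1 # forget gate
      vals <- b
    } else if (grepl("^fc\\d+_W$", nm)) {
      last <- grepl(sprintf("^fc%d_W$", nfc), nm)
      vals <- if (last) runif(nr * nc, -sqrt(6 / (nr + nc)), sqrt(6 / (nr + nc)))
              else rnorm(nr * nc, sd = sqrt(2 / nc))
    } # biases default to 0
    theta[off + seq_len(nr * nc)] <- vals
  }
  theta
}

#' Build an (untrained) segment classifier
#'
#' Initialises all weights from `seed` (the same seed always yields
#' bit-identical weights) and returns a model object that
#' [crnn_train()] can fit and [predict.scratch_crnn()] can apply.
#'
#' @param spec A `crnn_spec` (default: the standard architecture).
#' @param seed Integer seed for weight initialisation.
#' @return Object of class `scratch_crnn`.
#' @export
crnn_build <- function(spec = crnn_spec(), seed = 1L) {
  stopifnot(inherits(spec, "crnn_spec"))
  set.seed(seed)
  state <- new.env(parent = emptyenv())
  state$theta <- init_theta(spec)
  state$adam_m <- numeric(length(state$theta))
  state$adam_v <- numeric(length(state$theta))
  state$step <- 0L
  structure(list(spec = spec, state = state,
                 meta = list(init_seed = seed,
                             init_scheme = "he-normal conv/dense, glorot+orthogonal lstm, forget-bias 1",
                             epochs_trained = 0L, train_seed = NA_integer_),
                 history = data.frame(epoch = integer(), mean_loss = numeric(),
                                      scratch_fraction = numeric())),
            class = "scratch_crnn")
}

#' Raw forward pass on a prepared image batch
#'
#' Low-level inference: takes images already warped/resized to the
#' specification's input size, flattened one image per column
#' (`input_px^2` rows, `n_frames * B` columns, segment-major order), and
#' returns one probability per segment.  Dropout is disabled; the output is
#' deterministic given weights and input.
#'
#' @param model A `scratch_crnn`.
#' @param x Numeric matrix as described, pixel values in `[0, 1]`.
#' @return Numeric vector of probabilities in `(0, 1)`.
#' @export
crnn_forward <- function(model, x) {
  stopifnot(inherits(model, "scratch_crnn"))
  cpp_forward(model$state$theta, spec_as_list(model$spec), x)
}

#' Per-frame encoder features
#'
#' Applies only the shared convolutional encoder to each image column and
#' returns the flattened feature vectors; used to verify weight sharing
#' across time.
#'
#' @param model A `scratch_crnn`.
#' @param x Image batch as in [crnn_forward()] (any number of columns).
#' @return Matrix of per-image features (rows = flattened features).
#' @export
crnn_encode <- function(model, x) {
  cpp_encoder(model$state$theta, spec_as_list(model$spec), x)
}

#' Assemble the forward-ready batch matrix for a set of segments
#'
#' Resizes each segment's motion images to the model input size (bilinear;
#' interpolated values are kept, no re-binarization) and stacks them
#' column-wise in segment-major order.
#'
#' @param segments List of `segment` objects (raw 0/1 image matrices).
#' @param input_px Target side length.
#' @return Numeric matrix `input_px^2` x `n_frames * length(segments)`.
#' @export
segments_to_batch <- function(segments, input_px) {
  n_frames <- length(segments[[1]]$images)
  out <- matrix(0, input_px^2, n_frames * length(segments))
  for (s in seq_along(segments)) {
    out[, (s - 1L) * n_frames + seq_len(n_frames)] <-
      cpp_warp_stack(segments[[s]]$images, FALSE, FALSE, 0, input_px)
  }
  out
}

#' Predict scratch probabilities, classes or events
#'
#' Runs the classifier over segments without augmentation.  `newdata` may
#' be a `segment_set` (all segments are scored, per video), a list of
#' `segment` objects, or a prepared batch matrix.
#'
#' @param object A fitted `scratch_crnn`.
#' @param newdata Segments to score (see Details).
#' @param type `"prob"` for probability tracks, `"class"` for thresholded
#'   0/1 tracks, `"events"` for extracted scratch events.
#' @param cutoff Classification threshold; a segment is called scratching
#'   when its probability is strictly greater (default 0.5).
#' @param fps Frames per second for event durations (default 60).
#' @param batch_size Segments per forward batch (default 64).
#' @param ... Unused.
#' @return For a `segment_set`: a data.frame with `video`, `t` and the
#'   requested value(s); for other inputs a vector (or events data.frame).
#' @export
predict.scratch_crnn <- function(object, newdata, type = c("prob", "class", "events"),
                                 cutoff = 0.5, fps = 60, batch_size = 64, ...) {
  type <- match.arg(type)
  px <- object$spec$input_px
  nfr <- object$spec$n_frames
  score_segments <- function(segs) {
    p <- numeric(length(segs))
    i <- 1L
    while (i <= length(segs)) {
      j <- min(i + batch_size - 1L, length(segs))
      p[i:j] <- crnn_forward(object, segments_to_batch(segs[i:j], px))
      i <- j + 1L
    }
    p
  }
  if (inherits(newdata, "segment_set")) {
    if (2L * newdata$half_window + 1L != nfr)
      stop("segment length does not match model n_frames")
    segs <- lapply(seq_len(nrow(newdata$index)), function(i) get_segment(newdata, i))
    out <- data.frame(video = newdata$index$video, t = newdata$index$t,
                      prob = score_segments(segs))
    if (type == "prob") return(out)
    out$value <- as.integer(out$prob > cutoff)
    if (type == "class") return(out[, c("video", "t", "value")])
    ev <- lapply(split(out, out$video), function(d)
      extract_events(data.frame(time = d$t, value = d$value), fps = fps))
    return(do.call(rbind, Map(cbind, video = as.integer(names(ev)), ev)))
  }
  if (is.matrix(newdata)) {
    p <- crnn_forward(object, newdata)
  } else {
    if (inherits(newdata, "segment")) newdata <- list(newdata)
    p <- score_segments(newdata)
  }
  switch(type,
         prob = p,
         class = as.integer(p > cutoff),
         events = extract_events(data.frame(time = seq_along(p) - 1L,
                                            value = as.integer(p > cutoff)), fps = fps))
}

#' @export
print.scratch_crnn <- function(x, ...) {
  cat("<scratch_crnn> segment classifier\n")
  print(x$spec)
  cat(sprintf("  trained %d epoch(s)%s\n", x$meta$epochs_trained,
              if (x$meta$epochs_trained > 0)
                sprintf(", final mean loss %.4f", tail(x$history$mean_loss, 1)) else ""))
  invisible(x)
}

#' @export
summary.scratch_crnn <- function(object, ...) {
  s <- list(spec = object$spec, n_params = n_params(object$spec),
            epochs = object$meta$epochs_trained, history = object$history,
            meta = object$meta)
  class(s) <- "summary.scratch_crnn"
  s
}

#' @export
print.summary.scratch_crnn <- function(x, ...) {
  print(x$spec)
  cat(sprintf("epochs trained: %d (init seed %s, train seed %s)\n", x$epochs,
              x$meta$init_seed, x$meta$train_seed))
  if (nrow(x$history)) {
    cat(sprintf("loss: first %.4f, last %.4f, min %.4f\n",
                x$history$mean_loss[1], tail(x$history$mean_loss, 1),
                min(x$history$mean_loss)))
  }
  invisible(x)
}

#' Extract model weights as named matrices
#'
#' @param object A `scratch_crnn`.
#' @param ... Unused.
#' @return Named list of weight matrices / bias vectors.
#' @export
coef.scratch_crnn <- function(object, ...) {
  lay <- crnn_layout(object$spec)
  out <- list()
  for (i in seq_len(nrow(lay))) {
    v <- object$state$theta[lay$offset[i] + seq_len(lay$nrow[i] * lay$ncol[i])]
    out[[lay$name[i]]] <- matrix(v, lay$nrow[i], lay$ncol[i])
  }
  out
}

#' Plot the training loss history
#'
#' @param x A fitted `scratch_crnn`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.scratch_crnn <- function(x, ...) {
  if (!nrow(x$history)) stop("model has no training history")
  graphics::plot(x$history$epoch, x$history$mean_loss, type = "l",
                 xlab = "epoch", ylab = "mean binary cross-entropy", ...)
  invisible(x)
}
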