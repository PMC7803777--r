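# Fixtures are built in code; nothing is read from disk.

# A frame with a bright disc blob on a dark background.
blob_frame <- function(n = 64, cx = 32, cy = 32, r = 8, intensity = 200, bg = 0) {
  m <- matrix(bg, n, n)
  for (c in max(1, floor(cx - r)):min(n, ceiling(cx + r))) {
    for (rr in max(1, floor(cy - r)):min(n, ceiling(cy + r))) {
      if ((c - cx)^2 + (rr - cy)^2 <= r^2) m[rr, c] <- intensity
    }
  }
  storage.mode(m) <- "integer"
  m
}

# n random binary motion images of side px (raw matrices).
random_motion_images <- function(n, px = 8, p_on = 0.2, seed = 1) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    matrix(as.raw(runif(px * px) < p_on), px, px)
  })
}

# A small labelled segment set: one video of `n_images` random motion
# images with the given 0/1 frame-label vector (length n_images + 1).
tiny_segset <- function(n_images = 99, labels = NULL, px = 8, half_window = 10,
                        seed = 1) {
  if (is.null(labels)) labels <- integer(n_images + 1)
  build_dataset(list(list(images = random_motion_images(n_images, px, seed = seed),
                          labels = labels, id = "tiny")),
                half_window = half_window)
}

# A small, strongly separable segment set: scratch segments flicker
# (dense motion on alternating frames), others are sparse and static.
separable_segset <- function(n_images = 160, px = 16, half_window = 5, seed = 2) {
  set.seed(seed)
  labels <- integer(n_images + 1)
  labels[41:80] <- 1L  # one scratch bout (frames 40..79, 0-based)
  labels[121:150] <- 1L
  images <- lapply(seq_len(n_images), function(t) {
    scratch <- labels[t + 1L] == 1L
    p <- if (scratch && t %% 2 == 0) 0.5 else if (scratch) 0.05 else 0.02
    matrix(as.raw(runif(px * px) < p), px, px)
  })
  build_dataset(list(list(images = images, labels = labels, id = "sep")),
                half_window = half_window)
}

# Random binary track pair for fuzz tests (bursty so events exist).
random_track_pair <- function(len, seed) {
  set.seed(seed)
  mk <- function() {
    v <- integer(len)
    t <- 1L
    while (t <= len) {
      run <- sample(1:8, 1)
      val <- sample(0:1, 1, prob = c(0.7, 0.3))
      v[t:min(len, t + run - 1L)] <- val
      t <- t + run
    }
    v
  }
  list(pred = mk(), obs = mk())
}

# Brute-force oracles -------------------------------------------------------

# maximal runs of 1s by linear scan
brute_events <- function(values, times = seq_along(values) - 1L, fps = 60) {
  out <- data.frame(start_t = integer(), end_t = integer(),
                    n_segments = integer(), duration_s = numeric())
  i <- 1L
  n <- length(values)
  while (i <= n) {
    if (values[i] == 1L) {
      j <- i
      while (j < n && values[j + 1L] == 1L && times[j + 1L] == times[j] + 1L) j <- j + 1L
      out <- rbind(out, data.frame(start_t = times[i], end_t = times[j],
                                   n_segments = j - i + 1L,
                                   duration_s = (j - i + 1L) / fps))
      i <- j + 1L
    } else i <- i + 1L
  }
  out
}

# label every error segment by scanning all event overlaps
brute_error_taxonomy <- function(pred, obs) {
  times <- seq_along(pred) - 1L
  pe <- brute_events(pred)
  oe <- brute_events(obs)
  boundary <- 0L; false_detection <- 0L; oversight <- 0L
  event_of <- function(ev, t) which(ev$start_t <= t & ev$end_t >= t)
  overlap <- function(a, b) a$start_t <= b$end_t && a$end_t >= b$start_t
  for (i in seq_along(times)) {
    t <- times[i]
    if (pred[i] == 1L && obs[i] == 0L) {       # false positive segment
      e <- pe[event_of(pe, t), ]
      hit <- any(vapply(seq_len(nrow(oe)), function(j) overlap(e, oe[j, ]), TRUE))
      if (isTRUE(hit)) boundary <- boundary + 1L else false_detection <- false_detection + 1L
    } else if (pred[i] == 0L && obs[i] == 1L) { # false negative segment
      e <- oe[event_of(oe, t), ]
      hit <- any(vapply(seq_len(nrow(pe)), function(j) overlap(e, pe[j, ]), TRUE))
      if (isTRUE(hit)) boundary <- boundary + 1L else oversight <- oversight + 1L
    }
  }
  list(boundary = boundary, false_detection = false_detection, oversight = oversight)
}

# tiny network spec for fast model tests
tiny_spec <- function(px = 16, n_frames = 5) {
  crnn_spec(input_px = px, n_frames = n_frames, conv_filters = c(4, 4),
            lstm_units = c(8, 8), fc_widths = c(8, 4, 1))
}

# random prepared batch for the tiny spec
tiny_batch <- function(spec, B, seed = 3) {
  set.seed(seed)
  matrix((runif(spec$input_px^2 * spec$n_frames * B) > 0.8) * 1,
         spec$input_px^2, spec$n_frames * B)
}
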