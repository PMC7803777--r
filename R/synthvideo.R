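# Synthetic labelled arena videos: a bright mouse-like ellipse on a dark
# arena, with interleaved episodes of rest, locomotion, grooming (slow
# periodic appendage motion near the head) and scratching (fast periodic
# hindlimb motion at the rear flank), plus ground-truth frame labels.
# Only the motion-energy signature matters to the detector, so appendages
# are rendered as small oscillating ellipses, not articulated limbs.

BEHAVIOURS <- c("rest", "locomote", "groom", "scratch")

#' Configuration of the synthetic video generator
#'
#' Defaults emulate a 60 Hz top-down recording of a white mouse in a dark
#' arena at desk scale (480 x 480 rather than full HD; preprocessing is
#' size-agnostic).  Behaviour episodes follow a semi-Markov chain with
#' exponential dwell times; scratching is a fast (12 Hz) oscillation of a
#' small rear appendage, grooming a slow (3 Hz) oscillation near the
#' front.  The oscillation waveform has an asymmetric velocity profile
#' (fast stroke, slow return), so the per-frame motion-energy spectrum
#' peaks at the nominal frequency.
#'
#' @param frame_px Frame side length in pixels (square frames, default 480).
#' @param fps Frames per second (default 60).
#' @param n_frames Frames per video (default 1800, i.e. 30 s).
#' @param body_axes Body ellipse semi-axes in px (default c(48, 30)).
#' @param intensity Body/appendage intensity 0-255 (default 190).
#' @param bg Background intensity (default 10).
#' @param noise_sd Additive Gaussian pixel noise SD (default 4; low enough
#'   that binarization at the working threshold suppresses it).
#' @param dwell Named mean dwell times in seconds for rest, locomote,
#'   groom, scratch.
#' @param transition 4x4 matrix of transition weights (rows = from,
#'   cols = to, zero diagonal).  The default routes ~10% of transitions
#'   into scratch, giving a stationary scratch-frame share of about 2-3%.
#' @param scratch_hz,scratch_amp Scratch oscillation frequency (Hz,
#'   default 12; must be below fps/2) and amplitude (px, default 14).
#' @param groom_hz,groom_amp Grooming oscillation frequency (default 3 Hz)
#'   and amplitude (default 8 px).
#' @param invert Render a dark mouse on a light arena (emulates dark-coat
#'   animals; qualitative exploration only).
#' @param ensure_scratch Resample a video's behaviour script until it
#'   contains at least one scratch bout (only when scratch is reachable).
#' @return Object of class `synth_config`.
#' @export
synth_config <- function(frame_px = 480, fps = 60, n_frames = 1800,
                         body_axes = c(48, 30), intensity = 190, bg = 10,
                         noise_sd = 4,
                         dwell = c(rest = 3, locomote = 3, groom = 3, scratch = 0.5),
                         transition = NULL,
                         scratch_hz = 12, scratch_amp = 14,
                         groom_hz = 3, groom_amp = 8,
                         invert = FALSE, ensure_scratch = TRUE) {
  if (is.null(transition)) {
    transition <- matrix(0, 4, 4, dimnames = list(BEHAVIOURS, BEHAVIOURS))
    for (b in c("rest", "locomote", "groom")) {
      transition[b, setdiff(BEHAVIOURS, c(b, "scratch"))] <- 0.435
      transition[b, "scratch"] <- 0.13
    }
    transition["scratch", c("rest", "locomote", "groom")] <- 1 / 3
  }
  stopifnot(scratch_hz > 0, scratch_hz < fps / 2, groom_hz > 0, groom_hz < fps / 2,
            all(dwell > 0), all(BEHAVIOURS %in% names(dwell)),
            identical(dim(transition), c(4L, 4L)), all(diag(transition) == 0),
            n_frames >= 1, frame_px >= 64)
  structure(list(frame_px = as.integer(frame_px), fps = fps,
                 n_frames = as.integer(n_frames),
                 body_axes = body_axes, intensity = intensity, bg = bg,
                 noise_sd = noise_sd, dwell = dwell[BEHAVIOURS],
                 transition = transition,
                 scratch_hz = scratch_hz, scratch_amp = scratch_amp,
                 groom_hz = groom_hz, groom_amp = groom_amp,
                 invert = isTRUE(invert), ensure_scratch = isTRUE(ensure_scratch)),
            class = "synth_config")
}

#' Sample a behaviour script
#'
#' Semi-Markov sampling: each episode's behaviour is drawn from the
#' transition weights of the previous behaviour (self-transitions
#' excluded), with an exponentially distributed dwell time (mean from
#' `cfg$dwell`, truncated to at least 5 frames).  The initial behaviour is
#' drawn proportionally to the total weight into each behaviour.
#' Intervals tile `[0, n_frames)` exactly.  Uses the current R random
#' state.
#'
#' @param cfg A `synth_config`.
#' @return data.frame of class `behaviour_script` with `behaviour`,
#'   `start_frame`, `end_frame` (inclusive, 0-based).
#' @export
script_behaviours <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  draw <- function() {
    beh <- character(); start <- integer(); end <- integer()
    into <- colSums(cfg$transition)
    cur <- sample(BEHAVIOURS, 1, prob = into)
    frame <- 0L
    while (frame < cfg$n_frames) {
      mean_frames <- cfg$dwell[[cur]] * cfg$fps
      n <- max(5L, as.integer(round(rexp(1, 1 / mean_frames))))
      n <- min(n, cfg$n_frames - frame)
      beh <- c(beh, cur); start <- c(start, frame); end <- c(end, frame + n - 1L)
      frame <- frame + n
      w <- cfg$transition[cur, ]
      if (sum(w) == 0) next # absorbing behaviour; extend at next loop
      cur <- sample(BEHAVIOURS, 1, prob = w)
    }
    # merge adjacent identical behaviours (possible with absorbing states)
    keep <- c(TRUE, beh[-1] != beh[-length(beh)])
    grp <- cumsum(keep)
    data.frame(behaviour = beh[keep],
               start_frame = start[keep],
               end_frame = as.integer(tapply(end, grp, max)))
  }
  scratch_reachable <- cfg$ensure_scratch && sum(cfg$transition[, "scratch"]) > 0
  for (try in 1:200) {
    s <- draw()
    if (!scratch_reachable || any(s$behaviour == "scratch")) break
  }
  class(s) <- c("behaviour_script", "data.frame")
  s
}

script_frame_labels <- function(script, n_frames, behaviour) {
  lab <- integer(n_frames)
  rows <- script[script$behaviour == behaviour, , drop = FALSE]
  for (i in seq_len(nrow(rows))) {
    lab[(rows$start_frame[i]:rows$end_frame[i]) + 1L] <- 1L
  }
  lab
}

# velocity-asymmetric oscillation: fast stroke, slow return; the motion
# energy |d pos/dt| then peaks at f rather than 2f
osc_disp <- function(theta) sin(theta + sin(theta))

draw_ellipse <- function(frame, cx, cy, a, b, phi, intensity) {
  n <- nrow(frame)
  rad <- max(a, b) + 1
  rows <- max(1L, floor(cy - rad)):min(n, ceiling(cy + rad))
  cols <- max(1L, floor(cx - rad)):min(n, ceiling(cx + rad))
  if (!length(rows) || !length(cols)) return(frame)
  X <- outer(rep(1, length(rows)), cols) - cx
  Y <- outer(rows, rep(1, length(cols))) - cy
  u <- X * cos(phi) + Y * sin(phi)
  v <- -X * sin(phi) + Y * cos(phi)
  mask <- (u / a)^2 + (v / b)^2 <= 1
  sub <- frame[rows, cols]
  sub[mask] <- pmax(sub[mask], intensity)
  frame[rows, cols] <- sub
  frame
}

# Sequential frame stepper; returns a function() yielding the next frame.
make_stepper <- function(script, cfg) {
  n <- cfg$frame_px
  beh <- character(cfg$n_frames)
  istart <- integer(cfg$n_frames)
  for (i in seq_len(nrow(script))) {
    span <- (script$start_frame[i]:script$end_frame[i]) + 1L
    beh[span] <- script$behaviour[i]
    istart[span] <- script$start_frame[i]
  }
  margin <- max(cfg$body_axes) + cfg$scratch_amp + 20
  pos <- c(runif(1, margin, n - margin), runif(1, margin, n - margin))
  vel <- c(0, 0)
  phi <- runif(1, 0, 2 * pi)
  i <- 0L
  function() {
    i <<- i + 1L
    b <- beh[i]
    if (b == "locomote") {
      vel <<- 0.85 * vel + rnorm(2, sd = 1.2)
      spd <- sqrt(sum(vel^2))
      if (spd > 5) vel <<- vel * 5 / spd
      pos <<- pos + vel
      for (d in 1:2) { # reflect at arena walls
        if (pos[d] < margin) { pos[d] <<- 2 * margin - pos[d]; vel[d] <<- -vel[d] }
        if (pos[d] > n - margin) { pos[d] <<- 2 * (n - margin) - pos[d]; vel[d] <<- -vel[d] }
      }
      if (spd > 0.5) {
        head <- atan2(vel[2], vel[1])
        dphi <- atan2(sin(head - phi), cos(head - phi))
        phi <<- phi + 0.2 * dphi
      }
    } else {
      vel <<- c(0, 0)
    }
    base <- matrix(cfg$bg, n, n)
    base <- draw_ellipse(base, pos[1], pos[2], cfg$body_axes[1], cfg$body_axes[2],
                         phi, cfg$intensity)
    if (b %in% c("groom", "scratch")) {
      fast <- b == "scratch"
      f <- if (fast) cfg$scratch_hz else cfg$groom_hz
      amp <- if (fast) cfg$scratch_amp else cfg$groom_amp
      theta <- 2 * pi * f * (i - 1L - istart[i]) / cfg$fps
      disp <- amp * osc_disp(theta)
      ax <- c(cos(phi), sin(phi)); ay <- c(-sin(phi), cos(phi))
      if (fast) { # hindlimb at the rear flank, stroking across the body axis
        centre <- pos - 0.6 * cfg$body_axes[1] * ax + 0.7 * cfg$body_axes[2] * ay +
          disp * ay
        app <- c(12, 8)
      } else {    # forepaws near the head, moving along the body
        centre <- pos + 0.8 * cfg$body_axes[1] * ax + disp * ax
        app <- c(14, 9)
      }
      base <- draw_ellipse(base, centre[1], centre[2], app[1], app[2], phi,
                           cfg$intensity)
    }
    if (cfg$noise_sd > 0) base <- base + rnorm(n * n, sd = cfg$noise_sd)
    frame <- round(pmin(pmax(base, 0), 255))
    if (cfg$invert) frame <- 255 - frame
    storage.mode(frame) <- "integer"
    frame
  }
}

#' Render a behaviour script into frames and label tracks
#'
#' Renders each frame of the script: a bright body ellipse (stationary at
#' rest, smooth random-walk translation during locomotion) with a small
#' oscillating appendage ellipse during grooming (slow, near the head) and
#' scratching (fast, at the rear flank), plus additive pixel noise.  The
#' animal reflects off the arena walls.  Frame labels are 1 exactly on the
#' scratch intervals of the script; the grooming track is analogous.
#' Uses the current R random state.
#'
#' All frames are returned in memory; for long videos prefer
#' [synth_motion_dataset()], which streams frames through preprocessing.
#'
#' @param script A `behaviour_script`.
#' @param cfg A `synth_config`.
#' @return List with `frames` (list of integer matrices), `labels` and
#'   `grooming` (0/1 vectors, element 1 = frame 0).
#' @export
render_frames <- function(script, cfg) {
  step <- make_stepper(script, cfg)
  frames <- vector("list", cfg$n_frames)
  for (i in seq_len(cfg$n_frames)) frames[[i]] <- step()
  list(frames = frames,
       labels = script_frame_labels(script, cfg$n_frames, "scratch"),
       grooming = script_frame_labels(script, cfg$n_frames, "groom"))
}

derive_video_seeds <- function(seed, n_videos) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n_videos)
}

#' Generate a labelled synthetic dataset of videos
#'
#' Each video gets an independent seeded stream derived from `seed`, its
#' own behaviour script, rendered frames and ground-truth label tracks.
#' The manifest records the scripts, enabling exact label recovery.  The
#' same seed always reproduces byte-identical frames.
#'
#' @param cfg A `synth_config`.
#' @param n_videos Number of videos (>= 1).
#' @param seed Master seed.
#' @return List with `videos` (each: `frames`, `labels`, `grooming`,
#'   `script`, `id`) and `manifest` (seeds, config, scripts).
#' @export
generate_dataset <- function(cfg, n_videos, seed = 1L) {
  stopifnot(n_videos >= 1)
  vseeds <- derive_video_seeds(seed, n_videos)
  videos <- vector("list", n_videos)
  for (v in seq_len(n_videos)) {
    set.seed(vseeds[v])
    script <- script_behaviours(cfg)
    r <- render_frames(script, cfg)
    videos[[v]] <- list(frames = r$frames, labels = r$labels, grooming = r$grooming,
                        script = script, id = sprintf("synth%02d", v))
  }
  list(videos = videos,
       manifest = list(seed = seed, video_seeds = vseeds, n_videos = n_videos,
                       config = unclass(cfg)[setdiff(names(cfg), "transition")],
                       scripts = lapply(videos, `[[`, "script")))
}

#' Generate synthetic videos and stream them through preprocessing
#'
#' Memory-friendly composite for long videos: frames are rendered one at a
#' time and fed directly into [preprocess_sequence()], so only the motion
#' images are kept.  Output plugs straight into [build_dataset()].
#'
#' @param cfg A `synth_config`.
#' @param n_videos Number of videos.
#' @param seed Master seed.
#' @param threshold,crop_px,smooth,min_pixels Passed to
#'   [preprocess_sequence()].
#' @return List of videos, each with `images` (a `motion_images`),
#'   `labels`, `grooming`, `script`, `id`.
#' @export
synth_motion_dataset <- function(cfg, n_videos, seed = 1L, threshold = 25,
                                 crop_px = 300, smooth = 0.5, min_pixels = 20) {
  vseeds <- derive_video_seeds(seed, n_videos)
  videos <- vector("list", n_videos)
  for (v in seq_len(n_videos)) {
    set.seed(vseeds[v])
    script <- script_behaviours(cfg)
    step <- make_stepper(script, cfg)
    last <- new.env(parent = emptyenv()); last$i <- 0L
    acc <- function(i) { # sequential accessor
      stopifnot(i == last$i + 1L)
      last$i <- i
      step()
    }
    attr(acc, "n") <- cfg$n_frames
    mi <- preprocess_sequence(acc, threshold = threshold, crop_px = crop_px,
                              smooth = smooth, min_pixels = min_pixels)
    videos[[v]] <- list(images = mi,
                        labels = script_frame_labels(script, cfg$n_frames, "scratch"),
                        grooming = script_frame_labels(script, cfg$n_frames, "groom"),
                        script = script, id = sprintf("synth%02d", v))
  }
  videos
}

#' Dominant frequency of a periodic signal
#'
#' Discrete-Fourier peak (excluding the zero-frequency term) of a
#' detrended series; used to check the oscillation signature of rendered
#' behaviours.
#'
#' @param x Numeric series.
#' @param fps Sampling rate (Hz).
#' @return Frequency in Hz of the largest spectral magnitude.
#' @export
dominant_frequency <- function(x, fps) {
  x <- x - mean(x)
  n <- length(x)
  sp <- Mod(stats::fft(x))[2:(n %/% 2 + 1)]
  which.max(sp) * fps / n
}
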