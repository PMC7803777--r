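# Segment datasets: sliding 21-frame windows of motion images, labelled by
# the frame label at the window centre.

#' Build one segment of consecutive motion images
#'
#' A segment at centre time `t` is the ordered set of `2 * half_window + 1`
#' motion images from `t - half_window` to `t + half_window` -- the unit
#' the classifier sees.  Centre times whose window would leave the
#' available range are rejected (no padding).
#'
#' @param images A `motion_images` object, or a plain list of motion-image
#'   matrices (then taken to be at times `1 ... length(images)`).
#' @param t Centre time (same indexing as `images$times`).
#' @param half_window Window half width (default 10, i.e. 21 images).
#' @param label Optional 0/1 label to attach.
#' @return An object of class `segment`: list with `images` (list of
#'   matrices), `t`, `label`.
#' @export
build_segment <- function(images, t, half_window = 10, label = NA_integer_) {
  if (inherits(images, "motion_images")) {
    times <- images$times
    imgs <- images$images
  } else {
    imgs <- images
    times <- seq_along(imgs)
  }
  want <- (t - half_window):(t + half_window)
  pos <- match(want, times)
  if (anyNA(pos)) {
    stop(sprintf("segment window [%d, %d] out of range [%d, %d]",
                 t - half_window, t + half_window, min(times), max(times)))
  }
  structure(list(images = imgs[pos], t = t, label = label), class = "segment")
}

#' Label of the segment at centre time t
#'
#' A segment inherits exactly the frame label at its centre time;
#' neighbouring labels are irrelevant.
#'
#' @param frame_labels Integer 0/1 vector of per-frame labels; element 1 is
#'   frame 0 (0-based frame indexing).
#' @param t Centre time (0-based frame index).
#' @return The 0/1 label at `t`.
#' @export
label_segment <- function(frame_labels, t) {
  if (t < 0 || t > length(frame_labels) - 1L) {
    stop(sprintf("t = %d outside label track [0, %d]", t, length(frame_labels) - 1L))
  }
  as.integer(frame_labels[t + 1L])
}

#' Assemble a labelled segment dataset from one or more videos
#'
#' For every video, one segment is created per admissible centre time
#' (those whose `half_window` neighbourhood of motion images exists), and
#' labelled with the frame label at that time.  Images are stored once per
#' video and referenced by the segments, so overlapping windows cost no
#' extra memory.
#'
#' @param videos List of videos; each a list with `images` (a
#'   `motion_images` object or list of matrices), `labels` (0/1 per-frame
#'   vector, element 1 = frame 0), optionally `grooming` (same format) and
#'   `id`.
#' @param half_window Window half width (default 10).
#' @return An object of class `segment_set`: list with `videos` (per-video
#'   images/times/id), `index` (data.frame `video, t, label`), `half_window`,
#'   `counts` (per-class segment counts) and `scratch_index` (rows of
#'   `index` labelled 1).
#' @export
build_dataset <- function(videos, half_window = 10) {
  stopifnot(length(videos) >= 1)
  half_window <- as.integer(half_window)
  vids <- list()
  idx <- list()
  for (v in seq_along(videos)) {
    vid <- videos[[v]]
    id <- if (!is.null(vid$id)) vid$id else sprintf("video%02d", v)
    mi <- vid$images
    if (inherits(mi, "motion_images")) {
      times <- mi$times; imgs <- mi$images
    } else {
      imgs <- mi; times <- seq_along(imgs)
    }
    labels <- as.integer(vid$labels)
    # motion image at time t needs frames t-1, t; label track covers frames
    # 0 .. length(labels)-1
    if (max(times) > length(labels) - 1L) {
      stop(sprintf("video '%s': %d motion images but only %d frame labels",
                   id, length(imgs), length(labels)))
    }
    ok <- times[times - half_window >= min(times) & times + half_window <= max(times)]
    if (length(ok)) {
      idx[[length(idx) + 1L]] <- data.frame(
        video = v, t = ok, label = vapply(ok, function(t) label_segment(labels, t), 1L))
    }
    vids[[v]] <- list(images = imgs, times = times, id = id,
                      labels = labels,
                      grooming = if (!is.null(vid$grooming)) as.integer(vid$grooming) else NULL)
  }
  index <- if (length(idx)) do.call(rbind, idx) else data.frame(video = integer(), t = integer(), label = integer())
  structure(list(videos = vids, index = index, half_window = half_window,
                 counts = c(scratch = sum(index$label == 1L),
                            other = sum(index$label == 0L)),
                 scratch_index = which(index$label == 1L)),
            class = "segment_set")
}

#' Materialise one segment of a segment set
#'
#' @param segset A `segment_set`.
#' @param i Row of `segset$index`.
#' @return A `segment` object.
#' @export
get_segment <- function(segset, i) {
  row <- segset$index[i, ]
  vid <- segset$videos[[row$video]]
  pos <- match((row$t - segset$half_window):(row$t + segset$half_window), vid$times)
  structure(list(images = vid$images[pos], t = row$t, label = row$label),
            class = "segment")
}

#' @export
print.segment_set <- function(x, ...) {
  cat(sprintf("<segment_set> %d segments from %d video(s): %d scratch (%.2f%%), %d other\n",
              nrow(x$index), length(x$videos), x$counts[["scratch"]],
              100 * x$counts[["scratch"]] / max(1, nrow(x$index)),
              x$counts[["other"]]))
  invisible(x)
}

#' Read a frame-label CSV
#'
#' Two dialects are accepted: per-frame rows with header
#' `frame_index,scratch[,grooming]` (0-based frame index), or behaviour
#' intervals with header `start_frame,end_frame,behaviour` which are
#' expanded inclusively onto `n_frames` frames.
#'
#' @param path CSV file.
#' @param n_frames Total frame count (required for the interval dialect;
#'   otherwise inferred as `max(frame_index) + 1`).
#' @return List with `scratch` (0/1 vector, element 1 = frame 0) and
#'   `grooming` (or NULL).
#' @export
read_labels <- function(path, n_frames = NULL) {
  d <- read.csv(path)
  if (all(c("frame_index", "scratch") %in% names(d))) {
    n <- if (is.null(n_frames)) max(d$frame_index) + 1L else n_frames
    scratch <- integer(n)
    scratch[d$frame_index + 1L] <- as.integer(d$scratch)
    grooming <- NULL
    if ("grooming" %in% names(d)) {
      grooming <- integer(n)
      grooming[d$frame_index + 1L] <- as.integer(d$grooming)
    }
    return(list(scratch = scratch, grooming = grooming))
  }
  if (all(c("start_frame", "end_frame", "behaviour") %in% names(d))) {
    if (is.null(n_frames)) n_frames <- max(d$end_frame) + 1L
    scratch <- integer(n_frames)
    grooming <- integer(n_frames)
    for (i in seq_len(nrow(d))) {
      span <- (d$start_frame[i]:d$end_frame[i]) + 1L
      if (d$behaviour[i] == "scratch") scratch[span] <- 1L
      if (d$behaviour[i] == "groom") grooming[span] <- 1L
    }
    return(list(scratch = scratch, grooming = grooming))
  }
  stop("unrecognised label CSV: need frame_index,scratch[,grooming] or start_frame,end_frame,behaviour")
}

#' Write a per-frame label CSV
#'
#' @param labels List with `scratch` and optional `grooming` 0/1 vectors.
#' @param path Output CSV.
#' @export
write_labels <- function(labels, path) {
  d <- data.frame(frame_index = seq_along(labels$scratch) - 1L,
                  scratch = as.integer(labels$scratch))
  if (!is.null(labels$grooming)) d$grooming <- as.integer(labels$grooming)
  write.csv(d, path, row.names = FALSE)
}
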