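# Artifact formats: packed binary image arrays + JSON manifests for motion
# images and segment sets, checkpoint save/load for fitted models, and the
# track CSV dialects.

pack_images <- function(images) {
  do.call(c, lapply(images, as.vector))
}

unpack_images <- function(bytes, n, px) {
  lapply(seq_len(n), function(i) {
    matrix(bytes[((i - 1) * px * px + 1):(i * px * px)], px, px)
  })
}

#' Write motion images to disk
#'
#' Stores the binarized images as one packed binary array (1 byte per
#' pixel) with a JSON header, and the centroid track as CSV
#' (`frame_index,x,y,valid`).
#'
#' @param m A `motion_images` object.
#' @param prefix Output path prefix; writes `<prefix>.bin`,
#'   `<prefix>.json`, `<prefix>_centroids.csv`.
#' @export
write_motion <- function(m, prefix) {
  stopifnot(inherits(m, "motion_images"))
  writeBin(pack_images(m$images), paste0(prefix, ".bin"))
  jsonlite::write_json(list(n = length(m$images), px = m$px, times = m$times,
                            params = m$params),
                       paste0(prefix, ".json"), auto_unbox = TRUE, digits = NA)
  write.csv(m$centroids, paste0(prefix, "_centroids.csv"), row.names = FALSE)
}

#' Read motion images written by [write_motion()]
#'
#' @param prefix Path prefix used when writing.
#' @return A `motion_images` object.
#' @export
read_motion <- function(prefix) {
  hdr <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  bytes <- readBin(paste0(prefix, ".bin"), "raw", n = hdr$n * hdr$px^2)
  structure(list(images = unpack_images(bytes, hdr$n, hdr$px),
                 times = as.integer(hdr$times),
                 centroids = read.csv(paste0(prefix, "_centroids.csv")),
                 px = hdr$px, params = as.list(hdr$params)),
            class = "motion_images")
}

#' Write a segment set to disk
#'
#' Persists the per-video images as a packed binary array plus a JSON
#' manifest holding video ids, motion-image times and the full per-frame
#' label tracks, from which the segment index is rebuilt on read.
#'
#' @param segset A `segment_set`.
#' @param prefix Output path prefix; writes `<prefix>.bin`, `<prefix>.json`.
#' @export
write_segments <- function(segset, prefix) {
  stopifnot(inherits(segset, "segment_set"))
  con <- file(paste0(prefix, ".bin"), "wb")
  on.exit(close(con))
  vids <- lapply(segset$videos, function(v) {
    writeBin(pack_images(v$images), con)
    list(id = v$id, n_images = length(v$images),
         px = nrow(v$images[[1]]), times = v$times, labels = v$labels,
         grooming = v$grooming)
  })
  jsonlite::write_json(list(half_window = segset$half_window, videos = vids),
                       paste0(prefix, ".json"), auto_unbox = TRUE, digits = NA,
                       null = "null")
}

#' Read a segment set written by [write_segments()]
#'
#' @param prefix Path prefix used when writing.
#' @return A `segment_set`.
#' @export
read_segments <- function(prefix) {
  man <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  con <- file(paste0(prefix, ".bin"), "rb")
  on.exit(close(con))
  vids <- lapply(seq_len(nrow(man$videos)), function(i) {
    v <- man$videos[i, ]
    bytes <- readBin(con, "raw", n = v$n_images * v$px^2)
    imgs <- unpack_images(bytes, v$n_images, v$px)
    mi <- structure(list(images = imgs, times = as.integer(v$times[[1]]),
                         centroids = NULL, px = v$px, params = list()),
                    class = "motion_images")
    grooming <- v$grooming[[1]]
    list(images = mi, labels = as.integer(v$labels[[1]]),
         grooming = if (all(is.na(grooming)) || is.null(grooming)) NULL else as.integer(grooming),
         id = v$id)
  })
  build_dataset(vids, half_window = man$half_window)
}

spec_fingerprint <- function(spec) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(spec_as_list(spec), tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

#' Save a fitted model checkpoint
#'
#' Writes the flat weight vector (binary doubles), the optimiser moments,
#' and a JSON description: the architecture, a fingerprint of it, training
#' metadata and the loss history.  A checkpoint can only be loaded against
#' a matching architecture fingerprint.
#'
#' @param model A `scratch_crnn`.
#' @param dir Output directory (created if needed).
#' @export
save_crnn <- function(model, dir) {
  stopifnot(inherits(model, "scratch_crnn"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeBin(model$state$theta, file.path(dir, "weights.bin"))
  writeBin(c(model$state$adam_m, model$state$adam_v), file.path(dir, "adam.bin"))
  jsonlite::write_json(list(spec = spec_as_list(model$spec),
                            fingerprint = spec_fingerprint(model$spec),
                            step = model$state$step, meta = model$meta,
                            history = model$history),
                       file.path(dir, "model.json"), auto_unbox = TRUE, digits = NA)
}

#' Load a model checkpoint written by [save_crnn()]
#'
#' @param dir Checkpoint directory.
#' @return A `scratch_crnn`.
#' @export
load_crnn <- function(dir) {
  j <- jsonlite::read_json(file.path(dir, "model.json"), simplifyVector = TRUE)
  spec <- do.call(crnn_spec, as.list(j$spec))
  if (!identical(unname(spec_fingerprint(spec)), unname(j$fingerprint)))
    stop("checkpoint fingerprint does not match its architecture description")
  np <- n_params(spec)
  theta <- readBin(file.path(dir, "weights.bin"), "double", n = np + 1)
  if (length(theta) != np)
    stop(sprintf("weight file has %d parameters, spec needs %d", length(theta), np))
  state <- new.env(parent = emptyenv())
  state$theta <- theta
  mv <- readBin(file.path(dir, "adam.bin"), "double", n = 2 * np)
  state$adam_m <- mv[seq_len(np)]
  state$adam_v <- mv[np + seq_len(np)]
  state$step <- as.integer(j$step)
  hist <- as.data.frame(j$history)
  if (!nrow(hist)) hist <- data.frame(epoch = integer(), mean_loss = numeric(),
                                      scratch_fraction = numeric())
  structure(list(spec = spec, state = state, meta = as.list(j$meta), history = hist),
            class = "scratch_crnn")
}

#' Write a probability or label track CSV
#'
#' Columns are `segment_time,probability` for probability tracks and
#' `segment_time,label` for binary tracks.
#'
#' @param track data.frame with `time` and `prob` or `value`.
#' @param path Output CSV.
#' @export
write_track <- function(track, path) {
  if ("prob" %in% names(track)) {
    write.csv(data.frame(segment_time = track$time, probability = track$prob),
              path, row.names = FALSE)
  } else {
    write.csv(data.frame(segment_time = track$time, label = track$value),
              path, row.names = FALSE)
  }
}

#' Read a track CSV written by [write_track()]
#'
#' @param path CSV with `segment_time` and `probability` or `label`.
#' @return data.frame with `time` and `prob` or `value`.
#' @export
read_track <- function(path) {
  d <- read.csv(path)
  if ("probability" %in% names(d)) {
    data.frame(time = as.integer(d$segment_time), prob = d$probability)
  } else if ("label" %in% names(d)) {
    data.frame(time = as.integer(d$segment_time), value = as.integer(d$label))
  } else {
    stop("track CSV needs segment_time plus probability or label")
  }
}
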