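# Motion-image preprocessing: frame differencing, centroid tracking,
# crop + binarize.  A "frame" is an integer (or numeric) matrix of 8-bit
# grey intensities; a "motion image" is a raw 0/1 matrix.

#' Absolute difference between two consecutive frames
#'
#' Computes the per-pixel absolute intensity difference between two
#' greyscale frames, the first step of motion-image preprocessing.  Static
#' background cancels exactly; only moving structures survive.
#'
#' @param prev,curr Greyscale frames as matrices of intensities in
#'   `[0, 255]`, identical dimensions.
#' @return An integer matrix of the same dimensions, `abs(curr - prev)`.
#' @examples
#' a <- matrix(10L, 4, 4); b <- matrix(36L, 4, 4)
#' frame_difference(a, b)[1, 1]  # 26
#' @export
frame_difference <- function(prev, curr) {
  if (!all(dim(prev) == dim(curr))) {
    stop(sprintf("frame dimension mismatch: %dx%d vs %dx%d",
                 nrow(prev), ncol(prev), nrow(curr), ncol(curr)))
  }
  d <- abs(curr - prev)
  storage.mode(d) <- "integer"
  d
}

#' Estimate the animal centroid from a difference image
#'
#' The centroid is the mean position of all pixels whose difference
#' intensity exceeds `threshold` (the motion-energy centre of mass).  When
#' fewer than `min_pixels` pixels exceed the threshold -- e.g. a resting
#' animal produces an (almost) all-zero difference image -- the previous
#' centroid is returned instead (or the image centre if there is none) and
#' the estimate is flagged invalid.
#'
#' Coordinates are `(x, y)` = (column, row), 1-based pixel units.
#'
#' @param diff Difference image matrix.
#' @param threshold Intensity threshold in `[0, 255]`; strictly-greater
#'   comparison.
#' @param prev Optional previous centroid `c(x, y)` used as fallback.
#' @param min_pixels Minimum number of above-threshold pixels for a valid
#'   estimate (default 20).
#' @return A list with `x`, `y` and logical `valid`.
#' @export
estimate_centroid <- function(diff, threshold = 25, prev = NULL, min_pixels = 20) {
  stopifnot(threshold >= 0, threshold <= 255)
  idx <- which(diff > threshold)
  if (length(idx) < min_pixels) {
    if (is.null(prev)) {
      prev <- c((ncol(diff) + 1) / 2, (nrow(diff) + 1) / 2)
    }
    return(list(x = prev[[1]], y = prev[[2]], valid = FALSE))
  }
  nr <- nrow(diff)
  rows <- ((idx - 1L) %% nr) + 1L
  cols <- ((idx - 1L) %/% nr) + 1L
  list(x = mean(cols), y = mean(rows), valid = TRUE)
}

#' Crop a difference image around a centre and binarize it
#'
#' Extracts a `crop_px` x `crop_px` window centred on `centre` (rounded to
#' the nearest pixel; the window spans offsets `-crop_px/2 ... crop_px/2 - 1`
#' from the centre) and binarizes it: output pixel is 1 iff the difference
#' intensity is strictly greater than `threshold`.  Window regions falling
#' outside the image are zero-filled.
#'
#' @param diff Difference image matrix.
#' @param centre Centre `c(x, y)` (column, row) in source pixel coordinates.
#' @param crop_px Side length of the square crop (default 300).
#' @param threshold Binarization threshold in `[0, 255]` (default 25;
#'   strictly-greater comparison).
#' @return A `crop_px` x `crop_px` raw matrix with values 0/1 (a motion
#'   image).  Use `motion_to_matrix()` for an integer view.
#' @export
crop_binarize <- function(diff, centre, crop_px = 300, threshold = 25) {
  stopifnot(threshold >= 0, threshold <= 255, crop_px >= 1)
  cx <- as.integer(round(centre[[1]]))
  cy <- as.integer(round(centre[[2]]))
  half <- crop_px %/% 2
  # target rows/cols in source coordinates (may exceed the image)
  rows <- (cy - half):(cy - half + crop_px - 1L)
  cols <- (cx - half):(cx - half + crop_px - 1L)
  out <- matrix(as.raw(0), crop_px, crop_px)
  rok <- which(rows >= 1L & rows <= nrow(diff))
  cok <- which(cols >= 1L & cols <= ncol(diff))
  if (length(rok) && length(cok)) {
    sub <- diff[rows[rok], cols[cok], drop = FALSE]
    out[rok, cok] <- as.raw(sub > threshold)
  }
  out
}

#' Integer view of a motion image
#'
#' @param img Raw 0/1 motion-image matrix.
#' @return Integer matrix of 0s and 1s with the same dimensions.
#' @export
motion_to_matrix <- function(img) {
  m <- matrix(as.integer(img != as.raw(0)), nrow(img), ncol(img))
  m
}

#' A pluggable source of video frames
#'
#' Normalises the supported frame inputs -- an in-memory list of frame
#' matrices, a directory of numbered PNG/TIFF frames (lexicographic order =
#' temporal order), or a function `f(i)` with an `n` attribute -- into a
#' list with fields `n` and `get(i)` (1-based).
#'
#' @param x List of matrices, directory path, or accessor function.
#' @return A list with elements `n` (frame count) and `get` (accessor).
#' @export
frame_source <- function(x) {
  if (is.list(x)) {
    return(list(n = length(x), get = function(i) x[[i]]))
  }
  if (is.function(x)) {
    n <- attr(x, "n")
    if (is.null(n)) stop("frame accessor function needs an 'n' attribute")
    return(list(n = n, get = x))
  }
  if (is.character(x) && length(x) == 1 && dir.exists(x)) {
    files <- sort(list.files(x, pattern = "\\.(png|tif|tiff)$", ignore.case = TRUE,
                             full.names = TRUE))
    if (!length(files)) stop("no PNG/TIFF frames found in ", x)
    return(list(n = length(files), get = function(i) read_frame(files[i])))
  }
  stop("unsupported frame source: need a list of matrices, a directory, or a function")
}

#' Read a single frame image as a greyscale intensity matrix
#'
#' Colour input is converted to grey by standard luma weighting
#' (0.299 R + 0.587 G + 0.114 B).
#'
#' @param path PNG or TIFF file.
#' @return Integer matrix of intensities in `[0, 255]`.
#' @export
read_frame <- function(path) {
  ext <- tolower(tools::file_ext(path))
  a <- if (ext == "png") {
    png::readPNG(path)
  } else if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE)) stop("package 'tiff' required for TIFF frames")
    tiff::readTIFF(path)
  } else {
    stop("unsupported frame format: ", ext)
  }
  if (length(dim(a)) == 3) {
    ch <- dim(a)[3]
    a <- if (ch >= 3) 0.299 * a[, , 1] + 0.587 * a[, , 2] + 0.114 * a[, , 3] else a[, , 1]
  }
  m <- round(a * 255)
  storage.mode(m) <- "integer"
  m
}

#' Preprocess a frame sequence into motion images
#'
#' Applies the full preprocessing chain to every pair of adjoining frames:
#' absolute difference, motion-energy centroid estimation (exponentially
#' smoothed across frames, with fallback to the last valid centroid on
#' quiet frames), crop to `crop_px` and binarization.  All frames except
#' the first yield a motion image, so `N` frames give `N - 1` motion
#' images; motion image `t` is derived from frames `t - 1` and `t`
#' (0-based frame indexing).
#'
#' @param frames Frame source accepted by [frame_source()] (at least 2
#'   frames).
#' @param threshold Binarization / centroid intensity threshold (default 25).
#' @param crop_px Crop side length (default 300).
#' @param smooth Exponential smoothing factor for the centroid track in
#'   `(0, 1]`; 1 disables smoothing (default 0.5).
#' @param min_pixels Minimum above-threshold pixel count for a valid
#'   centroid (default 20).
#' @return An object of class `motion_images`: list with `images` (raw 0/1
#'   matrices), `times` (0-based difference indices `1 ... N-1`),
#'   `centroids` (data.frame `frame_index, x, y, valid`), `px`, and the
#'   parameters used.
#' @export
preprocess_sequence <- function(frames, threshold = 25, crop_px = 300,
                                smooth = 0.5, min_pixels = 20) {
  src <- frame_source(frames)
  if (src$n < 2) stop("need at least 2 frames, got ", src$n)
  n_out <- src$n - 1L
  images <- vector("list", n_out)
  cent <- data.frame(frame_index = integer(n_out), x = numeric(n_out),
                     y = numeric(n_out), valid = logical(n_out))
  prev <- src$get(1L)
  sm <- NULL # smoothed centroid
  for (i in seq_len(n_out)) {
    curr <- src$get(i + 1L)
    d <- frame_difference(prev, curr)
    est <- estimate_centroid(d, threshold = threshold, prev = sm,
                             min_pixels = min_pixels)
    if (est$valid) {
      sm <- if (is.null(sm)) c(est$x, est$y)
            else smooth * c(est$x, est$y) + (1 - smooth) * sm
    } else {
      sm <- c(est$x, est$y) # fallback value (previous centroid or centre)
    }
    images[[i]] <- crop_binarize(d, sm, crop_px = crop_px, threshold = threshold)
    cent$frame_index[i] <- i            # 0-based index of the current frame
    cent$x[i] <- sm[1]; cent$y[i] <- sm[2]; cent$valid[i] <- est$valid
    prev <- curr
  }
  structure(list(images = images, times = seq_len(n_out), centroids = cent,
                 px = crop_px,
                 params = list(threshold = threshold, crop_px = crop_px,
                               smooth = smooth, min_pixels = min_pixels)),
            class = "motion_images")
}

#' @export
print.motion_images <- function(x, ...) {
  cat(sprintf("<motion_images> %d images of %dx%d (threshold %s, %.0f%% valid centroids)\n",
              length(x$images), x$px, x$px, x$params$threshold,
              100 * mean(x$centroids$valid)))
  invisible(x)
}
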