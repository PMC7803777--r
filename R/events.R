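# Event extraction and evaluation: probability -> binary tracks, maximal
# runs of scratch segments, confusion metrics, the three-way error
# taxonomy (boundary / false detection / oversight), and event-level
# count/duration comparisons.

as_track <- function(x) {
  # accept a data.frame(time, value|prob) or a bare vector (times 0-based)
  if (is.data.frame(x)) {
    val <- if ("value" %in% names(x)) x$value else x$prob
    stopifnot(!is.null(x$time), !is.null(val))
    data.frame(time = as.integer(x$time), value = val)
  } else {
    data.frame(time = seq_along(x) - 1L, value = x)
  }
}

#' Threshold a probability track into a scratch/non-scratch track
#'
#' A segment is classified as scratching when its probability is strictly
#' greater than `cutoff`; a value of exactly `cutoff` is non-scratch.
#'
#' @param probs data.frame with `time` and `prob` columns, or a bare
#'   probability vector (times then 0-based).
#' @param cutoff Threshold in `[0, 1]` (default 0.5).
#' @return data.frame with `time` and binary `value`.
#' @export
threshold_track <- function(probs, cutoff = 0.5) {
  stopifnot(cutoff >= 0, cutoff <= 1)
  tr <- as_track(probs)
  data.frame(time = tr$time, value = as.integer(tr$value > cutoff))
}

#' Extract scratch events from a binary track
#'
#' An event is a maximal run of consecutive scratch segments; a gap in the
#' track's centre times splits runs.  Durations are `n_segments / fps`
#' seconds.
#'
#' @param track Binary track (data.frame `time, value` or bare 0/1 vector).
#' @param fps Frames per second (default 60).
#' @return data.frame with `start_t`, `end_t` (inclusive), `n_segments`,
#'   `duration_s`; zero rows if the track has no scratch segment.
#' @export
extract_events <- function(track, fps = 60) {
  tr <- as_track(track)
  tr <- tr[order(tr$time), ]
  on <- tr$time[tr$value == 1L]
  if (!length(on)) {
    return(data.frame(start_t = integer(), end_t = integer(),
                      n_segments = integer(), duration_s = numeric()))
  }
  brk <- c(0L, which(diff(on) != 1L), length(on))
  starts <- on[brk[-length(brk)] + 1L]
  ends <- on[brk[-1L]]
  data.frame(start_t = starts, end_t = ends,
             n_segments = as.integer(ends - starts + 1L),
             duration_s = (ends - starts + 1) / fps)
}

#' Rebuild a binary track from its events
#'
#' Inverse of [extract_events()] over a given set of centre times.
#'
#' @param events data.frame with `start_t`, `end_t`.
#' @param times Centre times of the track to reconstruct.
#' @return data.frame `time, value`.
#' @export
events_to_track <- function(events, times) {
  value <- integer(length(times))
  for (i in seq_len(nrow(events))) {
    value[times >= events$start_t[i] & times <= events$end_t[i]] <- 1L
  }
  data.frame(time = as.integer(times), value = value)
}

check_aligned <- function(pred, obs) {
  if (length(pred$time) != length(obs$time) || any(pred$time != obs$time))
    stop("prediction and observation tracks have different segment time indices")
}

#' Segment-level confusion matrix of prediction vs observation
#'
#' @param pred,obs Aligned binary tracks (identical time index sets).
#' @return Object of class `confusion`: list with counts `tp`, `fn`, `fp`,
#'   `tn`.
#' @export
confusion <- function(pred, obs) {
  p <- as_track(pred); o <- as_track(obs)
  check_aligned(p, o)
  structure(list(tp = sum(p$value == 1L & o$value == 1L),
                 fn = sum(p$value == 0L & o$value == 1L),
                 fp = sum(p$value == 1L & o$value == 0L),
                 tn = sum(p$value == 0L & o$value == 0L)),
            class = "confusion")
}

#' @export
print.confusion <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
              dimnames = list(prediction = c("scratch", "not scratch"),
                              observation = c("scratch", "not scratch")))
  print(m)
  invisible(x)
}

#' Confusion-matrix percentages
#'
#' Sensitivity `100 tp/(tp+fn)`, specificity `100 tn/(tn+fp)`, positive
#' predictive value `100 tp/(tp+fp)` and negative predictive value
#' `100 tn/(tn+fn)`.  A metric whose denominator is 0 is undefined and
#' reported as `NA`.
#'
#' @param cm A `confusion` object or list with `tp`, `fn`, `fp`, `tn`.
#' @return Named numeric vector (percentages) with elements `sensitivity`,
#'   `specificity`, `ppv`, `npv`; undefined entries are `NA`.
#' @export
metrics <- function(cm) {
  rate <- function(num, den) if (den == 0) NA_real_ else 100 * num / den
  c(sensitivity = rate(cm$tp, cm$tp + cm$fn),
    specificity = rate(cm$tn, cm$tn + cm$fp),
    ppv = rate(cm$tp, cm$tp + cm$fp),
    npv = rate(cm$tn, cm$tn + cm$fn))
}

#' Classify error segments into boundary / false detection / oversight
#'
#' Every false-positive segment belongs to a predicted event: if that
#' event overlaps at least one observed event the error is a *boundary*
#' error (a start/end discrepancy), otherwise a *false detection*.  Every
#' false-negative segment belongs to an observed event: overlap with some
#' predicted event makes it a boundary error, otherwise an *oversight*.
#' The three counts always sum to `fp + fn` of the same comparison.
#'
#' @param pred,obs Aligned binary tracks.
#' @return Object of class `error_breakdown`: list with `boundary`,
#'   `false_detection`, `oversight` segment counts.
#' @export
classify_errors <- function(pred, obs) {
  p <- as_track(pred); o <- as_track(obs)
  check_aligned(p, o)
  pe <- extract_events(p)
  oe <- extract_events(o)
  overlaps_any <- function(s, e, other) {
    any(other$start_t <= e & other$end_t >= s)
  }
  boundary <- 0L; false_detection <- 0L; oversight <- 0L
  for (i in seq_len(nrow(pe))) {
    span <- p$time >= pe$start_t[i] & p$time <= pe$end_t[i]
    n_fp <- sum(span & o$value == 0L)
    if (overlaps_any(pe$start_t[i], pe$end_t[i], oe)) boundary <- boundary + n_fp
    else false_detection <- false_detection + n_fp
  }
  for (i in seq_len(nrow(oe))) {
    span <- o$time >= oe$start_t[i] & o$time <= oe$end_t[i]
    n_fn <- sum(span & p$value == 0L)
    if (overlaps_any(oe$start_t[i], oe$end_t[i], pe)) boundary <- boundary + n_fn
    else oversight <- oversight + n_fn
  }
  structure(list(boundary = boundary, false_detection = false_detection,
                 oversight = oversight),
            class = "error_breakdown")
}

#' @export
print.error_breakdown <- function(x, ...) {
  tot <- x$boundary + x$false_detection + x$oversight
  cat(sprintf("error segments: %d boundary, %d false detection, %d oversight (total %d)\n",
              x$boundary, x$false_detection, x$oversight, tot))
  invisible(x)
}

#' Pearson correlation of predicted vs observed event counts
#'
#' Compares the number of scratch events per video between prediction and
#' observation.
#'
#' @param counts data.frame with columns `pred` and `obs` (one row per
#'   video), at least 3 rows.
#' @return Pearson's r, or `NA` if either coordinate has zero variance.
#' @export
count_correlation <- function(counts) {
  stopifnot(nrow(counts) >= 3)
  if (stats::sd(counts$pred) == 0 || stats::sd(counts$obs) == 0) return(NA_real_)
  cor(counts$pred, counts$obs)
}

#' Match observed scratch events with overlapping predicted events
#'
#' Observed-event-centric duration comparison: each observed event is
#' paired with the summed duration of all predicted events overlapping it
#' (0 when none overlaps -- a prediction may fragment one long observed
#' bout into several short events, whose durations are accumulated).
#' Predicted events overlapping no observed event are reported separately.
#'
#' @param pred_events,obs_events Event data.frames from
#'   [extract_events()] on aligned tracks.
#' @return List with `pairs` (data.frame `obs_duration, pred_duration`)
#'   and `unmatched_pred` (events overlapping no observed event).
#' @export
match_durations <- function(pred_events, obs_events) {
  pred_matched <- logical(nrow(pred_events))
  pairs <- data.frame(obs_duration = numeric(nrow(obs_events)),
                      pred_duration = numeric(nrow(obs_events)))
  for (i in seq_len(nrow(obs_events))) {
    ov <- which(pred_events$start_t <= obs_events$end_t[i] &
                pred_events$end_t >= obs_events$start_t[i])
    pred_matched[ov] <- TRUE
    pairs$obs_duration[i] <- obs_events$duration_s[i]
    pairs$pred_duration[i] <- sum(pred_events$duration_s[ov])
  }
  list(pairs = pairs, unmatched_pred = pred_events[!pred_matched, , drop = FALSE])
}

#' Count grooming segments classified as scratching
#'
#' Measures confusion with grooming, the behaviour most similar to
#' scratching: how many segments labelled as grooming were predicted
#' scratch.
#'
#' @param pred Predicted binary track.
#' @param grooming Grooming-labelled binary track, aligned with `pred`.
#' @return Integer count.
#' @export
grooming_confusion <- function(pred, grooming) {
  p <- as_track(pred); g <- as_track(grooming)
  check_aligned(p, g)
  sum(p$value == 1L & g$value == 1L)
}

#' Full evaluation of a predicted track against observation
#'
#' Bundles the segment-level confusion matrix and percentages, the error
#' taxonomy, the event lists and the duration matching; optionally the
#' grooming confusion count.
#'
#' @param pred,obs Aligned binary tracks.
#' @param fps Frames per second (default 60).
#' @param grooming Optional grooming track aligned with `pred`.
#' @return Object of class `scratch_eval`.
#' @export
evaluate_tracks <- function(pred, obs, fps = 60, grooming = NULL) {
  p <- as_track(pred); o <- as_track(obs)
  cm <- confusion(p, o)
  ev_p <- extract_events(p, fps = fps)
  ev_o <- extract_events(o, fps = fps)
  out <- list(confusion = cm, metrics = metrics(cm),
              errors = classify_errors(p, o),
              pred_events = ev_p, obs_events = ev_o,
              durations = match_durations(ev_p, ev_o),
              grooming_as_scratch = if (!is.null(grooming)) grooming_confusion(p, grooming) else NA_integer_,
              fps = fps)
  class(out) <- "scratch_eval"
  out
}

#' @export
print.scratch_eval <- function(x, ...) {
  print(x$confusion)
  m <- x$metrics
  cat(sprintf("sensitivity %.1f%%  specificity %.1f%%  ppv %.1f%%  npv %.1f%%\n",
              m["sensitivity"], m["specificity"], m["ppv"], m["npv"]))
  print(x$errors)
  cat(sprintf("events: %d predicted, %d observed\n",
              nrow(x$pred_events), nrow(x$obs_events)))
  if (!is.na(x$grooming_as_scratch))
    cat(sprintf("grooming segments predicted as scratching: %d\n", x$grooming_as_scratch))
  invisible(x)
}

#' Serialise an evaluation to JSON
#'
#' @param x A `scratch_eval`.
#' @param path Output file.
#' @export
write_eval_json <- function(x, path) {
  jsonlite::write_json(list(
    confusion = x$confusion[c("tp", "fn", "fp", "tn")],
    metrics = as.list(x$metrics),
    errors = x$errors[c("boundary", "false_detection", "oversight")],
    pred_events = x$pred_events, obs_events = x$obs_events,
    grooming_as_scratch = x$grooming_as_scratch, fps = x$fps
  ), path, auto_unbox = TRUE, digits = NA, na = "null")
}
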