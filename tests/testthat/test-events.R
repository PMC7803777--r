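test_that("thresholding is strictly greater-than the cutoff", {
  pr <- data.frame(time = 0:3, prob = c(0.6, 0.5, 0.501, 0.01))
  tr <- threshold_track(pr)
  expect_identical(tr$value, c(1L, 0L, 1L, 0L))  # exactly 0.5 is non-scratch
  expect_identical(threshold_track(rep(0.01, 5))$value, integer(5) + 0L)
})

test_that("events are maximal runs of scratch segments", {
  ev <- extract_events(c(0, 0, 1, 1, 1, 0, 1, 0))
  expect_equal(nrow(ev), 2)
  expect_equal(ev$start_t, c(2, 6))
  expect_equal(ev$end_t, c(4, 6))
  expect_equal(ev$n_segments, c(3L, 1L))
  expect_equal(ev$duration_s, c(3, 1) / 60)      # 3 segments at 60 fps = 0.05 s
  expect_equal(nrow(extract_events(integer(10))), 0)
  # a gap in centre times splits a run
  gap <- data.frame(time = c(1, 2, 4, 5), value = c(1, 1, 1, 1))
  expect_equal(nrow(extract_events(gap)), 2)
})

test_that("events and tracks are a bijection", {
  for (seed in 1:25) {
    tr <- random_track_pair(80, seed)$pred
    ev <- extract_events(tr)
    back <- events_to_track(ev, times = seq_along(tr) - 1L)
    expect_identical(back$value, as.integer(tr))
    expect_identical(extract_events(back), ev)
  }
})

test_that("the confusion matrix counts the four outcomes", {
  cm <- confusion(c(1, 1, 0, 0), c(1, 0, 1, 0))
  expect_equal(unclass(cm)[c("tp", "fp", "fn", "tn")],
               list(tp = 1L, fp = 1L, fn = 1L, tn = 1L))
  cm2 <- confusion(c(1, 0, 1), c(1, 0, 1))
  expect_equal(cm2$fp + cm2$fn, 0)
  set.seed(8)
  for (i in 1:10) {
    p <- random_track_pair(50, i)
    cm3 <- confusion(p$pred, p$obs)
    expect_equal(cm3$tp + cm3$fn, sum(p$obs))            # conservation
    expect_equal(cm3$tp + cm3$fn + cm3$fp + cm3$tn, 50)
  }
  expect_error(confusion(data.frame(time = 1:3, value = 0),
                         data.frame(time = 2:4, value = 0)), "time indices")
})

test_that("metric closed forms and the undefined contract", {
  m <- metrics(list(tp = 80, fn = 20, fp = 10, tn = 890))
  expect_equal(unname(m["sensitivity"]), 80)
  expect_equal(unname(m["specificity"]), 100 * 890 / 900)
  expect_equal(unname(m["ppv"]), 100 * 80 / 90)
  expect_equal(unname(m["npv"]), 100 * 890 / 910)
  m0 <- metrics(list(tp = 0, fn = 0, fp = 3, tn = 7))
  expect_true(is.na(m0["sensitivity"]))                  # 0/0 is undefined
  expect_false(is.na(m0["specificity"]))
})

test_that("the error taxonomy resolves boundary, false detection, oversight", {
  # observed event 10-20, predicted 12-23: FNs 10-11 and FPs 21-23 are all
  # boundary errors of two overlapping events
  times <- 0:30
  obs <- events_to_track(data.frame(start_t = 10, end_t = 20), times)
  pred <- events_to_track(data.frame(start_t = 12, end_t = 23), times)
  eb <- classify_errors(pred, obs)
  expect_equal(eb$boundary, 5)
  expect_equal(eb$false_detection, 0)
  expect_equal(eb$oversight, 0)

  none <- data.frame(time = times, value = 0L)
  pred2 <- events_to_track(data.frame(start_t = 5, end_t = 8), times)
  expect_equal(classify_errors(pred2, none)$false_detection, 4)
  obs2 <- events_to_track(data.frame(start_t = 5, end_t = 8), times)
  expect_equal(classify_errors(none, obs2)$oversight, 4)
})

test_that("taxonomy and events match brute force on random tracks", {
  for (seed in 1:60) {
    len <- sample(20:60, 1)
    p <- random_track_pair(len, seed + 1000)
    expect_identical(extract_events(p$pred), brute_events(p$pred))
    eb <- classify_errors(p$pred, p$obs)
    bf <- brute_error_taxonomy(p$pred, p$obs)
    expect_equal(eb$boundary, bf$boundary)
    expect_equal(eb$false_detection, bf$false_detection)
    expect_equal(eb$oversight, bf$oversight)
    cm <- confusion(p$pred, p$obs)
    expect_equal(eb$boundary + eb$false_detection + eb$oversight, cm$fp + cm$fn)
  }
})

test_that("event-count correlation is Pearson's r with variance guard", {
  expect_equal(count_correlation(data.frame(pred = c(3, 5, 7), obs = c(3, 5, 7))), 1)
  expect_equal(count_correlation(data.frame(pred = c(1, 2, 3), obs = c(2, 4, 6))), 1)
  expect_true(is.na(count_correlation(data.frame(pred = c(2, 2, 2), obs = 1:3))))
  set.seed(9)
  r <- count_correlation(data.frame(pred = rnorm(1000), obs = rnorm(1000)))
  expect_lt(abs(r), 0.1)                                 # independent: r near 0
})

test_that("duration matching is observed-event-centric with summed overlaps", {
  ev <- function(s, e) data.frame(start_t = s, end_t = e,
                                  n_segments = e - s + 1L,
                                  duration_s = (e - s + 1) / 60)
  obs <- ev(c(10, 40), c(25, 45))
  same <- match_durations(obs, obs)
  expect_equal(same$pairs$obs_duration, same$pairs$pred_duration)
  expect_equal(nrow(same$unmatched_pred), 0)

  # one long observed bout fragmented into four predicted events
  pred <- ev(c(10, 14, 18, 23), c(12, 16, 21, 25))
  md <- match_durations(pred, ev(10, 25))
  expect_equal(nrow(md$pairs), 1)
  expect_equal(md$pairs$pred_duration, sum(pred$duration_s))

  md2 <- match_durations(ev(100, 105), ev(10, 25))       # disjoint
  expect_equal(md2$pairs$pred_duration, 0)
  expect_equal(nrow(md2$unmatched_pred), 1)
})

test_that("grooming segments predicted as scratching are counted", {
  expect_equal(grooming_confusion(c(0, 0, 0), c(1, 1, 1)), 0)
  expect_equal(grooming_confusion(c(1, 0, 1), c(1, 1, 0)), 1)
  expect_equal(grooming_confusion(c(1, 1, 0, 0), c(0, 0, 1, 1)), 0) # disjoint
})

test_that("evaluate_tracks bundles every statistic consistently", {
  p <- random_track_pair(120, 77)
  ev <- evaluate_tracks(p$pred, p$obs, grooming = as.integer(!p$obs))
  expect_s3_class(ev, "scratch_eval")
  expect_equal(ev$errors$boundary + ev$errors$false_detection + ev$errors$oversight,
               ev$confusion$fp + ev$confusion$fn)
  expect_equal(nrow(ev$pred_events), nrow(extract_events(p$pred)))
  expect_output(print(ev), "sensitivity")
  f <- tempfile(fileext = ".json")
  write_eval_json(ev, f)
  j <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(j$confusion$tp, ev$confusion$tp)
})
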