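test_that("behaviour scripts tile the video exactly", {
  cfg <- synth_config(n_frames = 1000, frame_px = 240)
  set.seed(10)
  for (i in 1:10) {
    s <- script_behaviours(cfg)
    expect_equal(s$start_frame[1], 0)
    expect_equal(s$end_frame[nrow(s)], 999)
    if (nrow(s) > 1) {
      expect_true(all(s$start_frame[-1] == s$end_frame[-nrow(s)] + 1)) # contiguous
    }
    expect_true(all(s$behaviour %in% c("rest", "locomote", "groom", "scratch")))
  }
})

test_that("rest-only transition weights give a single rest interval", {
  tr <- matrix(0, 4, 4, dimnames = list(scratchdetect:::BEHAVIOURS,
                                        scratchdetect:::BEHAVIOURS))
  tr[c("locomote", "groom", "scratch"), "rest"] <- 1
  cfg <- synth_config(n_frames = 100, frame_px = 240, transition = tr)
  set.seed(11)
  s <- script_behaviours(cfg)
  expect_equal(nrow(s), 1)
  expect_equal(s$behaviour, "rest")
  expect_equal(c(s$start_frame, s$end_frame), c(0, 99))
})

test_that("dwell times are exponential with the configured mean", {
  # mean 2 s = 120 frames; empirical mean over ~10,000 intervals within 10%
  cfg <- synth_config(n_frames = 200000, frame_px = 240,
                      dwell = c(rest = 2, locomote = 2, groom = 2, scratch = 2),
                      ensure_scratch = FALSE)
  set.seed(12)
  d <- integer()
  while (length(d) < 10000) {
    s <- script_behaviours(cfg)
    d <- c(d, s$end_frame - s$start_frame + 1L)
  }
  expect_equal(mean(head(d, 10000)), 120, tolerance = 0.1)
})

test_that("an all-rest script with zero noise renders identical frames", {
  tr <- matrix(0, 4, 4, dimnames = list(scratchdetect:::BEHAVIOURS,
                                        scratchdetect:::BEHAVIOURS))
  tr[c("locomote", "groom", "scratch"), "rest"] <- 1
  cfg <- synth_config(n_frames = 20, frame_px = 240, noise_sd = 0, transition = tr)
  set.seed(13)
  r <- render_frames(script_behaviours(cfg), cfg)
  expect_true(all(r$labels == 0L))
  for (i in 2:20) expect_identical(r$frames[[i]], r$frames[[1]])
})

test_that("labels are 1 exactly on the scripted scratch intervals", {
  cfg <- synth_config(n_frames = 300, frame_px = 240)
  script <- data.frame(behaviour = c("rest", "scratch", "groom", "scratch"),
                       start_frame = c(0L, 50L, 150L, 250L),
                       end_frame = c(49L, 149L, 249L, 299L))
  class(script) <- c("behaviour_script", "data.frame")
  set.seed(14)
  r <- render_frames(script, cfg)
  want <- integer(300); want[51:150] <- 1L; want[251:300] <- 1L
  expect_identical(r$labels, want)
  wantg <- integer(300); wantg[151:250] <- 1L
  expect_identical(r$grooming, wantg)
})

test_that("scratch and grooming render at their configured frequencies", {
  cfg <- synth_config(n_frames = 660, frame_px = 240)
  script <- data.frame(behaviour = c("rest", "scratch", "groom"),
                       start_frame = c(0L, 60L, 420L),
                       end_frame = c(59L, 419L, 659L))
  class(script) <- c("behaviour_script", "data.frame")
  set.seed(15)
  r <- render_frames(script, cfg)
  count <- vapply(2:660, function(i) sum(abs(r$frames[[i]] - r$frames[[i - 1]]) > 25), 1)
  f_scratch <- dominant_frequency(count[61:419], cfg$fps)
  f_groom <- dominant_frequency(count[421:659], cfg$fps)
  expect_lt(abs(f_scratch - 12) / 12, 0.2)   # within 20% of 12 Hz
  expect_lt(abs(f_groom - 3) / 3, 0.2)
  # motion energy separates the behaviours for even a trivial baseline
  expect_gt(mean(count[61:419]), 3 * mean(count[421:659]))
  expect_gt(mean(count[421:659]), mean(count[2:59]))
})

test_that("dataset generation is seed-reproducible with per-video streams", {
  cfg <- synth_config(n_frames = 40, frame_px = 240)
  d1 <- generate_dataset(cfg, n_videos = 2, seed = 5)
  d2 <- generate_dataset(cfg, n_videos = 2, seed = 5)
  expect_identical(d1$videos[[1]]$frames, d2$videos[[1]]$frames) # byte-identical
  expect_identical(d1$videos[[2]]$frames, d2$videos[[2]]$frames)
  expect_false(identical(d1$videos[[1]]$frames, d1$videos[[2]]$frames))
  d5 <- generate_dataset(cfg, n_videos = 5, seed = 6)
  expect_length(d5$manifest$scripts, 5)
  expect_length(d5$videos, 5)
})

test_that("realised scratch fraction stays in the calibrated band", {
  # defaults are tuned for ~2% scratch frames in the long run; over 10
  # script realisations the aggregate must stay within [1%, 4%]
  cfg <- synth_config(n_frames = 18000, frame_px = 240)
  set.seed(16)
  f <- replicate(10, {
    s <- script_behaviours(cfg)
    mean(scratchdetect:::script_frame_labels(s, cfg$n_frames, "scratch"))
  })
  expect_gt(mean(f), 0.01)
  expect_lt(mean(f), 0.04)
})

test_that("synthetic videos flow through the whole pipeline", {
  cfg <- synth_config(n_frames = 120, frame_px = 240, body_axes = c(30, 20),
                      scratch_amp = 10)
  vids <- synth_motion_dataset(cfg, n_videos = 1, seed = 21, crop_px = 120)
  expect_length(vids[[1]]$images$images, 119)
  ss <- build_dataset(vids, half_window = 5)
  expect_equal(nrow(ss$index), 119 - 10)
  # realised segment labels equal the script-derived frame labels
  expect_identical(ss$index$label, vids[[1]]$labels[ss$index$t + 1L])
  sp <- crnn_spec(input_px = 16, n_frames = 11, conv_filters = c(4, 4),
                  lstm_units = c(8, 8), fc_widths = c(8, 1))
  model <- crnn_build(sp, seed = 1)
  pr <- predict(model, ss, type = "prob")
  expect_equal(nrow(pr), nrow(ss$index))
  ev <- evaluate_tracks(threshold_track(data.frame(time = pr$t, prob = pr$prob)),
                        data.frame(time = ss$index$t, value = ss$index$label))
  expect_s3_class(ev, "scratch_eval")
})
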