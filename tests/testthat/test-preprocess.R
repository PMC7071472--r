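test_that("downsampling 2048 -> 256 Hz preserves duration and passband tones", {
  x <- sinusoid(10, amp = 1, rate = 2048, dur = 60)
  rec <- make_rec(x, rate = 2048)
  out <- resample_recording(rec, 256)
  expect_equal(nrow(out$data), 15360)       # 60 s x 256 Hz
  expect_equal(out$rate, 256)

  # the surviving tone matches the analytic sinusoid to < 1% amplitude error
  ref <- sinusoid(10, amp = 1, rate = 256, dur = 60)
  interior <- 256:(15360 - 256)
  err <- sqrt(mean((out$data[interior, "Fp1"] - ref[interior])^2))
  expect_lt(err / sqrt(mean(ref[interior]^2)), 0.01)

  expect_identical(resample_recording(rec, 2048), rec)
  expect_error(resample_recording(rec, 4096), "upsampling")
})

test_that("zero-phase band-pass keeps 10 Hz, kills 50 Hz and DC", {
  rec50 <- make_rec(sinusoid(50, amp = 1, rate = 256, dur = 10), rate = 256)
  out50 <- bandpass_recording(rec50, 0.5, 30)
  expect_lt(sqrt(mean(out50$data^2)) / sqrt(mean(rec50$data^2)), 0.10)

  rec10 <- make_rec(sinusoid(10, amp = 1, rate = 256, dur = 10), rate = 256)
  out10 <- bandpass_recording(rec10, 0.5, 30)
  mid <- 512:(2560 - 512)
  expect_equal(sqrt(mean(out10$data[mid, 1]^2)),
               sqrt(mean(rec10$data[mid, 1]^2)), tolerance = 0.05)

  # DC removal judged away from the filtfilt edge transients, whose decay
  # time is set by the 0.5 Hz corner
  recdc <- make_rec(rep(100, 256 * 30), rate = 256)
  outdc <- bandpass_recording(recdc, 0.5, 30)
  interior <- (5 * 256):(25 * 256)
  expect_lt(abs(mean(outdc$data[interior, 1])), 1)

  expect_error(bandpass_recording(rec10, 30, 0.5), "band edges")
  expect_error(bandpass_recording(rec10, 0.5, 200), "band edges")
})

test_that("sliding-window segmentation enumerates half-open windows", {
  rec60 <- make_rec(rnorm(256 * 60), rate = 256)
  s <- segment_recording(rec60, 1, 0.5)
  expect_equal(length(s$starts), 119)       # floor((60-1)/0.5) + 1
  expect_true(all(s$valid))

  s1 <- segment_recording(make_rec(rnorm(256), rate = 256))
  expect_equal(s1$starts, 0)

  s2 <- segment_recording(make_rec(rnorm(round(256 * 1.6)), rate = 256))
  expect_equal(s2$starts, c(0, 0.5))        # trailing 0.1 s discarded

  expect_error(segment_recording(make_rec(rnorm(100), rate = 256)),
               "shorter than the window")
})

test_that("blink detection flags injected blinks and stays quiet on clean data", {
  cfg <- tiny_config(seed = 31, dur = 60, blink_rate = 0)
  clean <- generate_participant(cfg, 0)$recordings$resting
  prep <- bandpass_recording(resample_recording(clean, 256), 0.5, 30)
  expect_equal(nrow(detect_blinks(prep)), 0)

  withblinks <- inject_blinks(clean, 10, seed = 7)
  prep2 <- bandpass_recording(resample_recording(withblinks, 256), 0.5, 30)
  det <- detect_blinks(prep2)
  ann <- withblinks$annotations
  n_true <- nrow(ann)
  overlaps <- vapply(seq_len(n_true), function(i) {
    any(det$start_s < ann$end_s[i] & det$end_s > ann$start_s[i])
  }, TRUE)
  expect_gte(sum(overlaps), n_true - 1)
  n_false <- sum(vapply(seq_len(nrow(det)), function(j) {
    !any(det$start_s[j] < ann$end_s & det$end_s[j] > ann$start_s)
  }, TRUE))
  expect_lte(n_false, 1)
  if (nrow(det) > 1) {
    expect_true(all(det$start_s[-1] >= det$end_s[-nrow(det)]))
  }
})

test_that("segment rejection follows interval intersection and is idempotent", {
  rec <- make_rec(rnorm(256 * 2), rate = 256)
  s <- segment_recording(rec)           # starts 0, 0.5, 1.0
  expect_identical(reject_segments(s, NULL)$valid, s$valid)
  expect_identical(
    reject_segments(s, data.frame(start_s = numeric(), end_s = numeric()))$valid,
    s$valid)

  hit <- reject_segments(s, data.frame(start_s = 0.25, end_s = 0.30))
  expect_identical(hit$valid, c(FALSE, TRUE, TRUE))
  expect_identical(reject_segments(hit, data.frame(start_s = 0.25,
                                                   end_s = 0.30))$valid,
                   hit$valid)

  all_gone <- reject_segments(s, data.frame(start_s = 0, end_s = 2))
  expect_false(any(all_gone$valid))
  expect_error(feature_series(all_gone, "FAA"), "valid segments")
})

test_that("LMS removes a stationary EOG mixture and passes through on zero references", {
  art <- experiment_artifacts(n_recordings = 0, n_clean = 0, seed = 7)
  expect_lt(art$lms_corr, 0.1)
  expect_lt(art$lms_distortion_ratio, 0.2)

  x <- rnorm(512)
  rec0 <- make_rec(x, x, rate = 256,
                   eog = list(EOG1 = rep(0, 512), EOG2 = rep(0, 512)))
  out0 <- lms_remove_eog(rec0)
  expect_identical(out0$data[, "Fp1"], rec0$data[, "Fp1"])

  expect_error(lms_remove_eog(rec0, eog_channels = "EOGX"), "available")
})

test_that("the preprocessing pipeline removes blink-contaminated samples", {
  art <- experiment_artifacts(n_recordings = 3, n_clean = 0, seed = 3)
  expect_gte(art$blink_sample_removal, 0.95)
})
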