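test_that("generation is deterministic given (config, index) and varies with seed", {
  cfg <- tiny_config(seed = 5)
  a <- generate_participant(cfg, 0)
  b <- generate_participant(cfg, 0)
  expect_identical(a$recordings$resting$data, b$recordings$resting$data)
  expect_identical(a$truth, b$truth)
  other <- generate_participant(tiny_config(seed = 6), 0)
  expect_false(identical(a$recordings$resting$data,
                         other$recordings$resting$data))
})

test_that("zero modulation depth yields zero truth dynamic range", {
  bp <- default_band_profile()
  bp$depth_lo <- bp$depth_hi <- 0
  cfg <- tiny_config(seed = 2, band_profile = bp, asym_depth = c(0, 0))
  p <- generate_participant(cfg, 0)
  expect_true(all(abs(p$truth$iqr$iqr) < 1e-12))
})

test_that("constant interhemispheric alpha offset gives constant truth FAA", {
  bp <- default_band_profile()
  bp$depth_lo <- bp$depth_hi <- 0
  # alpha amplitude at Fp1 = e^0.5 x Fp2  =>  FAA = ln(a1^2/a2^2) = 1
  cfg <- tiny_config(seed = 3, band_profile = bp, asym_depth = c(0, 0),
                     asym_offset = 0.5)
  p <- generate_participant(cfg, 0)
  faa_truth <- p$truth$series$value[p$truth$series$feature == "FAA"]
  expect_equal(faa_truth, rep(1, length(faa_truth)), tolerance = 1e-12)
})

test_that("invalid configurations name the offending field", {
  expect_error(cohort_config(n_participants = 2), "n_participants")
  expect_error(cohort_config(resting_duration = -1), "resting_duration")
  expect_error(cohort_config(task_durations = c(napping = 60)),
               "task_durations")
  expect_error(cohort_config(blink_rate = -1), "blink_rate")
  expect_error(
    cohort_config(link_spec = list(FAA = list(predictor = "IQR-Nope",
                                              coefficient = 1,
                                              noise_sd = 0))),
    "valid names")
  cfg <- tiny_config()
  expect_error(generate_participant(cfg, 5), "participant_index")
})

test_that("the link ties task dynamic ranges to the designated resting predictor", {
  pred <- "IQR-Asym-Alpha-8-12"
  # zero coefficient, zero noise: every participant shares the same target
  cfg0 <- cohort_config(n_participants = 4, resting_duration = 20,
                        task_durations = NULL, sessions = "resting",
                        eog = FALSE, seed = 4,
                        link_spec = list(FAA = list(predictor = pred,
                                                    coefficient = 0,
                                                    noise_sd = 0)))
  coh0 <- generate_cohort(cfg0)
  tgt0 <- coh0$truth_iqr$target_iqr[coh0$truth_iqr$feature == "FAA"]
  expect_equal(length(unique(tgt0)), 1)

  # unit coefficient, near-zero noise: target tracks the measured predictor
  cfg1 <- cohort_config(n_participants = 12, resting_duration = 30,
                        task_durations = NULL, sessions = "resting",
                        eog = FALSE, seed = 4,
                        link_spec = list(FAA = list(predictor = pred,
                                                    coefficient = 1,
                                                    noise_sd = 0.01)))
  coh1 <- generate_cohort(cfg1)
  tgt1 <- coh1$truth_iqr$target_iqr[coh1$truth_iqr$feature == "FAA"]
  expect_gt(cor(coh1$measured_predictors[, pred], tgt1), 0.9)

  # different seeds give different ground-truth tables
  coh2 <- generate_cohort(cohort_config(
    n_participants = 4, resting_duration = 20, task_durations = NULL,
    sessions = "resting", eog = FALSE, seed = 5,
    link_spec = cfg0$link_spec))
  expect_false(identical(coh0$truth_iqr$true_iqr, coh2$truth_iqr$true_iqr))
})

test_that("with vanishing link noise the predictor explains the target exactly", {
  pred <- "IQR-Asym-Alpha-8-12"
  cfg <- cohort_config(n_participants = 8, resting_duration = 20,
                       task_durations = NULL, sessions = "resting",
                       eog = FALSE, seed = 11,
                       link_spec = list(FAA = list(predictor = pred,
                                                   coefficient = 1.3,
                                                   noise_sd = 0)))
  coh <- generate_cohort(cfg)
  tgt <- coh$truth_iqr$target_iqr[coh$truth_iqr$feature == "FAA"]
  fit <- lm(tgt ~ coh$measured_predictors[, pred])
  # summary.lm warns that the fit is essentially perfect — which is the point
  r2 <- suppressWarnings(summary(fit)$r.squared)
  expect_gt(r2, 1 - 1e-10)
})

test_that("blink injection is Poisson, in-bounds, and absent at rate zero", {
  cfg <- tiny_config(seed = 8, dur = 60, blink_rate = 0)  # start clean
  p <- generate_participant(cfg, 0)
  rec <- p$recordings$resting
  expect_identical(inject_blinks(rec, 0, seed = 1), rec)
  expect_error(inject_blinks(rec, -2, seed = 1), ">= 0")

  counts <- vapply(1:100, function(s) {
    out <- inject_blinks(rec, 12, seed = s)
    sum(out$annotations$label == "blink")
  }, 1L)
  total <- sum(counts)
  # total ~ Poisson(1200); central 99% interval
  expect_gt(total, qpois(0.005, 1200))
  expect_lt(total, qpois(0.995, 1200))
  out <- inject_blinks(rec, 12, seed = 3)
  ann <- out$annotations[out$annotations$label == "blink", ]
  expect_true(all(ann$start_s >= 0 & ann$end_s <= duration(rec)))
})

test_that("an alpha-only participant concentrates 2-18 Hz power in 8-12 Hz", {
  bp <- default_band_profile()
  bp$rms_uv <- c(1e-4, 1e-4, 10, 1e-4, 1e-4)
  cfg <- tiny_config(seed = 3, dur = 30, band_profile = bp,
                     background_rms = 0, blink_rate = 0)
  p <- generate_participant(cfg, 0)
  x <- p$recordings$resting$data[, "Fp1"]
  frac <- band_power(x, "alpha3", cfg$native_rate) /
    band_power(x, "total", cfg$native_rate)
  expect_gt(frac, 0.9)
})

test_that("stored truth IQRs equal the IQR of the stored truth series", {
  p <- generate_participant(tiny_config(seed = 12), 1)
  for (r in seq_len(nrow(p$truth$iqr))) {
    sel <- p$truth$series$session == p$truth$iqr$session[r] &
      p$truth$series$feature == p$truth$iqr$feature[r]
    expect_identical(iqr(p$truth$series$value[sel]), p$truth$iqr$iqr[r])
  }
})

test_that("cohorts round-trip through the delimited on-disk format", {
  cfg <- cohort_config(n_participants = 3, resting_duration = 10,
                       task_durations = c(valence = 10),
                       sessions = c("resting", "valence"),
                       link_spec = NULL, seed = 21)
  coh <- generate_cohort(cfg)
  dir <- withr::local_tempdir()
  write_cohort(coh, dir)
  rec <- read_recording(file.path(dir, "P001_resting.tsv"))
  orig <- coh$participants[[1]]$recordings$resting
  expect_equal(rec$rate, orig$rate)
  expect_identical(rec$channels, orig$channels)
  expect_identical(rec$roles, orig$roles)
  expect_equal(rec$data, orig$data, tolerance = 1e-6)
  expect_equal(rec$annotations$start_s, orig$annotations$start_s,
               tolerance = 1e-6)
})
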