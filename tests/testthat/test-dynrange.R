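test_that("iqr follows the linear-interpolation quantile convention", {
  expect_equal(iqr(c(1, 2, 3, 4)), 1.5)
  expect_identical(iqr(rep(2.2, 10)), 0)
  expect_error(iqr(c(1, 2, 3)), "at least 4")
  expect_error(iqr(c(1, 2, NA, 4)), "finite")

  set.seed(20)
  x <- rnorm(50)
  expect_equal(iqr(x + 5), iqr(x))
  expect_equal(iqr(-3 * x), 3 * iqr(x))
})

test_that("iqr agrees with a sort-based quantile oracle", {
  set.seed(21)
  for (k in 1:250) {
    n <- sample(4:60, 1)
    x <- rnorm(n) * 10^sample(-3:3, 1)
    expect_equal(iqr(x), iqr_oracle(x), tolerance = 1e-12)
  }
})

test_that("dynamic ranges reproduce the generator truth exactly", {
  p <- generate_participant(tiny_config(seed = 30), 0)
  tr <- p$truth$series
  tr$participant <- p$participant
  dr <- dynamic_ranges(tr, include_resting = c(FAA = TRUE, rFTP = TRUE,
                                               rFLBP = TRUE))
  for (r in seq_len(nrow(dr))) {
    truth <- p$truth$iqr$iqr[p$truth$iqr$feature == dr$feature[r]]
    expect_identical(dr$iqr[r], truth)
  }
})

test_that("deeper amplitude modulation gives larger estimated dynamic ranges", {
  deltas <- vapply(1:20, function(s) {
    est_iqr <- function(depth) {
      bp <- default_band_profile()
      bp$depth_lo <- bp$depth_hi <- depth
      cfg <- tiny_config(seed = 400 + s, dur = 30, band_profile = bp,
                         asym_depth = c(0, 0), blink_rate = 0)
      p <- generate_participant(cfg, 0)
      ss <- preprocess_recording(p$recordings$resting, "resting")
      fs <- feature_series(ss, "rFTP")
      iqr(fs$value)
    }
    est_iqr(0.5) - est_iqr(0.25)
  }, 1)
  expect_gt(mean(deltas), 0)
  expect_gte(sum(deltas > 0), 15)
})

test_that("dynamic_ranges is order-invariant and omits short groups with a message", {
  set.seed(22)
  mk <- function(id, feat, n) {
    data.frame(participant = id, session = "valence", feature = feat,
               value = rnorm(n))
  }
  tab <- rbind(mk("P2", "FAA", 30), mk("P1", "FAA", 30), mk("P1", "rFTP", 3))
  expect_message(dr <- dynamic_ranges(tab), "omitting")
  expect_equal(dr$participant, c("P1", "P2"))
  expect_false("rFTP" %in% dr$feature)

  shuffled <- tab[sample(nrow(tab)), ]
  expect_message(dr2 <- dynamic_ranges(shuffled), "omitting")
  expect_equal(dr, dr2)
})

test_that("resting segments join the pool only for the relative-power features", {
  set.seed(23)
  base <- data.frame(participant = "P1", session = "valence",
                     feature = "FAA", value = rnorm(20))
  rest <- data.frame(participant = "P1", session = "resting",
                     feature = "FAA", value = rnorm(20) + 10)
  dr_task <- dynamic_ranges(rbind(base, rest))
  expect_equal(dr_task$n_segments, 20)   # resting excluded for FAA by default
  dr_all <- dynamic_ranges(rbind(base, rest),
                           include_resting = c(FAA = TRUE, rFTP = TRUE,
                                               rFLBP = TRUE))
  expect_equal(dr_all$n_segments, 40)
})
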