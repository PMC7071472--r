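test_that("band power matches the Parseval oracle on bin-centered sinusoids", {
  expect_identical(band_power(rep(0, 256), "alpha2", 256), 0)

  x <- sinusoid(10, amp = 2, rate = 256, dur = 1)
  expect_equal(band_power(x, "alpha2", 256), 2, tolerance = 0.05)  # A^2/2
  expect_lt(band_power(x, "delta", 256), 0.01 * band_power(x, "alpha2", 256))

  # Parseval: total across all frequencies equals the mean square
  expect_equal(band_power(x, c(0, 128), 256) +
                 sum(Mod(fft(x))[c(1, 129)]^2) / (256^2),
               mean(x^2), tolerance = 1e-10)

  expect_error(band_power(x, c(100, 200), 256), "Nyquist")
})

test_that("relative power is a proper fraction and the band partition tiles the total", {
  x <- sinusoid(10, amp = 3, rate = 256, dur = 1)
  expect_identical(relative_power(x, "total", 256), 1)
  expect_gt(relative_power(x, "alpha3", 256), 0.95)

  set.seed(42)
  parts <- replicate(100, {
    z <- rnorm(256)
    sum(vapply(partition_bands()$name, function(b) {
      relative_power(z, b, 256)
    }, 1))
  })
  expect_equal(mean(parts), 1, tolerance = 0.02)

  expect_error(relative_power(rep(0, 256), "theta", 256), "degenerate")
})

test_that("asymmetry is the log power ratio and antisymmetric", {
  expect_identical(asymmetry(3.7, 3.7), 0)
  expect_equal(asymmetry(exp(1) * 2, 2), 1)
  set.seed(1)
  p1 <- rexp(50); p2 <- rexp(50)
  expect_equal(asymmetry(p1, p2), -asymmetry(p2, p1))
  expect_error(asymmetry(0, 1), "positive")
})

test_that("FAA equals alpha2 band-power asymmetry and scales as amplitude^2", {
  x <- sinusoid(11, amp = 1, rate = 256, dur = 1)
  expect_identical(faa(x, x, 256), 0)
  expect_equal(faa(sqrt(exp(1)) * x, x, 256), 1, tolerance = 0.05)
  y <- sinusoid(11, amp = 0.7, rate = 256, dur = 1, phase = 1)
  expect_identical(faa(x, y, 256),
                   asymmetry(band_power(x, "alpha2", 256),
                             band_power(y, "alpha2", 256)))
})

test_that("gain invariances: power ~ c^2, relative/asymmetry/FAA unchanged", {
  set.seed(3)
  x <- rnorm(256); y <- rnorm(256)
  c0 <- 3.7
  expect_equal(band_power(c0 * x, "theta", 256),
               c0^2 * band_power(x, "theta", 256))
  expect_equal(relative_power(c0 * x, "theta", 256),
               relative_power(x, "theta", 256))
  expect_equal(faa(c0 * x, c0 * y, 256), faa(x, y, 256))
})

test_that("feature series cover valid segments and match pure-tone expectations", {
  x <- rnorm(256 * 10)
  s <- segment_recording(make_rec(x, x, rate = 256))
  fs <- feature_series(s, "FAA")
  expect_equal(fs$value, rep(0, 19))

  theta_rec <- make_rec(sinusoid(6, amp = 5, rate = 256, dur = 10), rate = 256)
  ft <- feature_series(segment_recording(theta_rec), "rFTP")
  expect_true(all(ft$value > 0.95))

  s2 <- reject_segments(s, data.frame(start_s = 0, end_s = 2))
  expect_equal(nrow(feature_series(s2, "rFLBP")), sum(s2$valid))
})
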