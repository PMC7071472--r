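test_that("canonical predictor names follow the published dialect", {
  expect_identical(predictor_name("IQR", "Asym", NULL, "alpha3"),
                   "IQR-Asym-Alpha-8-12")
  expect_identical(predictor_name("IQR", "Rel", "Fp1", "theta"),
                   "IQR-Rel-Fp1-Theta-4-8")
  expect_identical(predictor_name("IQR", "Asym", NA, "total"),
                   "IQR-Asym-total")
  expect_error(predictor_name("IQR", "Asym", "Fp1", "theta"), "no channel")
  expect_error(predictor_name("Mean", "Abs", NULL, "theta"), "require")
  expect_error(predictor_name("Mean", "Abs", "Fp1", "sigma"), "unknown band")
})

test_that("the vocabulary has exactly 112 unique names in fixed order", {
  vocab <- predictor_vocabulary()
  expect_equal(nrow(vocab), 112)
  expect_equal(anyDuplicated(vocab$name), 0)
  expect_identical(vocab, predictor_vocabulary())   # stable across calls
  expect_equal(sum(vocab$kind == "Asym"), 16)
})

test_that("extraction yields 112 finite predictors with the degenerate full-band values", {
  set.seed(10)
  s <- segment_recording(make_rec(rnorm(256 * 10), rnorm(256 * 10)))
  pv <- extract_candidate_predictors(s)
  expect_equal(length(pv), 112)
  expect_identical(names(pv), predictor_vocabulary()$name)
  expect_true(all(is.finite(pv)))
  for (ch in c("Fp1", "Fp2", "Fp12")) {
    expect_equal(pv[[paste0("Mean-Rel-", ch, "-total")]], 1)
    expect_equal(pv[[paste0("IQR-Rel-", ch, "-total")]], 0)
  }
})

test_that("channel-identical input zeroes every asymmetry predictor", {
  x <- rnorm(256 * 6)
  pv <- extract_candidate_predictors(segment_recording(make_rec(x, x)))
  asym <- pv[grepl("-Asym-", names(pv))]
  expect_equal(length(asym), 16)
  expect_equal(unname(asym), rep(0, 16))
})

test_that("predictors respect gain invariance classes and recompute identically", {
  set.seed(11)
  x1 <- rnorm(256 * 8); x2 <- rnorm(256 * 8)
  s1 <- segment_recording(make_rec(x1, x2))
  s2 <- segment_recording(make_rec(2.5 * x1, 2.5 * x2))
  p1 <- extract_candidate_predictors(s1)
  p2 <- extract_candidate_predictors(s2)
  kinds <- predictor_vocabulary()$kind
  expect_equal(p2[kinds == "Rel"], p1[kinds == "Rel"])
  expect_equal(p2[kinds == "Asym"], p1[kinds == "Asym"])
  expect_equal(unname(p2[kinds == "Abs"]), unname(2.5^2 * p1[kinds == "Abs"]))
  expect_identical(p1, extract_candidate_predictors(s1))
})

test_that("too few valid segments is an error", {
  s <- segment_recording(make_rec(rnorm(256 * 2)))   # 3 segments
  expect_error(extract_candidate_predictors(s), "at least 4")
})

test_that("predictor tables round-trip losslessly with vocabulary validation", {
  set.seed(12)
  X <- matrix(rnorm(2 * 112), 2, 112,
              dimnames = list(c("P001", "P002"), predictor_vocabulary()$name))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_predictors(X, path)
  X2 <- read_predictors(path)
  expect_equal(X2, X, tolerance = 1e-12)
  bad <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
  bad$`IQR-Asym-total` <- NULL
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write.table(bad, path2, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_predictors(path2), "missing")
})
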