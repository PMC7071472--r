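test_that("nrmse matches direct arithmetic and its invariances", {
  expect_identical(nrmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(nrmse(c(0, 2), c(1, 1)), 0.5)
  set.seed(40)
  a <- rnorm(30); p <- rnorm(30)
  direct <- sqrt(mean((a - p)^2)) / (max(a) - min(a))
  expect_equal(nrmse(a, p), direct, tolerance = 1e-15)
  expect_equal(nrmse(3 * a, 3 * p), nrmse(a, p))
  expect_error(nrmse(a, p[-1]), "equal length")
  expect_error(nrmse(rep(1, 5), rnorm(5)), "zero range")
})

test_that("FSFS finds an exactly-predictive column first and decreases its criterion", {
  set.seed(41)
  X <- matrix(rnorm(20 * 10), 20, 10,
              dimnames = list(NULL, sprintf("pred%02d", 1:10)))
  y <- X[, "pred07"]
  sel <- fsfs(X, y, model_spec("MLR"))
  expect_identical(sel[1], "pred07")
  crit <- attr(sel, "criterion")
  expect_lt(crit[2], 1e-10)

  # the optional inner leave-one-out criterion also finds the exact column
  sel_loo <- fsfs(X, y, model_spec("MLR"), criterion = "inner_loo",
                  max_predictors = 2)
  expect_identical(sel_loo[1], "pred07")

  y2 <- rnorm(20)
  sel2 <- fsfs(X, y2, model_spec("MLR"), max_predictors = 5)
  crit2 <- attr(sel2, "criterion")
  expect_true(all(diff(crit2) < 0))
  expect_lte(length(sel2), 5)

  expect_error(fsfs(X, rep(1, 20), model_spec("MLR")), "zero range")
  expect_error(fsfs(X[1:3, ], y[1:3], model_spec("MLR")), "at least 4")
})

test_that("LOOCV with the mean-model baseline equals a hand-rolled LOO oracle", {
  set.seed(42)
  X <- matrix(rnorm(12 * 112), 12, 112,
              dimnames = list(sprintf("P%03d", 1:12),
                              predictor_vocabulary()$name))
  y <- rnorm(12)
  res <- loocv(X, y, model_spec("Baseline", predictors = character(0)),
               use_fsfs = FALSE)
  expect_equal(nrow(res$per_participant), 12)
  oracle_pred <- vapply(1:12, function(i) mean(y[-i]), 1)
  expect_equal(res$per_participant$predicted, oracle_pred, tolerance = 1e-12)
  expect_equal(res$nrmse, nrmse(y, oracle_pred), tolerance = 1e-12)
})

test_that("each fold's model is fit strictly outside the held-out participant", {
  set.seed(43)
  X <- matrix(rnorm(10 * 6), 10, 6, dimnames = list(NULL, paste0("c", 1:6)))
  y <- X[, 1] + rnorm(10, sd = 0.1)
  res <- loocv(X, y, model_spec("MLR"), use_fsfs = FALSE)
  # oracle: refit every fold independently of the loocv internals (no shared
  # standardization or selection state can survive this comparison)
  for (i in seq_len(10)) {
    ref <- fit_predict(model_spec("MLR"), X[-i, , drop = FALSE], y[-i],
                       X[i, , drop = FALSE])
    expect_equal(res$per_participant$predicted[i], ref, tolerance = 1e-12)
  }
  # and the held-out row's own values only matter at prediction time:
  # scaling row i cannot change what the fold-i model learned
  X2 <- X
  X2[4, ] <- X[4, ] * 100
  res2 <- loocv(X2, y, model_spec("MLR"), use_fsfs = FALSE)
  ref4 <- fit_predict(model_spec("MLR"), X[-4, , drop = FALSE], y[-4],
                      X2[4, , drop = FALSE])
  expect_equal(res2$per_participant$predicted[4], ref4, tolerance = 1e-12)
})

test_that("FSFS-selected models beat the mean baseline on recoverable signal", {
  wins <- vapply(1:20, function(s) {
    set.seed(500 + s)
    n <- 14
    X <- matrix(rnorm(n * 112), n, 112,
                dimnames = list(NULL, predictor_vocabulary()$name))
    y <- X[, 5] + rnorm(n, sd = 0.05 * sd(X[, 5]))
    svm_res <- loocv(X, y, model_spec("SVMR"), use_fsfs = TRUE,
                     max_predictors = 1, seed = s)
    base <- loocv(X, y, model_spec("Baseline", predictors = character(0)),
                  use_fsfs = FALSE, seed = s)
    svm_res$nrmse < base$nrmse
  }, TRUE)
  expect_gte(sum(wins), 11)   # majority over 20 seeds
})

test_that("the model registry honours its contracts", {
  set.seed(44)
  n <- 15
  X <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- drop(X %*% c(1, -2, 0.5)) + rnorm(n, sd = 0.1)

  # MLR reproduces the normal-equations oracle
  pred <- fit_predict(model_spec("MLR"), X, y, X)
  Xc <- cbind(1, scale(X))
  beta <- solve(t(Xc) %*% Xc, t(Xc) %*% y)
  expect_equal(pred, drop(Xc %*% beta), tolerance = 1e-8)

  # depth-0 tree predicts the training mean
  expect_equal(fit_predict(model_spec("TR", maxdepth = 0), X, y, X),
               rep(mean(y), n))

  # GPR interpolates noise-free linear targets on the training points
  ylin <- drop(X %*% c(1, 2, -1))
  gpred <- fit_predict(model_spec("GPR"), X, ylin, X)
  expect_equal(gpred, ylin, tolerance = 1e-3)

  # stochastic fitters are deterministic given the seed
  e1 <- fit_predict(model_spec("ebTR"), X, y, X, seed = 7)
  e2 <- fit_predict(model_spec("ebTR"), X, y, X, seed = 7)
  expect_identical(e1, e2)
  expect_false(identical(e1, fit_predict(model_spec("ebTR"), X, y, X,
                                         seed = 8)))

  # kSVMR and SVMR run and return one prediction per test row
  expect_length(fit_predict(model_spec("kSVMR"), X, y, X[1:3, , drop = FALSE]),
                3)
  expect_error(fit_predict(model_spec("MLR"), X, y, X[, 1:2]), "match")
  fake <- structure(list(family = "XGB", hyperparameters = list()),
                    class = "model_spec")
  expect_error(fit_predict(fake, X, y, X), "unknown model family")
})

test_that("the paired permutation test is one-tailed, smoothed, and reproducible", {
  set.seed(45)
  a <- rexp(20)
  expect_gte(paired_permutation_test(a, a, n_perm = 200, seed = 1), 0.5)
  b <- a * 0.2     # clearly smaller errors
  p1 <- paired_permutation_test(a, b, n_perm = 2000, seed = 2)
  expect_lt(p1, 0.05)
  expect_identical(p1, paired_permutation_test(a, b, n_perm = 2000, seed = 2))
  expect_gt(p1, 0)   # add-one smoothing keeps p strictly positive
  expect_error(paired_permutation_test(a, b[-1]), "equal length")
})
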