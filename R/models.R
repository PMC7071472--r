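#' Specify a regression model family
#'
#' Registry of the model families compared in the evaluation: multiple linear
#' regression (MLR), tree regression (TR), ensemble bagged tree regression
#' (ebTR), linear and radial-kernel support vector machine regression
#' (SVMR / kSVMR), Gaussian process regression (GPR), and a Baseline that
#' fits MLR on a fixed predictor set without feature selection. All families
#' standardize predictors using training-fold statistics only and are
#' deterministic given a seed. Hyperparameters are documented package
#' defaults and can be overridden via `...`.
#'
#' @param family one of `"MLR"`, `"TR"`, `"ebTR"`, `"SVMR"`, `"kSVMR"`,
#'   `"GPR"`, `"Baseline"`.
#' @param ... hyperparameter overrides. TR: `minsplit` (5), `cp` (0.01),
#'   `maxdepth` (5; 0 predicts the training mean). ebTR: `ntree` (50),
#'   `minsplit` (5). SVMR/kSVMR: `cost` (1), `epsilon` (0.1), and for kSVMR
#'   `gamma` (1/p). GPR: `sigma` (RBF inverse width, 1/p), `var` (noise
#'   variance, 1e-4). Baseline: `predictors` (character vector of fixed
#'   predictor names; empty means intercept-only, i.e. the training mean).
#' @return list of class `model_spec` with `family` and `hyperparameters`.
#' @export
model_spec <- function(family = c("MLR", "TR", "ebTR", "SVMR", "kSVMR",
                                  "GPR", "Baseline"), ...) {
  family <- match.arg(family)
  defaults <- switch(family,
    MLR = list(),
    TR = list(minsplit = 5, cp = 0.01, maxdepth = 5),
    ebTR = list(ntree = 50, minsplit = 5),
    SVMR = list(cost = 1, epsilon = 0.1),
    kSVMR = list(cost = 1, epsilon = 0.1, gamma = NULL),
    GPR = list(sigma = NULL, var = 1e-4),
    Baseline = list(predictors = character(0))
  )
  hp <- utils::modifyList(defaults, list(...))
  structure(list(family = family, hyperparameters = hp),
            class = "model_spec")
}

#' Fit a model on training data and predict on test data
#'
#' Predictors are standardized (center/scale) with training-fold statistics;
#' zero-variance columns are left centered only. With zero predictor columns
#' every family degenerates to predicting the training mean. Stochastic
#' fitters (ebTR) draw their randomness from `seed` through a private
#' substream, so repeated calls are bit-identical.
#'
#' @param model a [model_spec()].
#' @param X_train,X_test numeric matrices with matching column names.
#' @param y_train numeric response vector.
#' @param seed integer seed for stochastic fitters.
#' @return numeric predictions, one per test row.
#' @export
fit_predict <- function(model, X_train, y_train, X_test, seed = 0L) {
  stopifnot(inherits(model, "model_spec"))
  X_train <- as.matrix(X_train)
  X_test <- as.matrix(X_test)
  if (ncol(X_train) != ncol(X_test) ||
      !identical(colnames(X_train), colnames(X_test))) {
    stop("X_test columns must match X_train", call. = FALSE)
  }
  hp <- model$hyperparameters
  family <- model$family
  if (family == "Baseline") {
    sel <- hp$predictors
    missing_cols <- setdiff(sel, colnames(X_train))
    if (length(missing_cols) > 0) {
      stop("Baseline predictors not in X: ",
           paste(missing_cols, collapse = ", "), call. = FALSE)
    }
    X_train <- X_train[, sel, drop = FALSE]
    X_test <- X_test[, sel, drop = FALSE]
    family <- "MLR"
  }
  if (ncol(X_train) == 0 || (family == "TR" && identical(hp$maxdepth, 0))) {
    return(rep(mean(y_train), nrow(X_test)))
  }
  n_tr <- nrow(X_train)
  mu <- colMeans(X_train)
  sdev <- sqrt(pmax(colSums(X_train^2) - n_tr * mu^2, 0) / (n_tr - 1))
  sdev[sdev < 1e-12] <- 1
  std <- function(m) {
    (m - matrix(mu, nrow(m), length(mu), byrow = TRUE)) /
      matrix(sdev, nrow(m), length(sdev), byrow = TRUE)
  }
  Xs <- std(X_train)
  Xt <- std(X_test)
  p <- ncol(Xs)
  # response standardized for the scale-sensitive fitters (epsilon tube, GP
  # noise variance); predictions mapped back
  my <- mean(y_train)
  sy <- stats::sd(y_train)
  if (!is.finite(sy) || sy < 1e-12) return(rep(my, nrow(X_test)))
  ys <- (y_train - my) / sy

  switch(family,
    MLR = {
      fit <- stats::lm.fit(cbind(1, Xs), y_train)
      beta <- fit$coefficients
      beta[is.na(beta)] <- 0
      drop(cbind(1, Xt) %*% beta)
    },
    TR = {
      df_tr <- data.frame(y = y_train, Xs, check.names = TRUE)
      df_te <- data.frame(Xt, check.names = TRUE)
      names(df_te) <- names(df_tr)[-1]
      fit <- rpart::rpart(y ~ ., data = df_tr, method = "anova",
                          control = rpart::rpart.control(
                            minsplit = hp$minsplit, cp = hp$cp,
                            maxdepth = max(hp$maxdepth, 1), xval = 0))
      unname(stats::predict(fit, df_te))
    },
    ebTR = {
      with_substream(as.integer(seed), 1L, {
        fit <- randomForest::randomForest(
          x = Xs, y = y_train, ntree = hp$ntree, mtry = p,
          nodesize = hp$minsplit, replace = TRUE)
        unname(stats::predict(fit, Xt))
      })
    },
    SVMR = {
      fit <- e1071::svm(x = Xs, y = ys, type = "eps-regression",
                        kernel = "linear", cost = hp$cost,
                        epsilon = hp$epsilon, scale = FALSE)
      if (fit$tot.nSV == 0) return(rep(my, nrow(Xt)))
      my + sy * unname(stats::predict(fit, Xt))
    },
    kSVMR = {
      fit <- e1071::svm(x = Xs, y = ys, type = "eps-regression",
                        kernel = "radial", cost = hp$cost,
                        epsilon = hp$epsilon,
                        gamma = hp$gamma %||% (1 / p), scale = FALSE)
      if (fit$tot.nSV == 0) return(rep(my, nrow(Xt)))
      my + sy * unname(stats::predict(fit, Xt))
    },
    GPR = {
      # posterior mean with an RBF kernel, computed directly so the noise
      # variance can sit below the floor kernlab::gausspr() imposes
      kern <- kernlab::rbfdot(sigma = hp$sigma %||% (1 / p))
      K <- kernlab::kernelMatrix(kern, Xs)@.Data
      Kt <- kernlab::kernelMatrix(kern, Xt, Xs)@.Data
      alpha <- solve(K + hp$var * diag(nrow(K)), ys)
      my + sy * drop(Kt %*% alpha)
    },
    stop("unknown model family '", family, "'", call. = FALSE)
  )
}
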