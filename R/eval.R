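#' Normalized root-mean-square error
#'
#' RMSE divided by the range (max - min) of the actual values; a value of
#' 0.15 means the typical prediction error is 15% of the span of the actual
#' dynamic ranges. Invariant to common rescaling of both vectors.
#'
#' @param actual,predicted numeric vectors of equal length (>= 2).
#' @return nonnegative scalar.
#' @examples
#' nrmse(c(0, 2), c(1, 1))  # 0.5
#' @export
nrmse <- function(actual, predicted) {
  if (length(actual) != length(predicted)) {
    stop("actual and predicted must have equal length", call. = FALSE)
  }
  if (length(actual) < 2) stop("need at least 2 values", call. = FALSE)
  rng <- max(actual) - min(actual)
  if (rng <= 0) {
    stop("actual values have zero range; nRMSE undefined", call. = FALSE)
  }
  sqrt(mean((actual - predicted)^2)) / rng
}

#' Forward sequential feature selection (FSFS)
#'
#' Greedy forward selection from the empty set: at each round every remaining
#' candidate is tried, the one minimizing the selection criterion is taken,
#' and it is added only if it strictly reduces the current criterion;
#' otherwise selection stops. The default criterion is the training-set fit
#' nRMSE (the model is fit on the training fold and evaluated on that same
#' fold); an inner leave-one-out criterion is available behind
#' `criterion = "inner_loo"` but is not the default. The initial criterion
#' is the nRMSE of predicting the training mean. Ties are broken by
#' canonical predictor order (column order of `X_train`).
#'
#' @param X_train predictor matrix (participants x predictors).
#' @param y_train response vector (must have nonzero range).
#' @param model a [model_spec()] used to score candidate sets.
#' @param max_predictors optional cap on the selected-set size
#'   (default unlimited; selection normally self-terminates).
#' @param criterion `"train"` (training-fold fit nRMSE, default) or
#'   `"inner_loo"` (leave-one-out nRMSE within the training fold; much more
#'   expensive).
#' @param seed seed forwarded to stochastic fitters.
#' @return character vector of selected predictor names in selection order
#'   (possibly empty), with the criterion sequence (initial criterion
#'   followed by the criterion after each addition) attached as attribute
#'   `"criterion"`.
#' @export
fsfs <- function(X_train, y_train, model, max_predictors = Inf,
                 criterion = c("train", "inner_loo"), seed = 0L) {
  criterion <- match.arg(criterion)
  X_train <- as.matrix(X_train)
  n_tr <- nrow(X_train)
  if (n_tr < 4) {
    stop("FSFS requires at least 4 training participants", call. = FALSE)
  }
  if (max(y_train) - min(y_train) <= 0) {
    stop("degenerate response: zero range", call. = FALSE)
  }
  score_cols <- function(cols) {
    Xc <- X_train[, cols, drop = FALSE]
    pred <- if (criterion == "train") {
      fit_predict(model, Xc, y_train, Xc, seed = seed)
    } else {
      vapply(seq_len(n_tr), function(j) {
        fit_predict(model, Xc[-j, , drop = FALSE], y_train[-j],
                    Xc[j, , drop = FALSE], seed = seed)
      }, numeric(1))
    }
    nrmse(y_train, pred)
  }
  selected <- character(0)
  crit <- nrmse(y_train, rep(mean(y_train), length(y_train)))
  crit_path <- crit
  remaining <- colnames(X_train)
  while (length(remaining) > 0 && length(selected) < max_predictors) {
    scores <- vapply(remaining, function(cand) {
      score_cols(c(selected, cand))
    }, numeric(1))
    best <- which.min(scores)   # ties: first in canonical order
    if (scores[best] < crit) {
      selected <- c(selected, remaining[best])
      remaining <- remaining[-best]
      crit <- scores[best]
      crit_path <- c(crit_path, crit)
    } else {
      break
    }
  }
  attr(selected, "criterion") <- crit_path
  selected
}

#' Leave-one-participant-out cross-validation
#'
#' For each held-out participant, feature selection (if enabled) and model
#' fitting use only the remaining participants; the held-out dynamic range
#' is then predicted, and after all folds the overall nRMSE is computed from
#' the full actual/predicted vectors. Baseline models always use their fixed
#' predictor set and skip FSFS.
#'
#' @param X predictor matrix with participant row names.
#' @param y actual dynamic ranges, one per row of `X`.
#' @param model a [model_spec()].
#' @param use_fsfs run [fsfs()] inside each training fold (default `TRUE`);
#'   if `FALSE` (non-Baseline), all predictors are used.
#' @param max_predictors,fsfs_criterion forwarded to [fsfs()].
#' @param seed integer; each fold derives its own substream.
#' @return list of class `eval_result`: `model`, `nrmse`, `per_participant`
#'   (data frame: participant, actual, predicted, n_selected, selected),
#'   `selection_frequency` (percent of folds selecting each chosen
#'   predictor), `mean_selected`.
#' @export
loocv <- function(X, y, model, use_fsfs = TRUE, max_predictors = Inf,
                  fsfs_criterion = "train", seed = 0L) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 4) stop("LOOCV requires at least 4 participants", call. = FALSE)
  stopifnot(length(y) == n, all(is.finite(y)))
  ids <- rownames(X) %||% as.character(seq_len(n))
  preds <- numeric(n)
  sel_list <- vector("list", n)
  for (i in seq_len(n)) {
    fold_seed <- substream_seed(as.integer(seed), i)
    Xtr <- X[-i, , drop = FALSE]
    ytr <- y[-i]
    sel <- if (model$family == "Baseline") {
      model$hyperparameters$predictors
    } else if (use_fsfs) {
      as.character(fsfs(Xtr, ytr, model, max_predictors = max_predictors,
                        criterion = fsfs_criterion, seed = fold_seed))
    } else {
      colnames(X)
    }
    sel_list[[i]] <- sel
    preds[i] <- if (model$family != "Baseline" && length(sel) == 0) {
      mean(ytr)
    } else if (model$family == "Baseline") {
      fit_predict(model, Xtr, ytr, X[i, , drop = FALSE], seed = fold_seed)
    } else {
      fit_predict(model, Xtr[, sel, drop = FALSE], ytr,
                  X[i, sel, drop = FALSE], seed = fold_seed)
    }
  }
  freq <- sort(table(unlist(sel_list)) / n * 100, decreasing = TRUE)
  structure(
    list(model = model,
         nrmse = nrmse(y, preds),
         per_participant = data.frame(
           participant = ids, actual = y, predicted = preds,
           n_selected = vapply(sel_list, length, 1L),
           selected = vapply(sel_list, paste, "", collapse = ";"),
           stringsAsFactors = FALSE),
         selection_frequency = stats::setNames(as.numeric(freq), names(freq)),
         mean_selected = mean(vapply(sel_list, length, 1L))),
    class = "eval_result"
  )
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("<eval_result> %s: nRMSE %.4f over %d participants (mean %.2f predictors/fold)\n",
              x$model$family, x$nrmse, nrow(x$per_participant),
              x$mean_selected))
  invisible(x)
}

#' One-tailed paired permutation test on cross-validated squared errors
#'
#' Tests whether model `b` predicts better than model `a` from the paired
#' per-participant squared errors. The statistic is the RMSE difference
#' `sqrt(mean(sqerr_b)) - sqrt(mean(sqerr_a))` (proportional to the nRMSE
#' difference, since both models share the actual-value range); its null
#' distribution is built by randomly swapping the two models' errors within
#' participants (sign flips of the paired assignment). One-tailed p-value
#' with add-one smoothing: `p = (1 + #{permuted <= observed}) / (n_perm + 1)`;
#' small p means b's error is genuinely lower.
#'
#' @param sqerr_a,sqerr_b squared prediction errors per participant for the
#'   two models (equal length).
#' @param n_perm number of permutations (default 10000).
#' @param seed integer seed.
#' @return p-value in (0, 1].
#' @export
paired_permutation_test <- function(sqerr_a, sqerr_b, n_perm = 10000,
                                    seed = 1L) {
  if (length(sqerr_a) != length(sqerr_b)) {
    stop("paired error vectors must have equal length", call. = FALSE)
  }
  n <- length(sqerr_a)
  d_obs <- sqrt(mean(sqerr_b)) - sqrt(mean(sqerr_a))
  with_substream(as.integer(seed), 0L, {
    swap <- matrix(stats::runif(n_perm * n) < 0.5, n_perm, n)
    a_perm <- swap %*% sqerr_b + (!swap) %*% sqerr_a
    b_perm <- swap %*% sqerr_a + (!swap) %*% sqerr_b
    d_perm <- sqrt(b_perm / n) - sqrt(a_perm / n)
    (1 + sum(d_perm <= d_obs)) / (n_perm + 1)
  })
}
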