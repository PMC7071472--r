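#' Feature-matched baseline predictor for each target feature
#'
#' The fixed resting predictor a no-selection baseline model uses: the IQR of
#' the same quantity the task feature measures (alpha2 asymmetry for FAA,
#' channel-mean relative theta for rFTP, channel-mean relative low beta for
#' rFLBP).
#'
#' @param feature `"FAA"`, `"rFTP"` or `"rFLBP"`.
#' @return a canonical predictor name.
#' @export
baseline_predictor <- function(feature = c("FAA", "rFTP", "rFLBP")) {
  switch(match.arg(feature),
         FAA = "IQR-Asym-Alpha-10-12",
         rFTP = "IQR-Rel-Fp12-Theta-4-8",
         rFLBP = "IQR-Rel-Fp12-Beta-12-15")
}

#' Configuration for a full pipeline run
#'
#' @param mode `"synthetic"` (generate the cohort) or `"csv-dir"` (read
#'   recordings written by [write_cohort()] from `input_dir`).
#' @param cohort a [cohort_config()] (synthetic mode).
#' @param input_dir directory of delimited recordings (csv-dir mode).
#' @param models named list of [model_spec()]s to evaluate (a feature-matched
#'   `Baseline` is always evaluated alongside).
#' @param use_fsfs run forward selection inside every training fold.
#' @param max_predictors cap forwarded to [fsfs()].
#' @param include_resting per-feature inclusion of resting segments in the
#'   dynamic-range pool (see [dynamic_ranges()]).
#' @param lms_sessions session types preprocessed with LMS instead of blink
#'   rejection.
#' @param n_perm permutations for the baseline-vs-model comparison.
#' @param threshold_rule suitability threshold rule; only
#'   `"mean_minus_sd"` is registered.
#' @param out_dir output directory for persisted tables and the summary.
#' @param seed root seed for every stochastic stage.
#' @return list of class `run_config`.
#' @export
run_config <- function(mode = c("synthetic", "csv-dir"),
                       cohort = cohort_config(),
                       input_dir = NULL,
                       models = list(SVMR = model_spec("SVMR")),
                       use_fsfs = TRUE,
                       max_predictors = Inf,
                       include_resting = c(FAA = FALSE, rFTP = TRUE,
                                           rFLBP = TRUE),
                       lms_sessions = "attention",
                       n_perm = 10000,
                       threshold_rule = "mean_minus_sd",
                       out_dir = tempfile("restdyn-run-"),
                       seed = 1L) {
  mode <- match.arg(mode)
  if (mode == "csv-dir") {
    if (is.null(input_dir) || !dir.exists(input_dir)) {
      config_error("input_dir", "must be an existing directory in csv-dir mode")
    }
  }
  if (length(models) == 0) config_error("models", "must be non-empty")
  stopifnot(all(vapply(models, inherits, TRUE, "model_spec")))
  structure(
    list(mode = mode, cohort = cohort, input_dir = input_dir, models = models,
         use_fsfs = use_fsfs, max_predictors = max_predictors,
         include_resting = include_resting, lms_sessions = lms_sessions,
         n_perm = n_perm, threshold_rule = threshold_rule,
         out_dir = out_dir, seed = as.integer(seed)),
    class = "run_config"
  )
}

#' Suitability screening against a cohort-derived threshold
#'
#' Flags whether a (predicted) dynamic range clears the heuristic screening
#' threshold. The default rule is `mean - sd` of the cohort's actual dynamic
#' ranges (sample standard deviation, n-1 denominator). Users below the
#' threshold are recommended an additional calibration session; users at or
#' above it can skip it.
#'
#' @param predicted numeric vector of predicted dynamic ranges.
#' @param cohort_iqrs actual dynamic ranges of the cohort (length >= 2).
#' @param rule threshold rule name; only `"mean_minus_sd"` is registered.
#' @return data frame: `predicted_iqr`, `threshold`, `suitable`,
#'   `recommendation` (`"skip calibration"` or `"calibrate"`).
#' @examples
#' suitability(0.5, c(1, 1, 1, 5))  # threshold 0: suitable
#' @export
suitability <- function(predicted, cohort_iqrs, rule = "mean_minus_sd") {
  if (length(cohort_iqrs) < 2) {
    stop("need at least 2 cohort IQRs to form a threshold", call. = FALSE)
  }
  threshold <- switch(rule,
    mean_minus_sd = mean(cohort_iqrs) - stats::sd(cohort_iqrs),
    stop("unknown threshold rule '", rule, "'", call. = FALSE)
  )
  ok <- predicted >= threshold
  data.frame(predicted_iqr = predicted, threshold = threshold, suitable = ok,
             recommendation = ifelse(ok, "skip calibration", "calibrate"),
             stringsAsFactors = FALSE)
}

# per-participant stage: preprocess all sessions, return feature rows +
# resting predictor vector (synthetic mode generates the participant here so
# only one participant's raw signals are in memory at a time)
process_participant <- function(part, config) {
  feats <- list()
  predictors <- NULL
  for (session in names(part$recordings)) {
    series <- preprocess_recording(part$recordings[[session]],
                                   session_type = session,
                                   lms_sessions = config$lms_sessions)
    if (session == "resting") {
      predictors <- extract_candidate_predictors(series)
    }
    wanted <- if (session == "resting") {
      names(config$include_resting)[config$include_resting]
    } else {
      switch(session, valence = "FAA", relaxation = "rFTP",
             attention = "rFLBP", character(0))
    }
    for (feat in wanted) {
      fs <- feature_series(series, feat)
      fs$participant <- part$participant
      fs$session <- session
      feats[[paste(session, feat)]] <- fs
    }
  }
  list(features = do.call(rbind, feats), predictors = predictors)
}

read_cohort_participant <- function(dir, participant) {
  files <- list.files(dir, pattern = paste0("^", participant, "_.*\\.tsv$"),
                      full.names = TRUE)
  sessions <- sub("\\.tsv$", "", sub(paste0("^", participant, "_"), "",
                                     basename(files)))
  recs <- lapply(files, read_recording)
  names(recs) <- sessions
  order <- intersect(c("resting", "valence", "relaxation", "attention"),
                     sessions)
  list(participant = participant, recordings = recs[order])
}

#' Run the full analysis pipeline
#'
#' Executes every stage in order -- cohort generation (or ingestion),
#' per-session preprocessing, feature-series extraction, resting predictor
#' extraction, dynamic ranges, model evaluation under LOOCV (+FSFS), paired
#' permutation comparison against the feature-matched baseline, and
#' suitability screening -- persisting every intermediate table under
#' `config$out_dir` and returning (and writing) a JSON-ready summary.
#' Deterministic: re-running the same config yields byte-identical outputs.
#'
#' @param config a [run_config()].
#' @return invisibly, the summary list (also written to
#'   `out_dir/summary.json`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  if (config$mode == "synthetic") {
    cohort_cfg <- resolve_link_noise(config$cohort)
    ids <- seq_len(cohort_cfg$n_participants) - 1L
    get_part <- function(i) generate_participant(cohort_cfg, ids[i])
    n_part <- length(ids)
  } else {
    files <- list.files(config$input_dir, pattern = "_resting\\.tsv$")
    participants <- sort(sub("_resting\\.tsv$", "", files))
    if (length(participants) == 0) {
      stop("pipeline stage ingest: no *_resting.tsv recordings in ",
           config$input_dir, call. = FALSE)
    }
    get_part <- function(i) read_cohort_participant(config$input_dir,
                                                    participants[i])
    n_part <- length(participants)
  }

  feature_rows <- list()
  pred_rows <- list()
  for (i in seq_len(n_part)) {
    part <- get_part(i)
    res <- tryCatch(process_participant(part, config),
                    error = function(e) {
                      stop("pipeline stage preprocess/features, participant ",
                           part$participant, ": ", conditionMessage(e),
                           call. = FALSE)
                    })
    feature_rows[[i]] <- res$features
    pred_rows[[part$participant]] <- res$predictors
  }
  features <- do.call(rbind, feature_rows)
  rownames(features) <- NULL
  X <- do.call(rbind, pred_rows)

  utils::write.table(features, file.path(config$out_dir, "feature_series.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_predictors(X, file.path(config$out_dir, "predictors.tsv"))

  dr <- dynamic_ranges(features, include_resting = config$include_resting)
  utils::write.table(dr, file.path(config$out_dir, "dynamic_ranges.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  evaluation <- list()
  scatter <- list()
  suit_rows <- list()
  for (feat in unique(dr$feature)) {
    sub <- dr[dr$feature == feat, , drop = FALSE]
    have <- intersect(rownames(X), sub$participant)
    if (length(have) < 4) next
    Xf <- X[have, , drop = FALSE]
    yf <- sub$iqr[match(have, sub$participant)]
    base <- model_spec("Baseline", predictors = baseline_predictor(feat))
    base_res <- loocv(Xf, yf, base, use_fsfs = FALSE, seed = config$seed)
    feat_eval <- list(baseline = list(model = "Baseline",
                                      nrmse = base_res$nrmse))
    best <- NULL
    for (mn in names(config$models)) {
      res <- loocv(Xf, yf, config$models[[mn]], use_fsfs = config$use_fsfs,
                   max_predictors = config$max_predictors,
                   seed = config$seed)
      sq_base <- (base_res$per_participant$actual -
                    base_res$per_participant$predicted)^2
      sq_mod <- (res$per_participant$actual -
                   res$per_participant$predicted)^2
      pval <- paired_permutation_test(sq_base, sq_mod,
                                      n_perm = config$n_perm,
                                      seed = config$seed)
      feat_eval[[mn]] <- list(
        model = res$model$family, nrmse = res$nrmse,
        mean_selected = res$mean_selected,
        selection_frequency = as.list(res$selection_frequency),
        p_vs_baseline = pval)
      scatter[[paste(feat, mn)]] <- cbind(feature = feat, model = mn,
                                          res$per_participant)
      if (is.null(best) || res$nrmse < best$nrmse) best <- res
    }
    evaluation[[feat]] <- feat_eval
    suit <- suitability(best$per_participant$predicted, yf,
                        rule = config$threshold_rule)
    suit <- cbind(participant = have, feature = feat, suit)
    suit_rows[[feat]] <- suit
  }
  if (length(scatter) > 0) {
    utils::write.table(do.call(rbind, scatter),
                       file.path(config$out_dir, "actual_vs_predicted.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (length(suit_rows) > 0) {
    utils::write.table(do.call(rbind, suit_rows),
                       file.path(config$out_dir, "suitability.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  summary <- list(
    n_participants = n_part,
    seed = config$seed,
    run_log = list(
      package_version = as.character(utils::packageVersion("restdyn")),
      mode = config$mode,
      models = vapply(config$models, `[[`, "", "family"),
      use_fsfs = config$use_fsfs,
      max_predictors = if (is.finite(config$max_predictors))
        config$max_predictors else "unlimited",
      lms_sessions = config$lms_sessions,
      include_resting = as.list(config$include_resting),
      n_perm = config$n_perm),
    features = stats::setNames(
      lapply(unique(dr$feature), function(f) {
        list(n = sum(dr$feature == f),
             mean_iqr = mean(dr$iqr[dr$feature == f]),
             sd_iqr = stats::sd(dr$iqr[dr$feature == f]))
      }), unique(dr$feature)),
    evaluation = evaluation,
    threshold_rule = paste(config$threshold_rule,
                           "(heuristic; not validated on held-out users)")
  )
  jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}
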