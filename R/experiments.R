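#' Parameter-recovery experiment: predict linked task IQRs from resting EEG
#'
#' The headline validation of the whole pipeline on the generator's study
#' conditions: a 35-participant cohort whose valence-feature (FAA) dynamic
#' range is driven by one designated resting predictor
#' (`IQR-Asym-Alpha-8-12`, unit coefficient, Gaussian noise with SD 10% of
#' the linked component's cohort spread). For each replicate cohort the 112
#' predictors are re-measured through the full artifact pipeline (blink
#' injection, detection, rejection), LOOCV+FSFS is run with the given model,
#' and the result is compared with an oracle that regresses on the designated
#' predictor alone (MLR, no selection).
#'
#' @param n_seeds number of replicate cohorts.
#' @param seed root seed; replicate `s` uses an independent substream.
#' @param n_participants cohort size.
#' @param model [model_spec()] evaluated with FSFS (default SVMR).
#' @param max_predictors FSFS parsimony cap per fold (default 3: the link
#'   plants exactly one informative predictor, and compact selected sets are
#'   characteristic of asymmetry-feature screening; the cap keeps the
#'   epsilon-insensitive SVR criterion from grinding through marginal
#'   training-fit gains).
#' @param noise_frac link noise SD as a fraction of the linked component's
#'   cohort SD.
#' @return data frame, one row per replicate: `seed`, `nrmse` (model),
#'   `oracle_nrmse`, `nrmse_ratio`, `true_predictor_pct` (percent of LOOCV
#'   folds whose selected set contains the designated predictor),
#'   `mean_selected`.
#' @export
experiment_recovery <- function(n_seeds = 20, seed = 1, n_participants = 35,
                                model = model_spec("SVMR"),
                                max_predictors = 3, noise_frac = 0.1) {
  true_pred <- "IQR-Asym-Alpha-8-12"
  out <- vector("list", n_seeds)
  for (s in seq_len(n_seeds)) {
    cohort_seed <- substream_seed(as.integer(seed), s)
    cfg <- cohort_config(
      n_participants = n_participants, task_durations = NULL,
      sessions = "resting", eog = FALSE,
      link_spec = list(FAA = list(predictor = true_pred, coefficient = 1,
                                  noise_frac = noise_frac)),
      seed = cohort_seed
    )
    coh <- generate_cohort(cfg)
    y <- coh$truth_iqr$target_iqr[coh$truth_iqr$feature == "FAA"]
    X <- t(vapply(coh$participants, function(p) {
      extract_candidate_predictors(
        preprocess_recording(p$recordings$resting, "resting"))
    }, numeric(112)))
    rownames(X) <- rownames(coh$measured_predictors)
    res <- loocv(X, y, model, use_fsfs = TRUE,
                 max_predictors = max_predictors, seed = cohort_seed)
    oracle <- loocv(X[, true_pred, drop = FALSE], y, model_spec("MLR"),
                    use_fsfs = FALSE, seed = cohort_seed)
    hit <- grepl(true_pred, res$per_participant$selected, fixed = TRUE)
    out[[s]] <- data.frame(
      seed = cohort_seed, nrmse = res$nrmse, oracle_nrmse = oracle$nrmse,
      nrmse_ratio = res$nrmse / oracle$nrmse,
      true_predictor_pct = 100 * mean(hit),
      mean_selected = res$mean_selected
    )
  }
  do.call(rbind, out)
}

#' Artifact-handling experiment: blink detection and LMS performance
#'
#' Measures, on default synthetic settings, (i) blink detection sensitivity
#' and the fraction of injected-blink samples removed by detection plus
#' segment rejection over `n_recordings` one-minute recordings, (ii) the
#' false-interval rate on `n_clean` clean minutes, and (iii) LMS ocular
#' removal on the stationary mixing construction EEG = clean + 0.8 x EOG
#' (residual correlation with the reference and clean-signal distortion,
#' first 2 s discarded).
#'
#' @param n_recordings one-minute recordings with blinks.
#' @param n_clean clean one-minute recordings.
#' @param seed root seed.
#' @return list with `sensitivity`, `false_per_clean_min`,
#'   `blink_sample_removal`, `lms_corr`, `lms_distortion_ratio`.
#' @export
experiment_artifacts <- function(n_recordings = 10, n_clean = 5, seed = 1) {
  hits <- 0; total <- 0; removed <- 0; blink_samp <- 0
  for (s in seq_len(n_recordings)) {
    cfg <- cohort_config(n_participants = 3, resting_duration = 60,
                         task_durations = NULL, sessions = "resting",
                         eog = FALSE, link_spec = NULL,
                         seed = substream_seed(as.integer(seed), s))
    p <- generate_participant(cfg, 0)
    rec <- bandpass_recording(
      resample_recording(p$recordings$resting, 256), 0.5, 30)
    det <- detect_blinks(rec)
    series <- reject_segments(segment_recording(rec), det)
    ann <- p$recordings$resting$annotations
    b0 <- ann$start_s[ann$label == "blink"]
    b1 <- ann$end_s[ann$label == "blink"]
    total <- total + length(b0)
    for (i in seq_along(b0)) {
      hits <- hits + any(det$start_s < b1[i] & det$end_s > b0[i])
    }
    # fraction of blink-event time falling in surviving (valid) segments
    grid <- seq(0, duration(rec) - 1 / 256, by = 1 / 256)
    in_blink <- rep(FALSE, length(grid))
    for (i in seq_along(b0)) in_blink <- in_blink | (grid >= b0[i] & grid < b1[i])
    in_valid <- rep(FALSE, length(grid))
    for (k in which(series$valid)) {
      in_valid <- in_valid |
        (grid >= series$starts[k] & grid < series$starts[k] + series$window_s)
    }
    blink_samp <- blink_samp + sum(in_blink)
    removed <- removed + sum(in_blink & !in_valid)
  }
  false_int <- 0
  for (s in seq_len(n_clean)) {
    cfg <- cohort_config(n_participants = 3, resting_duration = 60,
                         task_durations = NULL, sessions = "resting",
                         blink_rate = 0, eog = FALSE, link_spec = NULL,
                         seed = substream_seed(as.integer(seed), 1000L + s))
    p <- generate_participant(cfg, 0)
    rec <- bandpass_recording(
      resample_recording(p$recordings$resting, 256), 0.5, 30)
    false_int <- false_int + nrow(detect_blinks(rec))
  }
  lms <- with_substream(as.integer(seed), 2000L, {
    n <- 256 * 60
    eog1 <- band_limited_noise(n, 256, 0.5, 8) * 10
    eog2 <- band_limited_noise(n, 256, 0.5, 8) * 8
    clean <- band_limited_noise(n, 256, 8, 12) * 10
    rec <- eeg_recording(list(Fp1 = clean + 0.8 * eog1, Fp2 = clean + 0.5 * eog2,
                              EOG1 = eog1, EOG2 = eog2), 256)
    out <- lms_remove_eog(rec)
    keep <- (2 * 256):n
    list(corr = abs(stats::cor(out$data[keep, "Fp1"], eog1[keep])),
         distortion = sqrt(mean((out$data[keep, "Fp1"] - clean[keep])^2)) /
           sqrt(mean((0.8 * eog1[keep])^2)))
  })
  list(sensitivity = hits / total,
       false_per_clean_min = false_int / n_clean,
       blink_sample_removal = removed / blink_samp,
       lms_corr = lms$corr,
       lms_distortion_ratio = lms$distortion)
}

#' Type-I-error calibration of the paired permutation test
#'
#' Simulated null: both models' per-participant squared errors drawn i.i.d.
#' from the same distribution (squared standard normals); the rejection rate
#' at the given level over many replicates estimates the test's actual size.
#'
#' @param n_replicates null replicates.
#' @param n_participants paired observations per replicate.
#' @param n_perm permutations per test.
#' @param alpha nominal level.
#' @param seed root seed.
#' @return list with `rejection_rate` and `n_replicates`.
#' @export
experiment_permutation_null <- function(n_replicates = 500,
                                        n_participants = 35,
                                        n_perm = 2000, alpha = 0.05,
                                        seed = 1) {
  rej <- 0
  for (r in seq_len(n_replicates)) {
    p <- with_substream(as.integer(seed), r, {
      a <- stats::rnorm(n_participants)^2
      b <- stats::rnorm(n_participants)^2
      paired_permutation_test(a, b, n_perm = n_perm,
                              seed = substream_seed(as.integer(seed),
                                                    100000L + r))
    })
    rej <- rej + (p < alpha)
  }
  list(rejection_rate = rej / n_replicates, n_replicates = n_replicates)
}
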