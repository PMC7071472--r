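#!/usr/bin/env Rscript
# Predict each participant's task-feature dynamic range from the resting
# predictors: LOOCV with forward sequential feature selection per model
# family, nRMSE scoring, and a one-tailed paired permutation comparison of
# each model against the feature-matched no-selection baseline.

source(file.path("analysis", "00_config.R"))

X <- read_predictors(file.path(results_dir, "resting_predictors.tsv"))
dr <- read.table(file.path(results_dir, "dynamic_ranges.tsv"),
                 header = TRUE, sep = "\t")

nrmse_rows <- list()
freq_rows <- list()
for (feat in unique(dr$feature)) {
  sub <- dr[dr$feature == feat, ]
  ids <- intersect(rownames(X), sub$participant)
  y <- sub$iqr[match(ids, sub$participant)]
  Xf <- X[ids, , drop = FALSE]

  base <- loocv(Xf, y, model_spec("Baseline",
                                  predictors = baseline_predictor(feat)),
                use_fsfs = FALSE, seed = analysis_seed)
  sq_base <- (base$per_participant$actual - base$per_participant$predicted)^2
  nrmse_rows[[paste(feat, "Baseline")]] <-
    data.frame(feature = feat, model = "Baseline", nrmse = base$nrmse,
               mean_selected = NA, p_vs_baseline = NA)

  for (mn in names(analysis_models)) {
    res <- loocv(Xf, y, analysis_models[[mn]], use_fsfs = TRUE,
                 max_predictors = analysis_max_predictors,
                 seed = analysis_seed)
    sq <- (res$per_participant$actual - res$per_participant$predicted)^2
    pval <- paired_permutation_test(sq_base, sq, n_perm = 10000,
                                    seed = analysis_seed)
    nrmse_rows[[paste(feat, mn)]] <-
      data.frame(feature = feat, model = mn, nrmse = res$nrmse,
                 mean_selected = res$mean_selected, p_vs_baseline = pval)
    top <- utils::head(res$selection_frequency, 5)
    freq_rows[[paste(feat, mn)]] <-
      data.frame(feature = feat, model = mn, predictor = names(top),
                 selection_pct = as.numeric(top))
  }
  message("evaluated ", feat)
}

nrmse_tab <- do.call(rbind, nrmse_rows)
rownames(nrmse_tab) <- NULL
write.table(nrmse_tab, file.path(results_dir, "model_nrmse.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
freq_tab <- do.call(rbind, freq_rows)
rownames(freq_tab) <- NULL
write.table(freq_tab, file.path(results_dir, "selection_frequency.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

message("nRMSE per feature and model:")
print(nrmse_tab, digits = 4)
message("Top selected predictors written to selection_frequency.tsv")
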