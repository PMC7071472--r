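#!/usr/bin/env Rscript
# Screening report: who could skip an individual calibration session?
#
# For each feature, take the best model's LOOCV predictions of the dynamic
# range and flag participants whose predicted IQR falls below the heuristic
# cohort threshold (mean - sample SD of the actual IQRs).

source(file.path("analysis", "00_config.R"))

X <- read_predictors(file.path(results_dir, "resting_predictors.tsv"))
dr <- read.table(file.path(results_dir, "dynamic_ranges.tsv"),
                 header = TRUE, sep = "\t")
nrmse_tab <- read.table(file.path(results_dir, "model_nrmse.tsv"),
                        header = TRUE, sep = "\t")

rows <- list()
for (feat in unique(dr$feature)) {
  sub <- dr[dr$feature == feat, ]
  ids <- intersect(rownames(X), sub$participant)
  y <- sub$iqr[match(ids, sub$participant)]
  cand <- nrmse_tab[nrmse_tab$feature == feat & nrmse_tab$model != "Baseline", ]
  best_name <- cand$model[which.min(cand$nrmse)]
  res <- loocv(X[ids, , drop = FALSE], y, analysis_models[[best_name]],
               use_fsfs = TRUE, max_predictors = analysis_max_predictors,
               seed = analysis_seed)
  s <- suitability(res$per_participant$predicted, y)
  rows[[feat]] <- cbind(participant = ids, feature = feat,
                        model = best_name, actual_iqr = y, s)
  message(sprintf("%s (best: %s): %d/%d flagged for calibration", feat,
                  best_name, sum(!s$suitable), length(ids)))
}
report <- do.call(rbind, rows)
rownames(report) <- NULL
write.table(report, file.path(results_dir, "suitability_report.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

jsonlite::write_json(
  list(threshold_rule = "mean - sample SD of cohort IQRs (heuristic)",
       n_flagged = sum(!report$suitable),
       n_records = nrow(report)),
  file.path(results_dir, "suitability_summary.json"),
  auto_unbox = TRUE, digits = NA, pretty = TRUE)
message("Wrote suitability_report.tsv")
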