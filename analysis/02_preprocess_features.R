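#!/usr/bin/env Rscript
# Preprocess every session and extract feature series, resting predictors,
# and dynamic ranges.
#
# Stage order per session: downsample to 256 Hz; LMS ocular filtering for
# the attention sessions (EOG-referenced); zero-phase 0.5-30 Hz band-pass;
# 1-s / 50%-overlap segmentation; blink detection + segment rejection for
# the non-LMS sessions. Dynamic ranges are the type-7 IQRs of the
# per-segment feature series (resting segments pooled for the relative-power
# features only).

source(file.path("analysis", "00_config.R"))

cohort <- generate_cohort(analysis_cohort)

features <- list()
predictors <- list()
for (p in cohort$participants) {
  for (session in names(p$recordings)) {
    series <- preprocess_recording(p$recordings[[session]],
                                   session_type = session)
    if (session == "resting") {
      predictors[[p$participant]] <- extract_candidate_predictors(series)
      wanted <- c("rFTP", "rFLBP")
    } else {
      wanted <- switch(session, valence = "FAA", relaxation = "rFTP",
                       attention = "rFLBP")
    }
    for (feat in wanted) {
      fs <- feature_series(series, feat)
      fs$participant <- p$participant
      fs$session <- session
      features[[paste(p$participant, session, feat)]] <- fs
    }
  }
  message("processed ", p$participant)
}
features <- do.call(rbind, features)
rownames(features) <- NULL

X <- do.call(rbind, predictors)
write_predictors(X, file.path(results_dir, "resting_predictors.tsv"))

dr <- dynamic_ranges(features)
write.table(dr, file.path(results_dir, "dynamic_ranges.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

rej <- aggregate(value ~ feature, features, length)
message("Feature series segment counts:")
print(rej)
message("Dynamic ranges (IQR) per feature:")
print(aggregate(iqr ~ feature, dr,
                function(v) c(mean = mean(v), sd = sd(v))))
message("Wrote resting_predictors.tsv and dynamic_ranges.tsv")
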