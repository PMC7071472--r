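#!/usr/bin/env Rscript
# Simulate the synthetic pBCI cohort and record its ground truth.
#
# Each participant gets a 60-s resting recording and three 60-s task sessions
# (valence / relaxation / attention analogues) at 2048 Hz, with eye blinks
# injected and each task feature's dynamic range linked to its
# feature-matched resting predictor. Writes the ground-truth tables and a
# short excerpt of one recording; raw waveforms are regenerated on demand by
# later scripts (generation is deterministic given the config).

source(file.path("analysis", "00_config.R"))

message("Generating ", analysis_cohort$n_participants, "-participant cohort ...")
cohort <- generate_cohort(analysis_cohort)

write.table(cohort$truth_iqr, file.path(results_dir, "cohort_truth_iqr.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write_predictors(cohort$measured_predictors,
                 file.path(results_dir, "cohort_measured_predictors.tsv"))

# 2-s excerpt of the first participant's resting recording for illustration
p1 <- cohort$participants[[1]]
rec <- p1$recordings$resting
excerpt <- eeg_recording(rec$data[seq_len(2 * rec$rate), , drop = FALSE],
                         rate = rec$rate, channels = rec$channels,
                         roles = rec$roles)
write_recording(resample_recording(excerpt, 256),
                file.path(results_dir, "example_resting_excerpt.tsv"))

tgt <- cohort$truth_iqr[cohort$truth_iqr$session == "resting", ]
message("Linked task-feature IQR targets per feature (cohort range):")
for (f in unique(tgt$feature)) {
  v <- tgt$target_iqr[tgt$feature == f]
  message(sprintf("  %-6s %.3f - %.3f", f, min(v), max(v)))
}
n_blinks <- sum(vapply(cohort$participants,
                       function(p) length(unlist(p$blink_times)), 1))
message("Total injected blinks across cohort: ", n_blinks)
message("Wrote ground-truth tables to ", results_dir)
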