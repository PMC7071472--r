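# Shared configuration for the analysis drivers.
#
# The cohort is fully determined by this config plus the seed: later scripts
# regenerate what they need deterministically instead of shipping hundreds of
# megabytes of raw waveforms between steps. Sizes here are a desk-scale
# demonstration cohort (12 participants, 60-s sessions); the package-level
# experiments (scripts/acceptance.R, tests) use the full 35-participant
# conditions.

library(restdyn)

analysis_seed <- 20260921L

analysis_cohort <- cohort_config(
  n_participants = 12,
  resting_duration = 60,
  task_durations = c(valence = 60, relaxation = 60, attention = 60),
  seed = analysis_seed
)

analysis_models <- list(
  MLR = model_spec("MLR"),
  TR = model_spec("TR"),
  SVMR = model_spec("SVMR")
)

analysis_max_predictors <- 3

results_dir <- file.path("results")
dir.create(results_dir, showWarnings = FALSE)
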