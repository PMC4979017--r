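#!/usr/bin/env Rscript
# Step 1 — simulate the study cohorts.
#
# Draws one probe population and emits a training cohort (150 cases, 50
# controls, with planted spike-in failures and low-quality samples) plus an
# independent validation cohort from the same population (75 cases, 50
# healthy controls, 25 benign-disease samples). Writes Ct tables, metadata
# and the ground truth under results/.

suppressPackageStartupMessages(library(mirvote))

seed <- 20160801L
dir.create("results", showWarnings = FALSE)

cfg <- simulation_config(seed = seed)
training <- generate_cohort(cfg)

va_cfg <- simulation_config(
  n_case = 75, n_control = 50, n_other = c(BPD = 25),
  n_spike_failures = c(case = 0, control = 0),
  n_lowquality = c(case = 0, control = 0),
  n_calibrators = 0, seed = seed + 1
)
validation <- generate_cohort(va_cfg, "VALIDATION",
                              population = training$truth$population)

write_ct_long(training$ct, "results/training_ct.csv")
write_metadata(training$metadata, "results/training_metadata.csv")
write_ct_long(validation$ct, "results/validation_ct.csv")
write_metadata(validation$metadata, "results/validation_metadata.csv")
write.csv(training$truth$informative, "results/truth_informative.csv",
          row.names = FALSE)
writeLines(training$truth$stable, "results/truth_stable.txt")
writeLines(c(training$truth$spike_failures, training$truth$lowquality),
           "results/truth_planted_failures.txt")

cat(sprintf("training: %d samples x %d probes; validation: %d samples\n",
            nrow(training$ct$ct), ncol(training$ct$ct), nrow(validation$ct$ct)))
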