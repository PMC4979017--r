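#!/usr/bin/env Rscript
# Step 5 — score the independent validation cohort with frozen parameters.
#
# The saved training run carries the normalizer set, calibrator means,
# training mu/SD and the final model; validation samples are normalized and
# called without any refitting. Healthy controls and the benign-disease
# group pool into combined specificity; per-stage and per-group positivity
# panels are written alongside, plus the planted-truth recovery summary.

suppressPackageStartupMessages(library(mirvote))

run <- readRDS("results/training_run.rds")
ct <- read_ct_long("results/validation_ct.csv")
md <- read_metadata("results/validation_metadata.csv")

vr <- run_validation(run, ct, md)

write.csv(as.data.frame(vr$calls), "results/validation_calls.csv",
          row.names = FALSE)
write.csv(as.data.frame(vr$roc$roc), "results/validation_roc.csv",
          row.names = FALSE)
write.csv(as.data.frame(vr$positivity), "results/validation_stage_positivity.csv",
          row.names = FALSE)
write.csv(as.data.frame(vr$group_positivity), "results/validation_group_positivity.csv",
          row.names = FALSE)

truth <- read.csv("results/truth_informative.csv")
overlap <- length(intersect(run$model$features, truth$probe))
summary <- data.frame(
  metric = c("sensitivity", "specificity", "accuracy", "auc",
             "chosen_k", "planted_overlap"),
  value = c(vr$eval$sensitivity, vr$eval$specificity, vr$eval$accuracy,
            vr$roc$auc, run$cv$chosen_k, overlap)
)
write.csv(summary, "results/validation_summary.csv", row.names = FALSE)

cat(sprintf("validation: sens %.3f spec %.3f AUC %.3f; %d/%d final features are planted\n",
            vr$eval$sensitivity, vr$eval$specificity, vr$roc$auc,
            overlap, length(run$model$features)))
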