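#!/usr/bin/env Rscript
# Step 4 — fit normalization parameters and train the voting classifier.
#
# Runs the complete training pipeline: QC, bootstrap normalizer selection,
# calibrator-anchored delta-delta-Ct and z-scoring (parameters frozen on the
# training cohort), repeated stratified 10-fold cross-validation to choose
# the feature count, and finalization by inclusion frequency. Reduced
# bootstrap/partition counts keep the script in the minutes range; the
# full-scale defaults are 10,000 each.

suppressPackageStartupMessages(library(mirvote))

seed <- 20160801L

ct <- read_ct_long("results/training_ct.csv")
md <- read_metadata("results/training_metadata.csv")

run <- run_training(ct, md, spike_probe = "ath-miR-159a", seed = seed,
                    n_bootstrap = 1000, n_partitions = 200)

saveRDS(run, "results/training_run.rds")
write.csv(data.frame(k = run$cv$k_grid,
                     mean_misclassification = unname(run$cv$mean_misclassification)),
          "results/cv_error_curve.csv", row.names = FALSE)
write.csv(as.data.frame(run$cv$inclusion[order(-run$cv$inclusion$n_included), ]),
          "results/cv_inclusion.csv", row.names = FALSE)
write.csv(data.frame(feature = run$model$features,
                     weight = unname(run$model$w),
                     boundary = unname(run$model$b)),
          "results/final_model.csv", row.names = FALSE)
write.csv(as.data.frame(run$training_calls), "results/training_calls.csv",
          row.names = FALSE)

cat(sprintf("chosen k = %d; training sens %.3f spec %.3f AUC %.3f\n",
            run$cv$chosen_k, run$training_eval$sensitivity,
            run$training_eval$specificity, run$training_roc$auc))
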