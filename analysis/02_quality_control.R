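#!/usr/bin/env Rscript
# Step 2 — quality control of the training cohort.
#
# Applies the spike-in filter (samples whose spike-in probe is undetected are
# removed), the detectability screen (probes detected in at least one
# retained sample), and the 25th-percentile Ct filter (samples whose
# 25th-percentile Ct, undetected imputed at the ceiling, is at or above the
# detection limit are removed). Writes the exclusion table.

suppressPackageStartupMessages(library(mirvote))

ct <- read_ct_long("results/training_ct.csv")
qc <- run_qc(ct, spike_probe = "ath-miR-159a")

excl <- rbind(
  data.frame(sample_id = qc$excluded_spike, reason = "spike_in_undetected"),
  data.frame(sample_id = qc$excluded_percentile, reason = "percentile_ge_cutoff")
)
write.csv(excl, "results/qc_exclusions.csv", row.names = FALSE)
writeLines(qc$retained, "results/qc_retained_samples.txt")
writeLines(qc$detectable_probes, "results/qc_detectable_probes.txt")
write.csv(data.frame(sample_id = names(qc$sample_percentiles),
                     p25_ct = unname(qc$sample_percentiles)),
          "results/qc_sample_percentiles.csv", row.names = FALSE)

cat(sprintf("retained %d samples (excluded %d spike, %d percentile); %d detectable probes\n",
            length(qc$retained), length(qc$excluded_spike),
            length(qc$excluded_percentile), length(qc$detectable_probes)))
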