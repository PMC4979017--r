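# mirvote

Build and validate blood-borne miRNA diagnostic classifiers from qPCR
cycle-threshold (Ct) profiles.

Circulating miRNAs can be profiled from serum by RT-qPCR arrays and used as
minimally invasive diagnostic markers. Getting from a raw Ct table to a
defensible classifier takes a chain of steps that are easy to get subtly
wrong: quality control of heavily censored Ct data, selection of stable
reference miRNAs for normalization, ΔΔCt and z-score transformation that
must be frozen on training parameters, and a classifier whose feature count
is chosen by honest cross-validation rather than resubstitution. mirvote
implements that chain end to end, with every stage unit-tested against
independent oracles and a synthetic-cohort generator with recorded ground
truth so the whole pipeline can be verified without patient data.

## The pipeline

1. **QC** — remove samples whose exogenous spike-in (`ath-miR-159a`) is
   undetected (failed extraction/RT); drop probes detected nowhere; remove
   samples whose 25th-percentile Ct (undetected imputed at the 40-cycle
   ceiling) is at or above the detection limit of 32 cycles.
2. **Normalizer selection** — candidates are probes detected in every
   retained sample; each is scored with the two-group model-based stability
   value of Andersen et al. (2004),
   ρ = mean over groups of (|shrunken group×gene interaction| + intra-group
   sampling SD), then ranked by the median stability across a stratified
   bootstrap (10,000 replicates); the top 3 form the normalizer.
3. **Normalization** — ΔCt = Ct − mean(normalizer Ct);
   ΔΔCt = ΔCt − mean ΔCt of 22 calibrator samples;
   z = (ΔΔCt − μ_train)/σ_train. All parameters are frozen on training and
   fingerprinted; validation is scored, never refit.
4. **Weighted voting** — each feature votes w·(x − b) with the
   signal-to-noise weight w = (μ_case − μ_ctrl)/(σ_case + σ_ctrl) and
   midpoint boundary b; POSITIVE iff the vote sum is > 0. The feature
   count is chosen by repeated stratified 10-fold cross-validation with
   ranking done inside each fold, and the final panel is assembled from
   cross-fold inclusion frequencies.
5. **Evaluation** — confusion metrics with benign-disease pooling into
   combined specificity, ROC/AUC by tie-corrected trapezoid, per-stage and
   per-group positivity panels, and cohort balance tables.

See `vignettes/methods.Rmd` for the full statistical specification,
parameter defaults and rationale, and known limitations.

## Worked example

Simulate a small study, train with frozen parameters, and score an
independent validation cohort drawn from the same probe population:

```r
library(mirvote)

cfg <- simulation_config(n_case = 60, n_control = 30, n_probes = 100,
                         n_spike_failures = c(case = 1, control = 1),
                         n_lowquality = c(case = 2, control = 0),
                         n_calibrators = 10, seed = 11)
train <- generate_cohort(cfg)
run <- run_training(train$ct, train$metadata, spike_probe = cfg$spike_probe,
                    seed = 11, n_bootstrap = 200, n_partitions = 100,
                    n_calibrators = 10)
print(run$qc)
#> <qc_report> 86 samples retained (2 excluded by spike-in filter, 2 by percentile filter); 100 detectable probes
print(run$normalizer)
#> <normalizer_set> miR-0028, miR-0090, miR-0052
print(run$cv)
#> <cv_report> 1000 fold-models; chosen k = 21 (mean misclassifications 0.049)
print(run$training_eval)
#> <confusion_report> sens 100.0% (57/57), spec 100.0% (29/29), acc 100.0%

va_cfg <- simulation_config(n_case = 30, n_control = 20, n_probes = 100,
                            n_spike_failures = c(case = 0, control = 0),
                            n_lowquality = c(case = 0, control = 0),
                            n_calibrators = 0, seed = 12)
va <- generate_cohort(va_cfg, "VALIDATION", population = train$truth$population)
vr <- run_validation(run, va$ct, va$metadata)
print(vr$roc)
#> <roc_report> AUC 1.000 over 52 thresholds
head(vr$calls, 3)
#> # A tibble: 3 × 3
#>   sample       vote_sum call
#>   <chr>           <dbl> <chr>
#> 1 va_s001_case     4.88 POSITIVE
#> 2 va_s002_case     2.37 POSITIVE
#> 3 va_s003_case     7.09 POSITIVE

# ground truth makes recovery checkable:
length(intersect(run$model$features, train$truth$informative$probe))
#> [1] 18
```

(This demo cohort is deliberately easy — a 1.5-cycle planted effect on 100
probes — so it separates perfectly; the test suite also exercises null and
marginal regimes.)

## Analysis workflow

`analysis/` contains numbered drivers that run a full simulated study and
write tables under `results/`:

```sh
Rscript analysis/01_simulate.R        # cohorts + ground truth
Rscript analysis/02_quality_control.R # exclusions, retained samples
Rscript analysis/03_normalizer.R      # bootstrap stability ranking
Rscript analysis/04_train.R           # CV curve, inclusion table, model
Rscript analysis/05_validate.R        # frozen-parameter validation report
```

## License

MIT (see `LICENSE`).
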