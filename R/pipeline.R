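#' Run the full training pipeline
#'
#' Executes the classifier-construction stages in their fixed order on a
#' training cohort: QC (spike-in filter, detectability screen, percentile
#' filter) -> normalizer candidate screen -> bootstrap stability ranking and
#' top-k normalizer selection -> normalization fit (calibrator means,
#' training mean/SD) -> candidate-feature screen -> repeated stratified
#' 10-fold cross-validation -> inclusion-frequency finalization -> training
#' cohort evaluation. Every stochastic stage derives its substream from the
#' single `seed`, so the run is exactly reproducible; the returned manifest
#' records the exclusion bookkeeping and parameter fingerprints.
#'
#' @param ct Raw training [ct_matrix()].
#' @param metadata Metadata tibble covering its samples.
#' @param spike_probe Spike-in probe id.
#' @param seed Integer top-level seed.
#' @param percentile_q,percentile_cutoff QC percentile filter knobs.
#' @param n_bootstrap Bootstrap replicates for normalizer ranking.
#' @param top_k_normalizers Size of the normalizer set; default 3.
#' @param n_calibrators Calibrator samples for the delta-delta-Ct anchor.
#' @param min_case_fraction Candidate-feature detectability fraction.
#' @param k_grid,n_folds,n_partitions Cross-validation knobs.
#' @param ceiling Imputation ceiling (cycles) for undetected reactions.
#' @return A list of class `training_run` with elements `qc`, `stability`,
#'   `normalizer`, `params`, `candidate_features`, `cv`, `model`, `z`,
#'   `training_calls`, `training_eval`, `training_roc`, `manifest`.
#' @export
run_training <- function(ct, metadata, spike_probe, seed,
                         percentile_q = 25, percentile_cutoff = 32,
                         n_bootstrap = 10000, top_k_normalizers = 3,
                         n_calibrators = 22, min_case_fraction = 0.10,
                         k_grid = 2:50, n_folds = 10, n_partitions = 10000,
                         ceiling = 40) {
  qc <- run_qc(ct, spike_probe, q = percentile_q, cutoff = percentile_cutoff,
               ceiling = ceiling)
  x <- ct_subset(qc$matrix, probes = qc$detectable_probes)
  grp <- group_vector(x, metadata)
  cand <- candidate_normalizers(x)
  stab <- bootstrap_stability(ct_subset(x, probes = cand), grp,
                              n_bootstrap = n_bootstrap,
                              seed = substream_seed(seed, "bootstrap"))
  normalizer <- select_normalizer(stab, k = top_k_normalizers)
  params <- fit_normalization(x, metadata, normalizer,
                              n_calibrators = n_calibrators, seed = seed,
                              ceiling = ceiling)
  z <- zscore(x, params)
  feats <- candidate_features(x, metadata, min_fraction = min_case_fraction,
                              exclude = normalizer$probes)
  feats <- intersect(colnames(z), feats)
  cv <- cross_validate(z[, feats, drop = FALSE], grp, k_grid = k_grid,
                       n_folds = n_folds, n_partitions = n_partitions,
                       seed = substream_seed(seed, "cv"))
  model <- finalize_voting(z[, feats, drop = FALSE], grp, cv)
  calls <- stats::predict(model, z)
  ev <- confusion_metrics(calls, metadata)
  roc <- roc_auc(calls$vote_sum, grp)
  manifest <- list(
    seed = seed,
    n_input_samples = nrow(ct$ct),
    excluded_spike = qc$excluded_spike,
    excluded_percentile = qc$excluded_percentile,
    n_retained = length(qc$retained),
    n_detectable_probes = length(qc$detectable_probes),
    n_normalizer_candidates = length(cand),
    normalizer = normalizer$probes,
    n_candidate_features = length(feats),
    chosen_k = cv$chosen_k,
    params_hash = attr(z, "params_hash"),
    model_hash = fingerprint(unclass(model))
  )
  structure(list(qc = qc, stability = stab, normalizer = normalizer,
                 params = params, candidate_features = feats, cv = cv,
                 model = model, z = z, training_calls = calls,
                 training_eval = ev, training_roc = roc, manifest = manifest),
            class = "training_run")
}

#' @export
print.training_run <- function(x, ...) {
  cat(sprintf(paste0(
    "<training_run> %d/%d samples retained; normalizer {%s}; k = %d features; ",
    "training sens %.1f%%, spec %.1f%%, AUC %.3f\n"),
    x$manifest$n_retained, x$manifest$n_input_samples,
    paste(x$normalizer$probes, collapse = ", "), x$cv$chosen_k,
    100 * x$training_eval$sensitivity, 100 * x$training_eval$specificity,
    x$training_roc$auc))
  invisible(x)
}

#' Apply a frozen training run to a validation cohort
#'
#' Normalizes the validation Ct matrix with the *frozen* training parameters
#' (nothing is refit), scores every sample with the final model, and reports
#' sensitivity/specificity over cases vs the designated negative groups, ROC
#' over the vote sums of those samples, and positivity panels for the other
#' groups and the requested strata.
#'
#' @param run A `training_run`.
#' @param ct Validation [ct_matrix()].
#' @param metadata Metadata tibble for the validation samples.
#' @param negative_groups Groups pooled as truly negative for specificity;
#'   default `"CONTROL"` plus `OTHER:BPD` when present (benign pulmonary
#'   disease pools with healthy controls); other `OTHER:` groups are reported
#'   only as positivity panels.
#' @param stratify_by Metadata columns for positivity stratification.
#' @return A list of class `validation_report`: `calls`, `eval`, `roc`,
#'   `positivity` (one tibble per stratification), `group_positivity`,
#'   `params_hash`.
#' @export
run_validation <- function(run, ct, metadata,
                           negative_groups = NULL, stratify_by = "stage") {
  stopifnot(inherits(run, "training_run"))
  grp_all <- group_vector(ct, metadata)
  if (is.null(negative_groups)) {
    negative_groups <- c("CONTROL", intersect("OTHER:BPD", unique(grp_all)))
  }
  # score only probes the frozen parameters know about (a validation card may
  # carry extra probes, e.g. its own spike-in)
  known <- c(run$params$normalizer, names(run$params$calibrator_mean))
  z <- zscore(ct_subset(ct, probes = intersect(probes(ct), known)), run$params)
  stopifnot(identical(attr(z, "params_hash"), run$manifest$params_hash))
  calls <- stats::predict(run$model, z)
  ev <- confusion_metrics(calls, metadata, negative_groups = negative_groups)
  in_roc <- grp_all == "CASE" | grp_all %in% negative_groups
  roc <- roc_auc(calls$vote_sum[in_roc], grp_all[in_roc])
  positivity <- lapply(stratify_by, function(field) {
    keep <- grp_all == "CASE"
    stratified_positivity(calls[keep, , drop = FALSE], metadata, field)
  })
  names(positivity) <- stratify_by
  group_positivity <- stratified_positivity(calls, metadata, "group")
  structure(list(calls = calls, eval = ev, roc = roc, positivity = positivity,
                 group_positivity = group_positivity,
                 params_hash = attr(z, "params_hash")),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("<validation_report> sens %.1f%% (%d/%d), spec %.1f%% (%d/%d), AUC %.3f\n",
              100 * x$eval$sensitivity, x$eval$tp, x$eval$tp + x$eval$fn,
              100 * x$eval$specificity, x$eval$tn, x$eval$tn + x$eval$fp,
              x$roc$auc))
  invisible(x)
}
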