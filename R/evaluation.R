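#' Confusion metrics for diagnostic calls
#'
#' Tallies a prediction table against truth labels: CASE samples are the
#' positive class; CONTROL and any `OTHER:` groups listed in
#' `negative_groups` are negatives. Groups not routed to either class (e.g.
#' other-cancer panels) are excluded here and should be reported via
#' [stratified_positivity()] instead. Counts are exact integers; proportions
#' are derived from them and never stored independently.
#'
#' @param calls Tibble with `sample` and `call` (`"POSITIVE"`/`"NEGATIVE"`),
#'   as returned by [predict.voting_model()].
#' @param metadata Metadata tibble with truth groups.
#' @param negative_groups Group labels counted as truly negative; default
#'   `"CONTROL"` plus every `OTHER:` group present (benign disease pools with
#'   healthy controls for combined specificity).
#' @return A list of class `confusion_report`: `tp`, `fn`, `tn`, `fp`,
#'   `sensitivity`, `specificity`, `accuracy`, `n_excluded`.
#' @export
confusion_metrics <- function(calls, metadata, negative_groups = NULL) {
  idx <- match(calls$sample, metadata$sample_id)
  if (anyNA(idx)) {
    stop_mirvote("mirvote_integrity_error", "call(s) without a truth label: %s",
                 paste(calls$sample[is.na(idx)], collapse = ", "))
  }
  grp <- metadata$group[idx]
  if (is.null(negative_groups)) {
    negative_groups <- unique(c("CONTROL", grep("^OTHER:", grp, value = TRUE)))
  }
  pos_call <- calls$call == "POSITIVE"
  is_case <- grp == "CASE"
  is_neg <- grp %in% negative_groups
  tp <- sum(is_case & pos_call); fn <- sum(is_case & !pos_call)
  fp <- sum(is_neg & pos_call); tn <- sum(is_neg & !pos_call)
  structure(list(
    tp = tp, fn = fn, tn = tn, fp = fp,
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    accuracy = if (tp + fn + tn + fp > 0) (tp + tn) / (tp + fn + tn + fp) else NA_real_,
    n_excluded = sum(!is_case & !is_neg)
  ), class = "confusion_report")
}

#' @export
print.confusion_report <- function(x, ...) {
  cat(sprintf("<confusion_report> sens %.1f%% (%d/%d), spec %.1f%% (%d/%d), acc %.1f%%\n",
              100 * x$sensitivity, x$tp, x$tp + x$fn,
              100 * x$specificity, x$tn, x$tn + x$fp, 100 * x$accuracy))
  invisible(x)
}

#' ROC curve and AUC from continuous scores
#'
#' Builds the ROC curve over all distinct score thresholds (call POSITIVE iff
#' score > threshold) and computes the AUC by the trapezoidal rule, which
#' equals the tie-corrected concordance probability
#' `P(score_case > score_control) + 0.5 P(equal)`.
#'
#' @param scores Numeric vector (e.g. vote sums), higher = more case-like.
#' @param truth Logical or label vector; `TRUE`/`"CASE"` marks positives.
#' @return A list of class `roc_report`: `roc` (tibble with `threshold`,
#'   `sensitivity`, `fpr`, from (0,0) to (1,1)) and `auc`.
#' @export
roc_auc <- function(scores, truth) {
  if (is.character(truth) || is.factor(truth)) truth <- as.character(truth) == "CASE"
  stopifnot(length(scores) == length(truth), all(is.finite(scores)))
  n_pos <- sum(truth); n_neg <- sum(!truth)
  if (n_pos == 0 || n_neg == 0) {
    stop_mirvote("mirvote_grouping_error", "ROC needs both classes present")
  }
  thr <- sort(unique(scores), decreasing = TRUE)
  sens <- vapply(thr, function(t) sum(scores > t & truth) / n_pos, numeric(1))
  fpr <- vapply(thr, function(t) sum(scores > t & !truth) / n_neg, numeric(1))
  roc <- tibble::tibble(
    threshold = c(Inf, thr),
    sensitivity = c(0, sens),
    fpr = c(0, fpr)
  )
  # the lowest threshold already yields (1,1) because calls use strict ">"
  # against thresholds below the minimum; append it explicitly
  roc <- rbind(roc, tibble::tibble(threshold = -Inf, sensitivity = 1, fpr = 1))
  roc <- unique(roc)
  auc <- sum(diff(roc$fpr) * (utils::head(roc$sensitivity, -1) + utils::tail(roc$sensitivity, -1)) / 2)
  structure(list(roc = roc, auc = auc), class = "roc_report")
}

#' @export
print.roc_report <- function(x, ...) {
  cat(sprintf("<roc_report> AUC %.3f over %d thresholds\n", x$auc, nrow(x$roc)))
  invisible(x)
}

#' Positivity rates by stratum
#'
#' Per-stratum counts of POSITIVE calls — how the paper-style panels
#' (disease stage, histology, other-cancer type) are reported. Strata with no
#' samples are omitted.
#'
#' @inheritParams confusion_metrics
#' @param stratify_by Metadata column to stratify on (`"stage"`,
#'   `"histology"`, or `"group"`).
#' @return Tibble with `stratum`, `n_positive`, `n_total`, `rate`.
#' @export
stratified_positivity <- function(calls, metadata, stratify_by = "stage") {
  if (!stratify_by %in% names(metadata)) {
    stop_mirvote("mirvote_config_error", "unknown stratification field '%s'", stratify_by)
  }
  idx <- match(calls$sample, metadata$sample_id)
  if (anyNA(idx)) {
    stop_mirvote("mirvote_integrity_error", "call(s) without metadata")
  }
  strat <- as.character(metadata[[stratify_by]][idx])
  keep <- !is.na(strat)
  pos <- calls$call[keep] == "POSITIVE"
  strat <- strat[keep]
  lev <- unique(strat)
  tibble::tibble(
    stratum = lev,
    n_positive = vapply(lev, function(l) sum(pos[strat == l]), integer(1),
                        USE.NAMES = FALSE),
    n_total = vapply(lev, function(l) sum(strat == l), integer(1),
                     USE.NAMES = FALSE)
  ) |> transform_rate()
}

transform_rate <- function(df) {
  df$rate <- df$n_positive / df$n_total
  df
}

#' Compare cohort characteristics between training and validation sets
#'
#' The standard balance table: two-sided Student's t-test (equal variances)
#' for numeric covariates, Fisher's exact test for 2-level categorical ones.
#'
#' @param train,validation Data frames of per-sample covariates.
#' @param numeric_vars,categorical_vars Column names to test.
#' @param alpha Two-sided significance level reported alongside; default
#'   0.05.
#' @return Tibble with `variable`, `test`, `statistic`, `p_value`,
#'   `significant`.
#' @export
cohort_compare <- function(train, validation, numeric_vars = character(),
                           categorical_vars = character(), alpha = 0.05) {
  rows <- list()
  for (v in numeric_vars) {
    a <- stats::na.omit(train[[v]]); b <- stats::na.omit(validation[[v]])
    tt <- stats::t.test(a, b, var.equal = TRUE)
    rows[[length(rows) + 1]] <- tibble::tibble(
      variable = v, test = "t", statistic = unname(tt$statistic), p_value = tt$p.value)
  }
  for (v in categorical_vars) {
    tab <- table(
      cohort = rep(c("train", "validation"), c(nrow(train), nrow(validation))),
      value = c(as.character(train[[v]]), as.character(validation[[v]]))
    )
    ft <- stats::fisher.test(tab)
    rows[[length(rows) + 1]] <- tibble::tibble(
      variable = v, test = "fisher", statistic = NA_real_, p_value = ft$p.value)
  }
  out <- do.call(rbind, rows)
  out$significant <- out$p_value < alpha
  out
}
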