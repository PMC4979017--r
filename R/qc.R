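#' Spike-in sample filter
#'
#' Removes samples in which the exogenous spike-in control probe (plant
#' miRNA added before RNA extraction, e.g. ath-miR-159a) was not detected:
#' its failure flags a failed extraction, not biology. The spike probe column
#' is dropped from the surviving matrix.
#'
#' @param x A [ct_matrix()].
#' @param spike_probe Identifier of the spike-in probe.
#' @return A list with `matrix` (filtered `ct_matrix` without the spike
#'   column) and `excluded_spike` (character vector of removed sample ids).
#' @export
filter_spike_in <- function(x, spike_probe) {
  stopifnot(inherits(x, "ct_matrix"))
  if (!spike_probe %in% probes(x)) {
    stop_mirvote("mirvote_config_error", "spike probe '%s' absent from matrix", spike_probe)
  }
  ok <- detected(x)[, spike_probe]
  keep <- samples(x)[ok]
  list(
    matrix = ct_subset(x, samples = keep, probes = setdiff(probes(x), spike_probe)),
    excluded_spike = samples(x)[!ok]
  )
}

#' Probes detected in at least one sample
#'
#' The detectability screen: probes with a finite Ct below the detection
#' limit in at least one sample. Input probe order is preserved.
#'
#' @param x A [ct_matrix()].
#' @return Character vector of probe ids.
#' @export
detectable_probes <- function(x) {
  stopifnot(inherits(x, "ct_matrix"), nrow(x$ct) > 0)
  probes(x)[colSums(detected(x)) >= 1]
}

#' Per-sample percentile filter
#'
#' For each sample, computes the `q`-th percentile of its Ct values over the
#' given probe list and removes samples whose percentile is at or above
#' `cutoff` cycles: if even the best quartile of a sample's reactions sits at
#' the detection limit, the sample carried too little RNA to profile.
#' Undetected reactions enter the percentile at `ceiling` cycles (the maximum
#' PCR cycle), so fully failed samples are guaranteed exclusion.
#'
#' @param x A [ct_matrix()].
#' @param probes Probe ids over which the percentile is computed (typically
#'   the frozen detectable-probe list).
#' @param q Percentile in `[0, 100]`; default 25.
#' @param cutoff Cycles; samples with percentile `>= cutoff` are removed.
#' @param ceiling Cycles imputed for undetected reactions; default 40.
#' @param type Quantile definition passed to [stats::quantile()]; default 7
#'   (linear interpolation between closest ranks).
#' @return A list with `matrix` (filtered `ct_matrix`), `excluded_percentile`
#'   (removed sample ids) and `sample_percentiles` (named numeric, all input
#'   samples).
#' @export
percentile_filter <- function(x, probes, q = 25, cutoff = 32, ceiling = 40, type = 7) {
  stopifnot(inherits(x, "ct_matrix"))
  if (length(probes) == 0) {
    stop_mirvote("mirvote_config_error", "percentile filter needs a nonempty probe list")
  }
  sub <- ct_subset(x, probes = probes)
  vals <- sub$ct
  vals[is.na(vals)] <- ceiling
  pct <- apply(vals, 1, stats::quantile, probs = q / 100, type = type, names = FALSE)
  names(pct) <- samples(x)
  keep <- samples(x)[pct < cutoff]
  list(
    matrix = ct_subset(x, samples = keep),
    excluded_percentile = samples(x)[pct >= cutoff],
    sample_percentiles = pct
  )
}

#' Run the full QC stage
#'
#' Applies, in this fixed order: the spike-in filter; the detectability
#' screen on the survivors (the resulting probe list is frozen for reuse on
#' validation data); the per-sample percentile filter over those probes.
#'
#' @inheritParams filter_spike_in
#' @inheritParams percentile_filter
#' @return A list of class `qc_report`: `matrix` (the QC'd `ct_matrix`),
#'   `excluded_spike`, `excluded_percentile`, `retained`,
#'   `detectable_probes`, `sample_percentiles`.
#' @export
run_qc <- function(x, spike_probe, q = 25, cutoff = 32, ceiling = 40) {
  st <- filter_spike_in(x, spike_probe)
  det <- detectable_probes(st$matrix)
  if (length(det) == 0) {
    stop_mirvote("mirvote_config_error", "no detectable probes after spike filter")
  }
  pf <- percentile_filter(st$matrix, det, q = q, cutoff = cutoff, ceiling = ceiling)
  out <- list(
    matrix = pf$matrix,
    excluded_spike = st$excluded_spike,
    excluded_percentile = pf$excluded_percentile,
    retained = samples(pf$matrix),
    detectable_probes = det,
    sample_percentiles = pf$sample_percentiles
  )
  class(out) <- "qc_report"
  out
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf(paste0(
    "<qc_report> %d samples retained (%d excluded by spike-in filter, ",
    "%d by percentile filter); %d detectable probes\n"),
    length(x$retained), length(x$excluded_spike), length(x$excluded_percentile),
    length(x$detectable_probes)))
  invisible(x)
}
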