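#' Per-sample normalizer value
#'
#' The arithmetic mean of the normalizer probes' Ct values in each sample —
#' the internal-control level against which every target probe is expressed.
#' An undetected normalizer probe (rare by construction, since normalizers
#' are detected in all training samples) is imputed at `ceiling` with a
#' warning.
#'
#' @param x A [ct_matrix()].
#' @param normalizer A `normalizer_set` (or character vector of probe ids).
#' @param ceiling Cycles imputed for an undetected normalizer reaction.
#' @return Named numeric vector, one value (cycles) per sample.
#' @export
normalizer_value <- function(x, normalizer, ceiling = 40) {
  ids <- if (inherits(normalizer, "normalizer_set")) normalizer$probes else normalizer
  missing <- setdiff(ids, probes(x))
  if (length(missing)) {
    stop_mirvote("mirvote_config_error", "normalizer probe(s) absent from matrix: %s",
                 paste(missing, collapse = ", "))
  }
  sub <- x$ct[, ids, drop = FALSE]
  if (anyNA(sub)) {
    warning(sprintf("%d undetected normalizer reaction(s) imputed at %g cycles",
                    sum(is.na(sub)), ceiling))
    sub[is.na(sub)] <- ceiling
  }
  rowMeans(sub)
}

# delta-Ct grid: target Ct (undetected imputed at ceiling) minus the
# per-sample normalizer value; probes is the target set (normalizers excluded)
delta_ct_grid <- function(x, normalizer, target_probes, ceiling = 40) {
  nv <- normalizer_value(x, normalizer, ceiling = ceiling)
  m <- x$ct[, target_probes, drop = FALSE]
  m[is.na(m)] <- ceiling
  m - nv
}

#' Fit normalization parameters on the training cohort
#'
#' Freezes everything needed to place any future sample on the training
#' z-score scale: (1) per-probe calibrator means — the mean delta-Ct of the
#' designated calibrator samples, the anchor that makes delta-delta-Ct
#' comparable across platforms/cards; (2) per-probe mean and SD of
#' delta-delta-Ct across *all* training samples, defining the z-transform.
#' Calibrators are taken from `is_calibrator` flags when present, otherwise
#' drawn at random (seeded) from the training samples. Probes with zero
#' training variance are flagged and excluded from modeling rather than
#' silently zeroed.
#'
#' @param x Training [ct_matrix()] (QC'd).
#' @param metadata Metadata tibble covering the samples of `x`.
#' @param normalizer A `normalizer_set`.
#' @param n_calibrators Number of calibrator samples when drawing at random;
#'   default 22.
#' @param seed Integer seed for the random calibrator draw (ignored when
#'   flags are present).
#' @param ceiling Imputation ceiling (cycles) for undetected reactions.
#' @return A `normalization_params` object.
#' @export
fit_normalization <- function(x, metadata, normalizer, n_calibrators = 22,
                              seed = NULL, ceiling = 40) {
  stopifnot(inherits(x, "ct_matrix"))
  ids <- if (inherits(normalizer, "normalizer_set")) normalizer$probes else normalizer
  target <- setdiff(probes(x), ids)
  idx <- match(samples(x), metadata$sample_id)
  if (anyNA(idx)) {
    stop_mirvote("mirvote_integrity_error", "sample(s) without metadata: %s",
                 paste(samples(x)[is.na(idx)], collapse = ", "))
  }
  flags <- metadata$is_calibrator[idx]
  if (any(flags)) {
    if (sum(flags) < n_calibrators) {
      stop_mirvote("mirvote_config_error", "only %d calibrator(s) flagged, %d requested",
                   sum(flags), n_calibrators)
    }
    calibrators <- samples(x)[flags]
  } else {
    if (n_calibrators > nrow(x$ct)) {
      stop_mirvote("mirvote_config_error", "n_calibrators exceeds training size")
    }
    if (is.null(seed)) {
      stop_mirvote("mirvote_config_error",
                   "seed required to draw calibrators when no is_calibrator flags are set")
    }
    set.seed(substream_seed(seed, "calibrators"))
    calibrators <- sort(sample(samples(x), n_calibrators))
  }
  dct <- delta_ct_grid(x, normalizer, target, ceiling = ceiling)
  calibrator_mean <- colMeans(dct[calibrators, , drop = FALSE])
  ddct <- sweep(dct, 2, calibrator_mean)
  mu <- colMeans(ddct)
  sd <- apply(ddct, 2, stats::sd)
  zero_var <- names(sd)[sd < 1e-12]
  if (length(zero_var)) {
    warning(sprintf("%d zero-variance probe(s) flagged and excluded from modeling: %s",
                    length(zero_var), paste(zero_var, collapse = ", ")))
  }
  out <- list(
    normalizer = ids,
    calibrators = calibrators,
    calibrator_mean = calibrator_mean,
    mu = mu,
    sd = sd,
    zero_variance = zero_var,
    detection_limit = x$detection_limit,
    ceiling = ceiling
  )
  class(out) <- "normalization_params"
  out
}

#' @export
print.normalization_params <- function(x, ...) {
  cat(sprintf("<normalization_params> normalizer {%s}; %d calibrators; %d probes (%d zero-variance)\n",
              paste(x$normalizer, collapse = ", "), length(x$calibrators),
              length(x$mu), length(x$zero_variance)))
  invisible(x)
}

#' Delta-delta-Ct values under frozen parameters
#'
#' `deltaCt(s, p) = Ct(s, p) - normalizer_value(s)`;
#' `deltadeltaCt = deltaCt - calibrator_mean(p)`. Values stay on the Ct
#' scale (higher = less abundant); no fold-change transform is applied, since
#' the classifier consumes z-scores where only relative direction matters.
#'
#' @param x A [ct_matrix()].
#' @param params A `normalization_params` object.
#' @return Numeric sample-by-probe matrix of delta-delta-Ct (cycles).
#' @export
delta_delta_ct <- function(x, params) {
  stopifnot(inherits(params, "normalization_params"))
  target <- intersect(probes(x), names(params$calibrator_mean))
  missing <- setdiff(setdiff(probes(x), params$normalizer), target)
  if (length(missing)) {
    stop_mirvote("mirvote_config_error", "probe(s) lacking a calibrator mean: %s",
                 paste(missing, collapse = ", "))
  }
  dct <- delta_ct_grid(x, params$normalizer, target, ceiling = params$ceiling)
  sweep(dct, 2, params$calibrator_mean[target])
}

#' Z-score expression matrix under frozen training parameters
#'
#' `z = (deltadeltaCt - training mean) / training SD` per probe. Applied to
#' the training matrix itself this yields per-probe mean 0 and SD 1; applied
#' to validation data the parameters are reused untouched (no refitting).
#' Zero-variance probes flagged at fit time are excluded from the output.
#'
#' @inheritParams delta_delta_ct
#' @return An `expression_matrix`: numeric sample-by-probe matrix of
#'   dimensionless z-scores, finite everywhere, with attribute `params_hash`
#'   fingerprinting the frozen parameters.
#' @export
zscore <- function(x, params) {
  ddct <- delta_delta_ct(x, params)
  keep <- setdiff(colnames(ddct), params$zero_variance)
  z <- sweep(sweep(ddct[, keep, drop = FALSE], 2, params$mu[keep]),
             2, params$sd[keep], "/")
  stopifnot(all(is.finite(z)))
  structure(z, params_hash = fingerprint(unclass(params)),
            class = c("expression_matrix", class(z)))
}
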