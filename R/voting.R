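#' Candidate diagnostic features
#'
#' Probes eligible for classifier construction: detected (finite Ct below the
#' detection limit) in at least a minimum fraction of the CASE samples of the
#' training cohort. Normalizer probes are excluded — a reference miRNA must
#' not also vote.
#'
#' @param x Training [ct_matrix()] (QC'd).
#' @param metadata Metadata tibble covering the samples of `x`.
#' @param min_fraction Minimum fraction of CASE samples in which a probe must
#'   be detected; default 0.10.
#' @param exclude Probe ids to exclude (typically the normalizer set).
#' @return Character vector of probe ids, input order preserved.
#' @export
candidate_features <- function(x, metadata, min_fraction = 0.10, exclude = character()) {
  grp <- group_vector(x, metadata)
  if (!any(grp == "CASE")) {
    stop_mirvote("mirvote_grouping_error", "no CASE samples in training matrix")
  }
  det <- detected(x)[grp == "CASE", , drop = FALSE]
  frac <- colMeans(det)
  setdiff(probes(x)[frac >= min_fraction], exclude)
}

# per-class means and n-1 SDs of a z-score matrix; rows split by CASE label
class_moments <- function(z, labels) {
  is_case <- labels == "CASE"
  if (sum(is_case) < 2 || sum(!is_case) < 2) {
    stop_mirvote("mirvote_grouping_error", "each class needs >= 2 samples")
  }
  zc <- z[is_case, , drop = FALSE]
  zh <- z[!is_case, , drop = FALSE]
  list(
    mu_case = colMeans(zc), mu_control = colMeans(zh),
    sd_case = sqrt(colSums(sweep(zc, 2, colMeans(zc))^2) / (nrow(zc) - 1)),
    sd_control = sqrt(colSums(sweep(zh, 2, colMeans(zh))^2) / (nrow(zh) - 1))
  )
}

#' Signal-to-noise ratio per feature
#'
#' The weighted-voting weight:
#' `S2N(g) = (mu_case(g) - mu_control(g)) / (sd_case(g) + sd_control(g))`,
#' with sample SDs (n-1 denominator). The denominator is floored at `floor`
#' (z-score units) so degenerate folds cannot produce infinite weights;
#' flooring is reported when triggered.
#'
#' @param z Numeric sample-by-feature matrix (z-scores).
#' @param labels Vector aligned with rows of `z`; `"CASE"` vs anything else.
#' @param floor Minimum denominator; default 1e-6.
#' @return Named numeric vector of S2N values.
#' @export
s2n <- function(z, labels, floor = 1e-6) {
  m <- class_moments(z, labels)
  den <- m$sd_case + m$sd_control
  if (any(den < floor)) {
    message(sprintf("S2N denominator floored for %d feature(s)", sum(den < floor)))
    den <- pmax(den, floor)
  }
  (m$mu_case - m$mu_control) / den
}

#' Train a weighted-voting model
#'
#' Stores, per feature, the signal-to-noise weight `w` and the decision
#' boundary `b` — the midpoint of the class means. A sample's vote on feature
#' `g` is `w_g * (x_g - b_g)`; the call is POSITIVE iff the vote sum exceeds
#' `threshold` (default 0, since each `b` already centers its feature between
#' the classes).
#'
#' @inheritParams s2n
#' @param features Feature (probe) ids to include, in order.
#' @param threshold Decision threshold on the vote sum; default 0.
#' @param floor S2N denominator floor.
#' @return A `voting_model`.
#' @export
train_voting <- function(z, labels, features, threshold = 0, floor = 1e-6) {
  missing <- setdiff(features, colnames(z))
  if (length(missing)) {
    stop_mirvote("mirvote_config_error", "feature(s) absent from z matrix: %s",
                 paste(missing, collapse = ", "))
  }
  zs <- z[, features, drop = FALSE]
  m <- class_moments(zs, labels)
  w <- s2n(zs, labels, floor = floor)
  out <- list(
    features = features,
    w = w,
    b = (m$mu_case + m$mu_control) / 2,
    mu_case = m$mu_case, mu_control = m$mu_control,
    sd_case = m$sd_case, sd_control = m$sd_control,
    threshold = threshold
  )
  class(out) <- "voting_model"
  out
}

#' @export
print.voting_model <- function(x, ...) {
  cat(sprintf("<voting_model> %d features, vote-sum threshold %g\n",
              length(x$features), x$threshold))
  invisible(x)
}

#' Score samples with a weighted-voting model
#'
#' @param object A `voting_model`.
#' @param z Numeric sample-by-feature matrix containing every model feature.
#' @param ... Unused.
#' @return A tibble with `sample`, `vote_sum` and `call`
#'   (`"POSITIVE"`/`"NEGATIVE"`); attribute `votes` holds the per-feature
#'   vote matrix.
#' @export
predict.voting_model <- function(object, z, ...) {
  missing <- setdiff(object$features, colnames(z))
  if (length(missing)) {
    stop_mirvote("mirvote_scoring_error", "z matrix lacks model feature(s): %s",
                 paste(missing, collapse = ", "))
  }
  zs <- z[, object$features, drop = FALSE]
  votes <- sweep(sweep(zs, 2, object$b), 2, object$w, "*")
  v <- unname(rowSums(votes))
  out <- tibble::tibble(
    sample = rownames(z) %||% as.character(seq_len(nrow(z))),
    vote_sum = v,
    call = ifelse(v > object$threshold, "POSITIVE", "NEGATIVE")
  )
  attr(out, "votes") <- votes
  out
}

#' Repeated stratified k-fold cross-validation for feature-count selection
#'
#' For each of `n_partitions` random partitions, samples are assigned to
#' `n_folds` class-stratified folds; each fold-model ranks features by |S2N|
#' on its training nine-tenths, builds weighted-voting models at every
#' feature count in `k_grid` and counts misclassifications on the held-out
#' fold. Feature selection thus happens *inside* every fold, so the held-out
#' error is an honest estimate. The chosen feature count minimizes the mean
#' per-fold-model misclassification count (smallest count on a tie), and
#' per-feature inclusion frequencies — in how many of the
#' `n_partitions * n_folds` fold-models the feature ranked in the chosen
#' top-k — are tallied at that count.
#'
#' @inheritParams s2n
#' @param k_grid Candidate feature counts; default `2:50`.
#' @param n_folds Folds per partition; default 10.
#' @param n_partitions Number of random partitions; default 10000.
#' @param seed Integer seed; partition `p` uses a deterministic substream.
#' @return A `cv_report`: list with `k_grid`, `mean_misclassification` (per
#'   k), `chosen_k`, `inclusion` (tibble: `feature`, `n_included`,
#'   `mean_rank`), `n_models`, `provenance`.
#' @export
cross_validate <- function(z, labels, k_grid = 2:50, n_folds = 10,
                           n_partitions = 10000, seed) {
  stopifnot(length(k_grid) >= 1, n_folds >= 2, n_partitions >= 1)
  nfeat <- ncol(z)
  k_grid <- sort(unique(pmin(k_grid, nfeat)))
  kmax <- max(k_grid)
  is_case <- labels == "CASE"
  n <- nrow(z)
  feat_ids <- colnames(z)
  n_models <- n_partitions * n_folds
  total_err <- setNames(numeric(length(k_grid)), k_grid)
  rank_store <- matrix(NA_integer_, n_models, kmax)
  model_i <- 0L
  regenerated <- 0L
  for (p in seq_len(n_partitions)) {
    repeat {
      set.seed(substream_seed(seed, p + regenerated * n_partitions))
      fold <- integer(n)
      for (cls in c(TRUE, FALSE)) {
        idx <- which(is_case == cls)
        fold[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))[seq_along(idx)]
      }
      # with class-stratified folds a one-class training side can only occur
      # in pathological designs; regenerate the partition if it does
      ok <- all(vapply(seq_len(n_folds), function(f) {
        tr <- fold != f
        any(is_case[tr]) && any(!is_case[tr]) && sum(fold == f) > 0
      }, logical(1)))
      if (ok) break
      regenerated <- regenerated + 1L
      if (regenerated > 100L) {
        stop_mirvote("mirvote_grouping_error", "cannot build two-class training folds")
      }
    }
    for (f in seq_len(n_folds)) {
      tr <- fold != f
      mom <- class_moments(z[tr, , drop = FALSE], labels[tr])
      s <- (mom$mu_case - mom$mu_control) / pmax(mom$sd_case + mom$sd_control, 1e-6)
      ranked <- order(-abs(s), feat_ids)[seq_len(kmax)]
      w <- s[ranked]
      b <- (mom$mu_case + mom$mu_control)[ranked] / 2
      zt <- z[!tr, ranked, drop = FALSE]
      votes <- sweep(sweep(zt, 2, b), 2, w, "*")
      vsum <- t(apply(votes, 1, cumsum)) # vote sum at every k = 1..kmax
      if (nrow(zt) == 1) vsum <- matrix(cumsum(votes[1, ]), 1)
      truth <- is_case[!tr]
      for (ki in seq_along(k_grid)) {
        pred <- vsum[, k_grid[ki]] > 0
        total_err[ki] <- total_err[ki] + sum(pred != truth)
      }
      model_i <- model_i + 1L
      rank_store[model_i, ] <- ranked
    }
  }
  if (regenerated > 0) message(sprintf("%d partition(s) regenerated", regenerated))
  mean_err <- total_err / n_models
  chosen_k <- k_grid[which.min(mean_err)] # which.min takes the first (smallest k) on ties
  top <- rank_store[, seq_len(chosen_k), drop = FALSE]
  n_included <- tabulate(top, nbins = nfeat)
  rank_pos <- col(top) # rank of the feature within its fold-model
  rank_sum <- vapply(seq_len(nfeat), function(i) sum(rank_pos[top == i]), numeric(1))
  inclusion <- tibble::tibble(
    feature = feat_ids,
    n_included = n_included,
    mean_rank = ifelse(n_included > 0, rank_sum / n_included, NA_real_)
  )
  structure(list(
    k_grid = k_grid,
    mean_misclassification = setNames(mean_err, k_grid),
    chosen_k = chosen_k,
    inclusion = inclusion,
    n_models = n_models,
    provenance = list(seed = seed, n_partitions = n_partitions, n_folds = n_folds,
                      k_grid = k_grid, regenerated = regenerated)
  ), class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> %d fold-models; chosen k = %d (mean misclassifications %.3f)\n",
              x$n_models, x$chosen_k,
              x$mean_misclassification[as.character(x$chosen_k)]))
  invisible(x)
}

#' Finalize the classifier from cross-validation inclusion frequencies
#'
#' Takes the chosen-k features most frequently included across all
#' fold-models (ties broken by smaller mean rank, then probe id) and trains
#' the final weighted-voting model on the full training cohort with that set.
#'
#' @inheritParams s2n
#' @param cv A `cv_report` from [cross_validate()].
#' @return A `voting_model` whose `features` are ordered by inclusion
#'   frequency.
#' @export
finalize_voting <- function(z, labels, cv) {
  inc <- cv$inclusion
  ord <- order(-inc$n_included, inc$mean_rank, inc$feature)
  feats <- inc$feature[ord][seq_len(cv$chosen_k)]
  train_voting(z, labels, feats)
}
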