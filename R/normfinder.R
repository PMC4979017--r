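#' Candidate reference miRNAs
#'
#' Probes detected (finite Ct below the detection limit) in every sample of a
#' QC'd matrix; only such probes can serve as normalizer candidates, since
#' the stability model tolerates no missing cells.
#'
#' @param x A QC'd [ct_matrix()].
#' @return Character vector of probe ids, input order preserved; empty with a
#'   warning when no probe is universally detected.
#' @export
candidate_normalizers <- function(x) {
  stopifnot(inherits(x, "ct_matrix"))
  out <- probes(x)[colSums(detected(x)) == nrow(x$ct)]
  if (length(out) == 0) {
    warning("no probe is detected in every sample; normalizer selection impossible")
  }
  out
}

#' Model-based reference-gene stability (NormFinder-style)
#'
#' Scores each candidate reference miRNA by a variance-decomposition model of
#' its Ct values across two sample groups: Ct is decomposed into a gene
#' effect, a per-sample effect (shared across genes, absorbing input-amount
#' variation), a gene-by-group interaction `d` (systematic group bias — the
#' enemy of a reference gene) and residual intra-group noise. The estimated
#' interaction is shrunken toward zero by an empirical-Bayes factor (the
#' ratio of its between-gene variance to that variance plus its sampling
#' variance), and the stability of gene *i* is
#' `rho_i = mean over groups of ( |shrunken d_ig| + SE(d_ig) )` —
#' dimensionless on the cycle scale, lower = more stable. Genes that are
#' constant in every sample score exactly 0.
#'
#' @param x A [ct_matrix()] restricted to candidate probes (no undetected
#'   cells among them).
#' @param groups Character/factor vector of group labels aligned with
#'   `samples(x)`, exactly two levels, each with at least 3 samples.
#' @return Named numeric vector of stability values (one per probe).
#' @export
normfinder_stability <- function(x, groups) {
  stopifnot(inherits(x, "ct_matrix"))
  y <- t(x$ct) # genes x samples
  if (anyNA(y)) {
    stop_mirvote("mirvote_value_error",
                 "undetected cells among candidates; apply candidate_normalizers() first")
  }
  if (nrow(y) < 2) {
    stop_mirvote("mirvote_config_error",
                 "stability needs >= 2 candidate genes (the variance decomposition compares genes)")
  }
  g <- as.character(groups)
  stopifnot(length(g) == ncol(y))
  lev <- unique(g)
  if (length(lev) != 2) {
    stop_mirvote("mirvote_grouping_error", "exactly 2 groups required, got %d", length(lev))
  }
  if (any(table(g) < 3)) {
    stop_mirvote("mirvote_grouping_error", "each group needs >= 3 samples")
  }
  n <- nrow(y) # genes
  K <- 2L
  A <- matrix(0, n, K, dimnames = list(rownames(y), lev)) # group means per gene
  V <- matrix(0, n, K) # sampling variance of A
  for (k in seq_len(K)) {
    yg <- y[, g == lev[k], drop = FALSE]
    ng <- ncol(yg)
    A[, k] <- rowMeans(yg)
    # two-way (gene + sample) residuals within the group
    r <- yg - rowMeans(yg) - rep(colMeans(yg), each = n) + mean(yg)
    sigma2 <- rowSums(r^2) * n / ((n - 1) * (ng - 1))
    V[, k] <- sigma2 / ng
  }
  # gene-by-group interaction: group means centered across genes and groups
  d <- A - rowMeans(A) - rep(colMeans(A), each = n) + mean(A)
  # exact sampling variance of d given independent group means:
  # d_ig = sum_{i'g'} (delta_ii' - 1/n)(delta_gg' - 1/K) A_i'g'
  u <- (1 - 1 / K)^2 * V + (1 / K)^2 * (rowSums(V) - V)
  vard <- (1 - 1 / n)^2 * u + (1 / n)^2 * (rep(colSums(u), each = n) - u)
  gamma2 <- max(0, mean(d^2) - mean(vard))
  denom <- gamma2 + vard
  shrunk <- ifelse(denom > 0, d * gamma2 / denom, 0)
  rho <- rowMeans(abs(shrunk) + sqrt(vard))
  names(rho) <- rownames(y)
  rho
}

#' Bootstrap stability ranking of candidate reference miRNAs
#'
#' Resamples samples with replacement within each group (preserving the
#' two-group design and group sizes), recomputes the stability value of every
#' candidate on each replicate, and summarizes each candidate by its median
#' stability across replicates and the rank of that median. Replicates are
#' seeded from deterministic substreams of `seed`, so results are exactly
#' reproducible and independent of evaluation order. Non-finite stability
#' values from degenerate replicates (e.g. a group collapsing onto one
#' repeated sample) are dropped from that candidate's median, with the count
#' reported.
#'
#' @inheritParams normfinder_stability
#' @param n_bootstrap Number of bootstrap replicates; default 10000.
#' @param seed Integer seed.
#' @return A `stability_table`: tibble with columns `probe`,
#'   `median_stability`, `rank`, `n_valid_replicates`, `full_data_stability`
#'   (the stability on the unresampled matrix, also reported since either
#'   summary may be wanted); attribute `provenance` records seed, replicate
#'   count and candidate list, attribute `replicates` the probe-by-replicate
#'   stability matrix.
#' @export
bootstrap_stability <- function(x, groups, n_bootstrap = 10000, seed) {
  stopifnot(inherits(x, "ct_matrix"), n_bootstrap >= 1)
  g <- as.character(groups)
  lev <- unique(g)
  idx_by_group <- lapply(lev, function(l) which(g == l))
  p <- probes(x)
  reps <- matrix(NA_real_, length(p), n_bootstrap, dimnames = list(p, NULL))
  for (r in seq_len(n_bootstrap)) {
    set.seed(substream_seed(seed, r))
    idx <- unlist(lapply(idx_by_group, function(ii) sample(ii, length(ii), replace = TRUE)))
    xm <- ct_matrix(x$ct[idx, , drop = FALSE] |> unname_rows_unique(),
                    x$detection_limit)
    reps[, r] <- tryCatch(normfinder_stability(xm, g[idx]),
                          error = function(e) rep(NA_real_, length(p)))
  }
  med <- apply(reps, 1, stats::median, na.rm = TRUE)
  n_valid <- rowSums(is.finite(reps))
  ord <- order(med, p)
  rank <- integer(length(p))
  rank[ord] <- seq_along(p)
  full <- normfinder_stability(x, g)
  out <- tibble::tibble(
    probe = p,
    median_stability = unname(med),
    rank = rank,
    n_valid_replicates = unname(n_valid),
    full_data_stability = unname(full[p])
  )
  attr(out, "provenance") <- list(seed = seed, n_bootstrap = n_bootstrap, candidates = p)
  attr(out, "replicates") <- reps
  class(out) <- c("stability_table", class(out))
  out
}

# bootstrap draws repeat samples; give repeated rows unique names so the
# ct_matrix invariant (unique sample ids) holds without changing the data
unname_rows_unique <- function(m) {
  rownames(m) <- sprintf("bs%04d.%s", seq_len(nrow(m)), rownames(m))
  m
}

#' Select the normalizer set
#'
#' The `k` candidates with the smallest median bootstrap stability; an exact
#' tie at the boundary is broken by lexicographic probe id (and reported via
#' a message).
#'
#' @param table A `stability_table` from [bootstrap_stability()].
#' @param k Number of reference miRNAs; default 3.
#' @return A `normalizer_set`: list with `probes` (ordered ids) and
#'   `provenance`.
#' @export
select_normalizer <- function(table, k = 3) {
  if (k > nrow(table)) {
    stop_mirvote("mirvote_config_error", "k = %d exceeds %d candidates", k, nrow(table))
  }
  ord <- order(table$median_stability, table$probe)
  sel <- ord[seq_len(k)]
  if (k < nrow(table) &&
      isTRUE(table$median_stability[ord[k]] == table$median_stability[ord[k + 1]])) {
    message(sprintf("stability tie at rank %d broken by probe id (%s over %s)",
                    k, table$probe[ord[k]], table$probe[ord[k + 1]]))
  }
  structure(list(probes = table$probe[sel],
                 provenance = c(attr(table, "provenance"), list(k = k))),
            class = "normalizer_set")
}

#' @export
print.normalizer_set <- function(x, ...) {
  cat(sprintf("<normalizer_set> %s\n", paste(x$probes, collapse = ", ")))
  invisible(x)
}
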