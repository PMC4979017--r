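# Independent oracles, written deliberately as slow explicit loops so they
# share no code path with the package's vectorized implementations.

# Model-based reference-gene stability, transcribed loop-by-loop from the
# two-group variance-decomposition model: per-group gene means A[i, g] with
# sampling variances V[i, g] from the two-way (gene + sample) residuals;
# gene-by-group interaction d[i, g] as the double-centered mean table;
# exact propagation of V through the centering coefficients
# (delta_ii' - 1/n)(delta_gg' - 1/K); empirical-Bayes shrinkage of d by
# gamma^2 / (gamma^2 + Var(d)); rho_i = mean_g(|d_shrunk| + sqrt(Var(d))).
oracle_normfinder <- function(y, groups) {
  # y: genes x samples
  lev <- unique(groups)
  n <- nrow(y); K <- length(lev)
  A <- matrix(0, n, K); V <- matrix(0, n, K)
  for (k in seq_len(K)) {
    yg <- y[, groups == lev[k], drop = FALSE]
    ng <- ncol(yg)
    for (i in seq_len(n)) A[i, k] <- mean(yg[i, ])
    col_mean <- numeric(ng)
    for (j in seq_len(ng)) col_mean[j] <- mean(yg[, j])
    grand <- mean(yg)
    for (i in seq_len(n)) {
      ss <- 0
      for (j in seq_len(ng)) {
        r <- yg[i, j] - A[i, k] - col_mean[j] + grand
        ss <- ss + r^2
      }
      sigma2 <- ss * n / ((n - 1) * (ng - 1))
      V[i, k] <- sigma2 / ng
    }
  }
  d <- matrix(0, n, K); vard <- matrix(0, n, K)
  for (i in seq_len(n)) {
    for (k in seq_len(K)) {
      d[i, k] <- A[i, k] - mean(A[i, ]) - mean(A[, k]) + mean(A)
      vv <- 0
      for (i2 in seq_len(n)) {
        for (k2 in seq_len(K)) {
          coef <- ((i2 == i) - 1 / n) * ((k2 == k) - 1 / K)
          vv <- vv + coef^2 * V[i2, k2]
        }
      }
      vard[i, k] <- vv
    }
  }
  gamma2 <- max(0, mean(d^2) - mean(vard))
  rho <- numeric(n)
  for (i in seq_len(n)) {
    acc <- 0
    for (k in seq_len(K)) {
      denom <- gamma2 + vard[i, k]
      shrunk <- if (denom > 0) d[i, k] * gamma2 / denom else 0
      acc <- acc + abs(shrunk) + sqrt(vard[i, k])
    }
    rho[i] <- acc / K
  }
  names(rho) <- rownames(y)
  rho
}

# AUC as the concordance probability by explicit pair counting, with half
# credit for ties across classes.
oracle_auc <- function(scores, truth) {
  pos <- scores[truth]
  neg <- scores[!truth]
  total <- 0
  for (a in pos) {
    for (b in neg) {
      total <- total + (a > b) + 0.5 * (a == b)
    }
  }
  total / (length(pos) * length(neg))
}

# Two-sided Fisher exact p-value by enumerating every table with the
# observed margins and summing the hypergeometric probabilities of tables no
# more probable than the observed one (with the conventional relative-error
# guard against float noise at equality).
oracle_fisher_p <- function(a, b, c, d) {
  m <- a + b; n2 <- c + d; k <- a + c
  lo <- max(0, k - n2); hi <- min(k, m)
  prob <- function(x) {
    choose(m, x) * choose(n2, k - x) / choose(m + n2, k)
  }
  p_obs <- prob(a)
  total <- 0
  for (x in lo:hi) {
    px <- prob(x)
    if (px <= p_obs * (1 + 1e-7)) total <- total + px
  }
  min(total, 1)
}

# Brute-force confusion tally over call/truth vectors.
oracle_confusion <- function(pos_call, is_case, is_neg) {
  tp <- fn <- tn <- fp <- 0
  for (i in seq_along(pos_call)) {
    if (is_case[i] && pos_call[i]) tp <- tp + 1
    if (is_case[i] && !pos_call[i]) fn <- fn + 1
    if (is_neg[i] && !pos_call[i]) tn <- tn + 1
    if (is_neg[i] && pos_call[i]) fp <- fp + 1
  }
  c(tp = tp, fn = fn, tn = tn, fp = fp)
}
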