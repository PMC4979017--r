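nf_fixture <- function() {
  x <- read_ct_long(extdata("normfinder_fixture_ct.csv"))
  md <- read_metadata(extdata("normfinder_fixture_groups.csv"))
  list(x = x, groups = md$group[match(samples(x), md$sample_id)])
}

test_that("normalizer candidates are probes detected in every sample", {
  brute <- function(x) {
    want <- character()
    for (p in probes(x)) {
      all_det <- TRUE
      for (s in samples(x)) {
        v <- x$ct[s, p]
        if (is.na(v) || v >= x$detection_limit) all_det <- FALSE
      }
      if (all_det) want <- c(want, p)
    }
    want
  }
  # heavy censoring: this draw leaves no fully detected probe, which warns
  x <- random_ct(12, 25, seed = 21, undetected_frac = 0.15)
  expect_identical(brute(x), character(0))
  expect_warning(got <- candidate_normalizers(x), "detected in every sample")
  expect_identical(got, character(0))
  # light censoring: non-empty candidate set, still equals the brute force
  x2 <- random_ct(12, 25, seed = 22, undetected_frac = 0.02)
  want2 <- brute(x2)
  expect_gt(length(want2), 0)
  expect_identical(candidate_normalizers(x2), want2)

  # one undetected cell disqualifies; full detection saturates
  m <- matrix(c(20, 21, 22, NA), 2, 2, dimnames = list(c("s1", "s2"), c("a", "b")))
  expect_identical(candidate_normalizers(ct_matrix(m)), "a")
  m[2, 2] <- 23
  expect_identical(candidate_normalizers(ct_matrix(m)), c("a", "b"))
})

test_that("stability values match the frozen independent-oracle fixture", {
  fx <- nf_fixture()
  got <- normfinder_stability(fx$x, fx$groups)
  expected <- read.csv(extdata("normfinder_expected.csv"))
  expect_equal(unname(got[expected$probe]), expected$stability, tolerance = 1e-6)
  # recompute with the loop oracle to guard the frozen file itself
  rho <- oracle_normfinder(t(fx$x$ct), fx$groups)
  expect_equal(unname(got[names(rho)]), unname(rho), tolerance = 1e-9)
})

test_that("stability behaves as the model dictates on constructed designs", {
  # perfectly stable genes: identical values in every sample -> stability 0
  m <- matrix(rep(c(20, 25), each = 8), 8, 2, dimnames = list(paste0("s", 1:8), c("a", "b")))
  got <- normfinder_stability(ct_matrix(m), rep(c("CASE", "CONTROL"), each = 4))
  expect_equal(unname(got), c(0, 0))

  # planted group bias makes a gene less stable than an unbiased peer
  set.seed(4)
  n <- 20
  grp <- rep(c("CASE", "CONTROL"), each = n / 2)
  base <- matrix(rnorm(n * 3, 24, 0.3), n, 3)
  base[grp == "CASE", 1] <- base[grp == "CASE", 1] + 2
  dimnames(base) <- list(sprintf("s%02d", 1:n), c("shifted", "flat1", "flat2"))
  rho <- normfinder_stability(ct_matrix(base), grp)
  expect_gt(rho["shifted"], rho["flat1"])
  expect_gt(rho["shifted"], rho["flat2"])

  # invariance: adding a constant to all Ct values of one sample is absorbed
  fx <- nf_fixture()
  shifted <- fx$x$ct
  shifted[3, ] <- shifted[3, ] + 5
  got0 <- normfinder_stability(fx$x, fx$groups)
  got1 <- normfinder_stability(ct_matrix(shifted, fx$x$detection_limit), fx$groups)
  expect_equal(got1, got0, tolerance = 1e-12)
})

test_that("stability refuses degenerate designs", {
  m <- matrix(20 + seq_len(12) / 10, 6, 2,
              dimnames = list(paste0("s", 1:6), c("a", "b")))
  expect_error(normfinder_stability(ct_matrix(m), rep("CASE", 6)),
               class = "mirvote_grouping_error")
  expect_error(normfinder_stability(ct_matrix(m), c("A", "A", "A", "B", "B", "C")),
               class = "mirvote_grouping_error")
  expect_error(normfinder_stability(ct_matrix(m[, 1, drop = FALSE]),
                                    rep(c("CASE", "CONTROL"), each = 3)),
               class = "mirvote_config_error")
})

test_that("bootstrap is deterministic and its single replicate is reproducible", {
  fx <- nf_fixture()
  t1 <- bootstrap_stability(fx$x, fx$groups, n_bootstrap = 25, seed = 42)
  t2 <- bootstrap_stability(fx$x, fx$groups, n_bootstrap = 25, seed = 42)
  expect_identical(as.data.frame(t1), as.data.frame(t2))
  expect_identical(attr(t1, "replicates"), attr(t2, "replicates"))
  expect_true(all(t1$median_stability >= 0))
  expect_setequal(t1$rank, seq_len(nrow(t1)))
  expect_equal(t1$probe[t1$rank == 1],
               t1$probe[which.min(t1$median_stability)])

  # replicate 1 equals a direct stability computation on the reconstructed draw
  one <- bootstrap_stability(fx$x, fx$groups, n_bootstrap = 1, seed = 7)
  g <- fx$groups
  set.seed(substream_seed(7, 1))
  idx <- unlist(lapply(unique(g), function(l) {
    ii <- which(g == l); sample(ii, length(ii), replace = TRUE)
  }))
  m <- fx$x$ct[idx, , drop = FALSE]
  rownames(m) <- sprintf("r%02d", seq_len(nrow(m)))
  direct <- normfinder_stability(ct_matrix(m), g[idx])
  expect_equal(one$median_stability, unname(direct[one$probe]), tolerance = 1e-12)
})

test_that("a group-shifted candidate never ranks most stable across seeds", {
  set.seed(99)
  n <- 30
  grp <- rep(c("CASE", "CONTROL"), each = n / 2)
  base <- matrix(rnorm(n * 5, 24, 0.4), n, 5)
  base[grp == "CASE", 5] <- base[grp == "CASE", 5] + 1.5
  dimnames(base) <- list(sprintf("s%02d", 1:n), c(paste0("flat", 1:4), "shifted"))
  x <- ct_matrix(base)
  for (s in 1:10) {
    tab <- bootstrap_stability(x, grp, n_bootstrap = 300, seed = s)
    expect_gt(tab$rank[tab$probe == "shifted"], 1)
  }
})

test_that("bootstrap median ranks converge between independent runs", {
  fx <- nf_fixture()
  a <- bootstrap_stability(fx$x, fx$groups, n_bootstrap = 1500, seed = 101)
  b <- bootstrap_stability(fx$x, fx$groups, n_bootstrap = 1500, seed = 202)
  tau <- cor(a$rank, b$rank[match(a$probe, b$probe)], method = "kendall")
  expect_gte(tau, 0.9)
})

test_that("normalizer selection takes the smallest medians with id tie-breaks", {
  tab <- tibble::tibble(probe = c("a", "b", "c", "d"),
                        median_stability = c(0.1, 0.3, 0.2, 0.5),
                        rank = c(1L, 3L, 2L, 4L),
                        n_valid_replicates = 10L,
                        full_data_stability = c(0.1, 0.3, 0.2, 0.5))
  class(tab) <- c("stability_table", class(tab))
  expect_identical(select_normalizer(tab, 3)$probes, c("a", "c", "b"))
  expect_identical(select_normalizer(tab, 4)$probes, c("a", "c", "b", "d"))
  expect_error(select_normalizer(tab, 5), class = "mirvote_config_error")

  tab$median_stability <- c(0.1, 0.2, 0.2, 0.5)
  expect_message(sel <- select_normalizer(tab, 2), "tie")
  expect_identical(sel$probes, c("a", "b")) # lexicographic winner at the boundary
})

test_that("planted stable probes dominate the top ranks on synthetic cohorts", {
  hits <- 0
  for (s in 1:10) {
    cfg <- simulation_config(n_case = 40, n_control = 20, n_probes = 60,
                             n_stable = 3, n_informative = 10,
                             n_spike_failures = c(case = 0, control = 0),
                             n_lowquality = c(case = 0, control = 0), seed = s)
    coh <- generate_cohort(cfg)
    qc <- run_qc(coh$ct, cfg$spike_probe)
    x <- ct_subset(qc$matrix, probes = qc$detectable_probes)
    grp <- coh$metadata$group[match(samples(x), coh$metadata$sample_id)]
    cand <- candidate_normalizers(x)
    tab <- bootstrap_stability(ct_subset(x, probes = cand), grp,
                               n_bootstrap = 60, seed = s)
    top3 <- tab$probe[tab$rank <= 3]
    if (all(top3 %in% coh$truth$stable)) hits <- hits + 1
  }
  expect_gte(hits, 9)
})
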