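voting_z <- function() {
  df <- read.csv(extdata("voting_fixture_z.csv"))
  z <- as.matrix(df[, c("f1", "f2", "f3")])
  rownames(z) <- df$sample
  list(z = z, labels = df$label)
}

test_that("candidate features use the case-detection rule, excluding normalizers", {
  m <- matrix(NA_real_, 10, 3, dimnames = list(sprintf("s%02d", 1:10), c("a", "b", "ref")))
  m[, "ref"] <- 25
  m[1:2, "a"] <- 28        # detected in 2 of 5 cases (40%)
  m[6:10, "b"] <- 28       # detected only in controls
  x <- ct_matrix(m)
  md <- two_group_metadata(x, 5)
  expect_identical(candidate_features(x, md, exclude = "ref"), "a")
  expect_identical(candidate_features(x, md, min_fraction = 0.5, exclude = "ref"),
                   character(0))
  md$group[] <- "CONTROL"
  expect_error(candidate_features(x, md), class = "mirvote_grouping_error")

  # brute-force count on a random censored matrix
  x2 <- random_ct(20, 15, seed = 13, undetected_frac = 0.5)
  md2 <- two_group_metadata(x2, 12)
  got <- candidate_features(x2, md2, min_fraction = 0.25)
  for (p in probes(x2)) {
    cnt <- 0
    for (s in md2$sample_id[md2$group == "CASE"]) {
      v <- x2$ct[s, p]
      if (!is.na(v) && v < 32) cnt <- cnt + 1
    }
    expect_identical(p %in% got, cnt / 12 >= 0.25)
  }
})

test_that("signal-to-noise ratio matches direct arithmetic and is antisymmetric", {
  z <- matrix(c(2, 0, -2, 0), 4, 1, dimnames = list(paste0("s", 1:4), "g"))
  lab <- c("CASE", "CASE", "CONTROL", "CONTROL")
  expect_equal(unname(s2n(z, lab)), 2 / (2 * sqrt(2)), tolerance = 1e-12)
  expect_equal(unname(s2n(z, rev(lab))), -2 / (2 * sqrt(2)), tolerance = 1e-12)

  # identical class distributions give exactly zero
  z2 <- matrix(rep(c(1, 2, 3), 2), 6, 1, dimnames = list(paste0("s", 1:6), "g"))
  expect_equal(unname(s2n(z2, rep(c("CASE", "CONTROL"), each = 3))), 0)

  set.seed(5)
  zr <- matrix(rnorm(40), 10, 4, dimnames = list(paste0("s", 1:10), paste0("g", 1:4)))
  labr <- rep(c("CASE", "CONTROL"), each = 5)
  got <- s2n(zr, labr)
  for (j in 1:4) {
    mc <- mean(zr[1:5, j]); mh <- mean(zr[6:10, j])
    expect_equal(unname(got[j]), (mc - mh) / (sd(zr[1:5, j]) + sd(zr[6:10, j])))
  }
  expect_equal(unname(s2n(zr, ifelse(labr == "CASE", "CONTROL", "CASE"))),
               -unname(got), tolerance = 1e-12)
  expect_error(s2n(zr[1:6, ], c("CASE", rep("CONTROL", 5))),
               class = "mirvote_grouping_error")
})

test_that("trained model parameters match hand-computed values on the fixture", {
  fx <- voting_z()
  model <- train_voting(fx$z, fx$labels, c("f1", "f2", "f3"))
  # hand computation: case means {1.5, 1, 0}, control means {-1.5, -0.5, 0};
  # case SDs {0.5, 0.5, 1}, control SDs {0.5, 0.5, 1}
  expect_equal(unname(model$mu_case), c(1.5, 1, 0))
  expect_equal(unname(model$mu_control), c(-1.5, -0.5, 0))
  expect_equal(unname(model$b), c(0, 0.25, 0))
  expect_equal(unname(model$w), c(3 / 1, 1.5 / 1, 0))
  expect_equal(sign(model$w), sign(model$mu_case - model$mu_control))

  # a zero-S2N feature contributes nothing to any vote
  p <- predict(model, fx$z)
  expect_equal(p$vote_sum,
               unname(3 * fx$z[, "f1"] + 1.5 * (fx$z[, "f2"] - 0.25)))
  expect_identical(p$call, ifelse(p$vote_sum > 0, "POSITIVE", "NEGATIVE"))
})

test_that("prediction is a plain weighted sum with boundary at the threshold", {
  model <- structure(list(features = "f", w = c(f = 0.5), b = c(f = 0),
                          mu_case = c(f = 1), mu_control = c(f = -1),
                          sd_case = c(f = 1), sd_control = c(f = 1),
                          threshold = 0), class = "voting_model")
  z <- matrix(c(2, 0), 2, 1, dimnames = list(c("a", "b"), "f"))
  p <- predict(model, z)
  expect_equal(p$vote_sum, c(1, 0))
  expect_identical(p$call, c("POSITIVE", "NEGATIVE")) # x == b is not positive
  expect_error(predict(model, matrix(0, 1, 1, dimnames = list("a", "g"))),
               class = "mirvote_scoring_error")

  set.seed(17)
  z5 <- matrix(rnorm(15), 3, 5, dimnames = list(paste0("s", 1:3), paste0("f", 1:5)))
  w <- rnorm(5); b <- rnorm(5)
  m5 <- structure(list(features = colnames(z5),
                       w = setNames(w, colnames(z5)), b = setNames(b, colnames(z5)),
                       threshold = 0), class = "voting_model")
  got <- predict(m5, z5)$vote_sum
  for (i in 1:3) {
    acc <- 0
    for (j in 1:5) acc <- acc + w[j] * (z5[i, j] - b[j])
    expect_equal(got[i], acc)
  }
})

test_that("label swap negates every weight and vote sum exactly", {
  set.seed(23)
  z <- matrix(rnorm(80), 16, 5,
              dimnames = list(sprintf("s%02d", 1:16), paste0("f", 1:5)))
  lab <- rep(c("CASE", "CONTROL"), each = 8)
  m1 <- train_voting(z, lab, colnames(z))
  m2 <- train_voting(z, ifelse(lab == "CASE", "CONTROL", "CASE"), colnames(z))
  expect_equal(m2$w, -m1$w, tolerance = 1e-12)
  expect_equal(m2$b, m1$b, tolerance = 1e-12)
  expect_equal(predict(m2, z)$vote_sum, -predict(m1, z)$vote_sum, tolerance = 1e-12)
})

test_that("cross-validation is deterministic and perfect on separable data", {
  set.seed(41)
  n <- 40
  z <- matrix(rnorm(n * 6, 0, 0.1), n, 6,
              dimnames = list(sprintf("s%02d", 1:n), paste0("f", 1:6)))
  lab <- rep(c("CASE", "CONTROL"), each = n / 2)
  z[lab == "CASE", 1] <- z[lab == "CASE", 1] + 10 # huge planted effect
  cv1 <- cross_validate(z, lab, k_grid = 1:6, n_partitions = 1, seed = 3)
  expect_true(all(cv1$mean_misclassification == 0))
  expect_equal(cv1$chosen_k, 1) # smallest count wins the tie
  cv2 <- cross_validate(z, lab, k_grid = 1:6, n_partitions = 1, seed = 3)
  expect_identical(cv1$mean_misclassification, cv2$mean_misclassification)
  expect_identical(as.data.frame(cv1$inclusion), as.data.frame(cv2$inclusion))
  expect_true(all(cv1$inclusion$n_included <= cv1$n_models))
  expect_equal(cv1$inclusion$n_included[1], cv1$n_models) # f1 in every top-1
})

test_that("finalization takes the most-included features with documented tie-breaks", {
  inc <- tibble::tibble(feature = c("a", "b", "c", "d"),
                        n_included = c(100L, 90L, 10L, 90L),
                        mean_rank = c(1, 3, 4, 2))
  cv <- structure(list(chosen_k = 2L, inclusion = inc), class = "cv_report")
  set.seed(31)
  z <- matrix(rnorm(48), 12, 4, dimnames = list(sprintf("s%02d", 1:12),
                                                c("a", "b", "c", "d")))
  lab <- rep(c("CASE", "CONTROL"), each = 6)
  model <- finalize_voting(z, lab, cv)
  expect_identical(model$features, c("a", "d")) # tie 90 vs 90 -> smaller mean rank
})

test_that("cross-validation recovers planted informative features", {
  set.seed(57)
  n <- 60; p <- 200; n_inf <- 30
  z <- matrix(rnorm(n * p), n, p,
              dimnames = list(sprintf("s%02d", 1:n), sprintf("f%03d", 1:p)))
  lab <- rep(c("CASE", "CONTROL"), each = n / 2)
  inf <- sample(colnames(z), n_inf)
  z[lab == "CASE", inf] <- z[lab == "CASE", inf] +
    rep(sample(c(-1.2, 1.2), n_inf, replace = TRUE), each = n / 2)
  cv <- cross_validate(z, lab, k_grid = seq(2, 50, 2), n_partitions = 100, seed = 5)
  top <- cv$inclusion$feature[order(-cv$inclusion$n_included,
                                    cv$inclusion$mean_rank)][1:cv$chosen_k]
  expect_gte(length(intersect(top, inf)) / length(top), 0.8)
})
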