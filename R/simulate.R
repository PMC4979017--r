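#' Simulation configuration for synthetic qPCR cohorts
#'
#' Describes a two-group serum-profiling cohort with the statistical
#' structure the pipeline assumes: per-probe Gaussian Ct noise on the cycle
#' scale, per-sample global offsets (input-amount variation, absorbed by the
#' normalizer), a planted set of group-shifted informative probes, a planted
#' set of low-variance reference-like probes, an exogenous spike-in probe,
#' right-censoring of reactions beyond the instrument ceiling, and planted QC
#' failures (undetectable spike; globally shifted low-RNA samples). Defaults
#' mirror the design of a 150-case / 50-control training cohort whose QC
#' stage removes 3 spike failures and 5 low-quality samples, leaving 192.
#'
#' @param n_case,n_control Group sizes before QC.
#' @param n_other Named integer vector of extra-group sizes (reported as
#'   `OTHER:<name>`), e.g. `c(BPD = 47)`; default none.
#' @param n_probes Number of endogenous probes (spike-in added on top).
#' @param n_informative Number of probes with a planted case-vs-control mean
#'   shift.
#' @param delta Planted shift magnitude in cycles; default 1.5.
#' @param up_fraction Fraction of informative probes shifted to *lower* Ct in
#'   cases (up-regulated); the rest shift up. Default 0.5.
#' @param n_stable Number of reference-like probes (low variance, no shift).
#' @param sd_stable Their residual SD in cycles; default 0.15.
#' @param baseline_mean_range,baseline_sd_range Ranges (cycles) from which
#'   per-probe baseline means / residual SDs are drawn uniformly.
#' @param offset_sd SD (cycles) of the per-sample global offset; default 0.5.
#' @param detection_limit,ceiling Detection threshold and instrument ceiling
#'   (cycles); reactions beyond the ceiling are emitted as undetected.
#' @param spike_probe,spike_mean,spike_sd Spike-in probe id and its Ct
#'   distribution.
#' @param n_spike_failures Named vector `c(case=, control=)` of planted
#'   spike-in extraction failures; default 2 + 1.
#' @param n_lowquality Named vector of planted low-RNA samples whose
#'   endogenous Ct values are globally shifted by `lowquality_shift` cycles
#'   (the spike-in, added at extraction, stays detectable, so the two QC
#'   failure modes are disjoint); default 5 + 0.
#' @param lowquality_shift Cycles; default 12.
#' @param other_effect Named numeric vector of effect multipliers for each
#'   `n_other` group (0 = control-like, 1 = case-like); defaults to 0.
#' @param n_calibrators Calibrator samples flagged among clean training
#'   samples; default 22.
#' @param stage_probs Probabilities of stages I--IV for case samples.
#' @param seed Integer top-level seed.
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(n_case = 150, n_control = 50, n_other = integer(),
                              n_probes = 300, n_informative = 20, delta = 1.5,
                              up_fraction = 0.5, n_stable = 5, sd_stable = 0.15,
                              baseline_mean_range = c(22, 30),
                              baseline_sd_range = c(1, 3), offset_sd = 0.5,
                              detection_limit = 32, ceiling = 40,
                              spike_probe = "ath-miR-159a", spike_mean = 20,
                              spike_sd = 0.3,
                              n_spike_failures = c(case = 2, control = 1),
                              n_lowquality = c(case = 5, control = 0),
                              lowquality_shift = 12,
                              other_effect = NULL, n_calibrators = 22,
                              stage_probs = c(I = 0.56, II = 0.15, III = 0.25, IV = 0.04),
                              seed = 1) {
  cfg <- as.list(environment())
  if (cfg$n_informative + cfg$n_stable > cfg$n_probes) {
    stop_mirvote("mirvote_config_error", "n_informative + n_stable exceeds n_probes")
  }
  if (cfg$sd_stable <= 0 || cfg$offset_sd < 0 || any(cfg$baseline_sd_range <= 0)) {
    stop_mirvote("mirvote_config_error", "all SDs must be positive")
  }
  if (any(c(cfg$n_case, cfg$n_control, cfg$n_other) < 0)) {
    stop_mirvote("mirvote_config_error", "sample counts must be nonnegative")
  }
  if (sum(n_spike_failures) + sum(n_lowquality) >
      min(cfg$n_case, sum(n_spike_failures["case"], n_lowquality["case"], cfg$n_case)) + cfg$n_control) {
    stop_mirvote("mirvote_config_error", "more planted failures than samples")
  }
  # a low-quality sample must push (at least) three quarters of its probes
  # past the detection limit, else the percentile filter cannot catch it
  if (cfg$baseline_mean_range[1] + cfg$lowquality_shift < cfg$detection_limit + 1) {
    stop_mirvote("mirvote_config_error",
                 "lowquality_shift too small to push probes past the detection limit")
  }
  if (is.null(cfg$other_effect)) {
    cfg$other_effect <- stats::setNames(rep(0, length(cfg$n_other)), names(cfg$n_other))
  }
  class(cfg) <- "simulation_config"
  cfg
}

# per-probe population parameters, drawn once and shared between the
# training and validation cohorts of one simulated study
draw_population <- function(config) {
  set.seed(substream_seed(config$seed, "population"))
  p <- config$n_probes
  ids <- sprintf("miR-%04d", seq_len(p))
  roles <- rep("noise", p)
  stable_idx <- sample(p, config$n_stable)
  roles[stable_idx] <- "stable"
  informative_idx <- sample(setdiff(seq_len(p), stable_idx), config$n_informative)
  roles[informative_idx] <- "informative"
  baseline <- stats::runif(p, config$baseline_mean_range[1], config$baseline_mean_range[2])
  sd <- stats::runif(p, config$baseline_sd_range[1], config$baseline_sd_range[2])
  # reference-like probes: low baseline (always detected) and tight SD
  baseline[stable_idx] <- stats::runif(config$n_stable, 20, 24)
  sd[stable_idx] <- config$sd_stable
  # informative probes: keep baselines low enough to be detectable in cases
  baseline[informative_idx] <- stats::runif(config$n_informative, 22, 28)
  effect <- rep(0, p)
  n_up <- round(config$up_fraction * config$n_informative)
  signs <- sample(rep(c(-1, 1), c(n_up, config$n_informative - n_up)))
  effect[informative_idx] <- signs * config$delta
  list(probe = ids, role = roles, baseline = baseline, sd = sd, effect = effect)
}

#' Generate a synthetic Ct cohort with recorded ground truth
#'
#' Draws `Ct(s, p) = baseline_p + offset_s + effect_p * x(group(s)) + noise`
#' with `noise ~ N(0, sd_p)`, where `x` is 1 for cases, 0 for controls and
#' the configured multiplier for other groups; censors reactions beyond the
#' instrument ceiling as undetected; adds the spike-in probe, forced
#' undetected in the planted extraction-failure samples; and shifts the
#' planted low-quality samples' endogenous reactions so their 25th-percentile
#' Ct exceeds the detection limit. Deterministic for a fixed config seed.
#'
#' @param config A [simulation_config()].
#' @param cohort `"TRAINING"` or `"VALIDATION"`; affects sample ids, the
#'   metadata cohort column and calibrator flagging (training only).
#' @param population Optional population parameters from a previous cohort's
#'   `truth$population`, so training and validation share probes and effects.
#' @return A list with `ct` (a [ct_matrix()]), `metadata` (tibble) and
#'   `truth` (planted informative/stable probe ids and effects, planted
#'   spike-failure and low-quality sample ids, per-sample offsets, and the
#'   population parameters).
#' @export
generate_cohort <- function(config, cohort = c("TRAINING", "VALIDATION"),
                            population = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  cohort <- match.arg(cohort)
  pop <- population %||% draw_population(config)
  set.seed(substream_seed(config$seed, paste0("samples-", cohort)))
  tag <- if (cohort == "TRAINING") "tr" else "va"
  other_groups <- if (length(config$n_other)) {
    rep(paste0("OTHER:", names(config$n_other)), as.integer(config$n_other))
  } else character()
  groups <- c(rep("CASE", config$n_case), rep("CONTROL", config$n_control), other_groups)
  n <- length(groups)
  other_tags <- if (length(config$n_other)) {
    rep(names(config$n_other), as.integer(config$n_other))
  } else character()
  sample_id <- sprintf("%s_s%03d_%s", tag, seq_len(n),
                       c(rep("case", config$n_case), rep("ctrl", config$n_control),
                         other_tags))
  mult <- ifelse(groups == "CASE", 1,
          ifelse(groups == "CONTROL", 0,
                 config$other_effect[sub("^OTHER:", "", groups)]))
  offsets <- stats::rnorm(n, 0, config$offset_sd)
  p <- config$n_probes
  noise <- matrix(stats::rnorm(n * p), n, p)
  ct <- matrix(rep(pop$baseline, each = n), n, p) +
    offsets +
    outer(mult, pop$effect) +
    sweep(noise, 2, pop$sd, "*")
  dimnames(ct) <- list(sample_id, pop$probe)
  # planted QC failures: draw case/control ids, spike failures first so the
  # two planted sets never overlap
  case_ids <- sample_id[groups == "CASE"]
  ctrl_ids <- sample_id[groups == "CONTROL"]
  pick <- function(pool, k) if (k > 0) sample(pool, k) else character()
  spike_fail <- c(pick(case_ids, config$n_spike_failures[["case"]]),
                  pick(ctrl_ids, config$n_spike_failures[["control"]]))
  lowq <- c(pick(setdiff(case_ids, spike_fail), config$n_lowquality[["case"]]),
            pick(setdiff(ctrl_ids, spike_fail), config$n_lowquality[["control"]]))
  ct[lowq, ] <- ct[lowq, ] + config$lowquality_shift
  spike <- config$spike_mean + offsets + stats::rnorm(n, 0, config$spike_sd)
  spike[sample_id %in% spike_fail] <- NA_real_
  ct <- cbind(ct, matrix(spike, n, 1, dimnames = list(NULL, config$spike_probe)))
  ct[ct >= config$ceiling & !is.na(ct)] <- NA_real_ # censored beyond the instrument ceiling
  planted <- c(spike_fail, lowq)
  calib <- rep(FALSE, n)
  if (cohort == "TRAINING" && config$n_calibrators > 0) {
    clean <- setdiff(c(case_ids, ctrl_ids), planted)
    calib[sample_id %in% sample(clean, config$n_calibrators)] <- TRUE
  }
  stage <- rep(NA_character_, n)
  stage[groups == "CASE"] <- sample(names(config$stage_probs), sum(groups == "CASE"),
                                    replace = TRUE, prob = config$stage_probs)
  metadata <- tibble::tibble(
    sample_id = sample_id, group = groups, cohort = cohort, stage = stage,
    histology = ifelse(groups == "CASE", "adenocarcinoma", NA_character_),
    is_calibrator = calib
  )
  truth <- list(
    informative = tibble::tibble(probe = pop$probe[pop$role == "informative"],
                                 effect = pop$effect[pop$role == "informative"]),
    stable = pop$probe[pop$role == "stable"],
    spike_failures = spike_fail,
    lowquality = lowq,
    offsets = stats::setNames(offsets, sample_id),
    population = pop
  )
  list(ct = ct_matrix(ct, config$detection_limit), metadata = metadata, truth = truth)
}

#' Write the committed oracle fixture inputs
#'
#' Regenerates, byte-identically, the small plain-text fixtures used by the
#' oracle tests: a two-group Ct matrix for the stability-value check, a
#' three-feature z-score table for the hand-computed weighted-voting check,
#' and a tied score vector for the ROC check. Expected values frozen from the
#' independent oracles live alongside these files in `inst/extdata/` and are
#' not rewritten here. All fixtures are synthetic.
#'
#' @param dir Output directory.
#' @return Invisibly, the written file paths.
#' @export
reference_fixtures <- function(dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  # stability fixture: 5 candidate probes x 12 samples (6 + 6), one probe
  # with a planted group shift, values rounded so the CSV is exact
  set.seed(20160810)
  n_s <- 12; grp <- rep(c("CONTROL", "CASE"), each = 6)
  base <- c(m1 = 21, m2 = 23, m3 = 25, m4 = 22, m5 = 24)
  shift <- c(0, 0, 0, 0, 1.2) # m5 carries a group bias
  offs <- round(stats::rnorm(n_s, 0, 0.4), 3)
  m <- sapply(seq_along(base), function(j) {
    round(base[j] + offs + shift[j] * (grp == "CASE") +
            round(stats::rnorm(n_s, 0, 0.3), 3), 3)
  })
  dimnames(m) <- list(sprintf("s%02d", seq_len(n_s)), names(base))
  nf_path <- file.path(dir, "normfinder_fixture_ct.csv")
  write_ct_long(ct_matrix(m), nf_path)
  meta <- tibble::tibble(sample_id = rownames(m), group = grp, cohort = "TRAINING",
                         stage = NA_character_, histology = NA_character_,
                         is_calibrator = FALSE)
  meta_path <- file.path(dir, "normfinder_fixture_groups.csv")
  write_metadata(meta, meta_path)
  # voting fixture: 6 samples x 3 features of z-scores, small integers/halves
  zdf <- data.frame(
    sample = sprintf("v%d", 1:6),
    f1 = c(1.0, 2.0, 1.5, -1.0, -2.0, -1.5),
    f2 = c(0.5, 1.5, 1.0, 0.0, -0.5, -1.0),
    f3 = c(-1.0, 0.0, 1.0, 1.0, 0.0, -1.0),
    label = c("CASE", "CASE", "CASE", "CONTROL", "CONTROL", "CONTROL")
  )
  v_path <- file.path(dir, "voting_fixture_z.csv")
  utils::write.csv(zdf, v_path, row.names = FALSE, quote = FALSE)
  # ROC fixture with ties across classes
  roc <- data.frame(score = c(2, 1, 1, 0, 1, 0, -1, -1),
                    truth = c("CASE", "CASE", "CASE", "CASE",
                              "CONTROL", "CONTROL", "CONTROL", "CONTROL"))
  r_path <- file.path(dir, "roc_tie_scores.csv")
  utils::write.csv(roc, r_path, row.names = FALSE, quote = FALSE)
  invisible(c(nf_path, meta_path, v_path, r_path))
}
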