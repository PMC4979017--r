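# Small in-code fixtures shared across test files.

# random Ct matrix with a given fraction of undetected cells
random_ct <- function(n_samples, n_probes, seed, undetected_frac = 0.1,
                      detection_limit = 32) {
  set.seed(seed)
  m <- matrix(round(runif(n_samples * n_probes, 18, 38), 3), n_samples, n_probes,
              dimnames = list(sprintf("s%03d", seq_len(n_samples)),
                              sprintf("p%03d", seq_len(n_probes))))
  m[runif(length(m)) < undetected_frac] <- NA_real_
  ct_matrix(m, detection_limit)
}

# minimal metadata for a ct_matrix with the first n_case samples as cases
two_group_metadata <- function(x, n_case, cohort = "TRAINING") {
  ids <- samples(x)
  tibble::tibble(
    sample_id = ids,
    group = rep(c("CASE", "CONTROL"), c(n_case, length(ids) - n_case)),
    cohort = cohort, stage = NA_character_, histology = NA_character_,
    is_calibrator = FALSE
  )
}

extdata <- function(f) {
  p <- system.file("extdata", f, package = "mirvote")
  if (!nzchar(p)) p <- file.path("../../inst/extdata", f)
  p
}
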