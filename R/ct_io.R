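#' Read a long-format Ct table
#'
#' Ingests the long CSV dialect of RQ-manager-style TLDA exports: one row per
#' (sample, probe) reaction with columns `sample`, `probe`, `ct`. Tokens in
#' `undetected_tokens` (case-sensitive, after whitespace trimming) map to
#' undetected; any other unparseable `ct` is an error that reports the
#' offending data row.
#'
#' @param path CSV file with header row `sample,probe,ct`.
#' @param undetected_tokens Strings that denote an undetected reaction.
#' @param detection_limit Cycles, passed to [ct_matrix()].
#' @return A [ct_matrix()] with samples and probes in order of first
#'   appearance.
#' @export
read_ct_long <- function(path, undetected_tokens = c("Undetermined", "", "NA"),
                         detection_limit = 32) {
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  need <- c("sample", "probe", "ct")
  if (!all(need %in% names(df))) {
    stop_mirvote("mirvote_format_error", "missing required column(s): %s",
                 paste(setdiff(need, names(df)), collapse = ", "))
  }
  sample <- trimws_all(df$sample)
  probe <- trimws_all(df$probe)
  ct_raw <- trimws_all(df$ct)
  # read.csv turns a literal NA field into <NA>; treat it as the "NA" token
  ct_raw[is.na(ct_raw)] <- "NA"
  key <- paste(sample, probe, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1]
    stop_mirvote("mirvote_integrity_error", "duplicate (sample, probe) pair: (%s)",
                 gsub("\r", ", ", dup))
  }
  und <- ct_raw %in% undetected_tokens
  ct_num <- suppressWarnings(as.numeric(ct_raw))
  bad <- which(!und & !is.finite(ct_num))
  if (length(bad)) {
    stop_mirvote("mirvote_value_error", "unparseable ct value '%s' at data row %d",
                 ct_raw[bad[1]], bad[1])
  }
  ct_num[und] <- NA_real_
  s_ids <- unique(sample)
  p_ids <- unique(probe)
  # pairs absent from the file (instruments may omit failed wells) are
  # undetected, like an explicit "Undetermined"
  m <- matrix(NA_real_, length(s_ids), length(p_ids), dimnames = list(s_ids, p_ids))
  m[cbind(sample, probe)] <- ct_num
  ct_matrix(m, detection_limit)
}

#' Read a wide-format Ct table
#'
#' Convenience reader for sample-rows-by-probe-columns fixtures; converts to
#' the same semantics as [read_ct_long()].
#'
#' @inheritParams read_ct_long
#' @param sample_col Name of the column holding sample identifiers.
#' @return A [ct_matrix()].
#' @export
read_ct_wide <- function(path, sample_col = "sample",
                         undetected_tokens = c("Undetermined", "", "NA"),
                         detection_limit = 32) {
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  if (!sample_col %in% names(df)) {
    stop_mirvote("mirvote_format_error", "missing sample column '%s'", sample_col)
  }
  s_ids <- trimws_all(df[[sample_col]])
  p_ids <- setdiff(names(df), sample_col)
  m <- matrix(NA_real_, length(s_ids), length(p_ids),
              dimnames = list(s_ids, trimws_all(p_ids)))
  for (j in seq_along(p_ids)) {
    v <- trimws_all(df[[p_ids[j]]])
    v[is.na(v)] <- "NA"
    und <- v %in% undetected_tokens
    num <- suppressWarnings(as.numeric(v))
    bad <- which(!und & !is.finite(num))
    if (length(bad)) {
      stop_mirvote("mirvote_value_error", "unparseable ct value '%s' (sample %s, probe %s)",
                   v[bad[1]], s_ids[bad[1]], p_ids[j])
    }
    num[und] <- NA_real_
    m[, j] <- num
  }
  ct_matrix(m, detection_limit)
}

#' Write a Ct matrix in the long CSV dialect
#'
#' Emits the format [read_ct_long()] accepts; undetected cells are written as
#' `"Undetermined"`. `write_ct_long` then `read_ct_long` is the identity up to
#' float formatting (15 significant digits are written).
#'
#' @param x A [ct_matrix()].
#' @param path Output CSV path.
#' @export
write_ct_long <- function(x, path) {
  stopifnot(inherits(x, "ct_matrix"))
  long <- expand.grid(probe = colnames(x$ct), sample = rownames(x$ct),
                      stringsAsFactors = FALSE)[, c("sample", "probe")]
  vals <- as.vector(t(x$ct))
  ct_chr <- ifelse(is.na(vals), "Undetermined", format(vals, digits = 15, trim = TRUE))
  utils::write.csv(data.frame(long, ct = ct_chr), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# canonical vocabularies for sample metadata
.group_case_labels <- c("CASE", "AD")
.group_control_labels <- c("CONTROL", "HS")
.cohort_levels <- c("TRAINING", "VALIDATION")

#' Read sample metadata
#'
#' Reads the per-sample annotation table driving the supervised steps:
#' required columns `sample_id`, `group`, `cohort`; optional `stage`,
#' `histology`, `is_calibrator`. Group labels are normalized to `CASE` /
#' `CONTROL`; any other label is preserved as `OTHER:<label>` so extra panels
#' (benign disease, other cancers) keep their identity. Calibrator flags are
#' only legal on training samples.
#'
#' @param path CSV file.
#' @param case_labels,control_labels Group strings recognized as case /
#'   control (case-insensitive).
#' @return A [tibble::tibble] with columns `sample_id`, `group`, `cohort`,
#'   `stage`, `histology`, `is_calibrator`.
#' @export
read_metadata <- function(path, case_labels = .group_case_labels,
                          control_labels = .group_control_labels) {
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  need <- c("sample_id", "group", "cohort")
  if (!all(need %in% names(df))) {
    stop_mirvote("mirvote_format_error", "missing required column(s): %s",
                 paste(setdiff(need, names(df)), collapse = ", "))
  }
  sample_id <- trimws_all(df$sample_id)
  if (anyDuplicated(sample_id)) {
    stop_mirvote("mirvote_integrity_error", "duplicate sample_id: %s",
                 sample_id[duplicated(sample_id)][1])
  }
  grp_raw <- trimws_all(df$group)
  group <- ifelse(toupper(grp_raw) %in% toupper(case_labels), "CASE",
           ifelse(toupper(grp_raw) %in% toupper(control_labels), "CONTROL",
                  paste0("OTHER:", grp_raw)))
  cohort <- toupper(trimws_all(df$cohort))
  bad <- setdiff(unique(cohort), .cohort_levels)
  if (length(bad)) {
    stop_mirvote("mirvote_format_error",
                 "unrecognized cohort value(s) %s; allowed: %s",
                 paste(bad, collapse = ", "), paste(.cohort_levels, collapse = ", "))
  }
  stage <- if ("stage" %in% names(df)) toupper(trimws_all(df$stage)) else NA_character_
  stage[stage %in% c("", "NA")] <- NA_character_
  bad_stage <- setdiff(stats::na.omit(unique(stage)), c("I", "II", "III", "IV"))
  if (length(bad_stage)) {
    stop_mirvote("mirvote_format_error", "unrecognized stage value(s): %s",
                 paste(bad_stage, collapse = ", "))
  }
  histology <- if ("histology" %in% names(df)) trimws_all(df$histology) else NA_character_
  histology[histology %in% c("", "NA")] <- NA_character_
  calib <- if ("is_calibrator" %in% names(df)) {
    v <- tolower(trimws_all(df$is_calibrator))
    out <- v %in% c("true", "t", "1", "yes")
    bad_cal <- setdiff(v, c("true", "t", "1", "yes", "false", "f", "0", "no", "", "na"))
    if (length(bad_cal)) {
      stop_mirvote("mirvote_format_error", "unparseable is_calibrator value: %s", bad_cal[1])
    }
    out
  } else rep(FALSE, nrow(df))
  if (any(calib & cohort != "TRAINING")) {
    stop_mirvote("mirvote_integrity_error",
                 "calibrator flag set on non-training sample(s): %s",
                 paste(sample_id[calib & cohort != "TRAINING"], collapse = ", "))
  }
  tibble::tibble(sample_id = sample_id, group = group, cohort = cohort,
                 stage = stage, histology = histology, is_calibrator = calib)
}

#' Write sample metadata
#'
#' @param metadata A metadata tibble as returned by [read_metadata()].
#' @param path Output CSV path.
#' @export
write_metadata <- function(metadata, path) {
  df <- as.data.frame(metadata)
  df$is_calibrator <- ifelse(df$is_calibrator, "true", "false")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

# group labels for the samples of a ct_matrix, in matrix order
group_vector <- function(x, metadata) {
  idx <- match(samples(x), metadata$sample_id)
  if (anyNA(idx)) {
    stop_mirvote("mirvote_integrity_error", "sample(s) without metadata: %s",
                 paste(samples(x)[is.na(idx)], collapse = ", "))
  }
  metadata$group[idx]
}
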