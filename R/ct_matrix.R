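#' Ct matrix container
#'
#' The pipeline's input currency: a sample-by-probe grid of qPCR
#' cycle-threshold (Ct) values. Undetected reactions (exported as
#' "Undetermined" by the instrument software) are stored as `NA`; a finite Ct
#' at or above the detection limit is stored as-is but does not count as
#' detected. Detection status is therefore a pure function of the stored value
#' and `detection_limit`, and changing the limit never mutates stored values.
#'
#' @param ct Numeric matrix, samples in rows, probes in columns; `NA` marks an
#'   undetected reaction. Row and column names are required and must be unique
#'   after whitespace trimming.
#' @param detection_limit Cycles; a probe is detected in a sample iff its Ct is
#'   finite and strictly below this limit. Default 32.
#' @return An object of class `ct_matrix`.
#' @export
#' @examples
#' m <- matrix(c(20.1, NA, 25, 30), 2, 2,
#'             dimnames = list(c("s1", "s2"), c("m1", "m2")))
#' x <- ct_matrix(m)
#' detected(x)
ct_matrix <- function(ct, detection_limit = 32) {
  if (!is.matrix(ct) || !is.numeric(ct)) {
    stop_mirvote("mirvote_format_error", "ct must be a numeric matrix")
  }
  if (is.null(rownames(ct)) || is.null(colnames(ct))) {
    stop_mirvote("mirvote_format_error", "ct matrix needs sample row names and probe column names")
  }
  rownames(ct) <- trimws_all(rownames(ct))
  colnames(ct) <- trimws_all(colnames(ct))
  if (anyDuplicated(rownames(ct))) {
    stop_mirvote("mirvote_integrity_error", "duplicate sample identifiers: %s",
                 paste(unique(rownames(ct)[duplicated(rownames(ct))]), collapse = ", "))
  }
  if (anyDuplicated(colnames(ct))) {
    stop_mirvote("mirvote_integrity_error", "duplicate probe identifiers: %s",
                 paste(unique(colnames(ct)[duplicated(colnames(ct))]), collapse = ", "))
  }
  finite <- ct[is.finite(ct)]
  if (length(finite) && (any(finite <= 0) || any(finite > 50))) {
    stop_mirvote("mirvote_value_error", "finite Ct values must lie in (0, 50]")
  }
  stopifnot(is.numeric(detection_limit), length(detection_limit) == 1, detection_limit > 0)
  structure(list(ct = ct, detection_limit = detection_limit), class = "ct_matrix")
}

#' @export
print.ct_matrix <- function(x, ...) {
  cat(sprintf("<ct_matrix> %d samples x %d probes, detection limit %g cycles, %d undetected cells\n",
              nrow(x$ct), ncol(x$ct), x$detection_limit, sum(is.na(x$ct))))
  invisible(x)
}

#' @export
dim.ct_matrix <- function(x) dim(x$ct)

#' @rdname ct_matrix
#' @param x A `ct_matrix`.
#' @export
samples <- function(x) rownames(x$ct)

#' @rdname ct_matrix
#' @export
probes <- function(x) colnames(x$ct)

#' @rdname ct_matrix
#' @return For `detected()`, a logical sample-by-probe matrix.
#' @export
detected <- function(x) {
  d <- is.finite(x$ct) & x$ct < x$detection_limit
  d[is.na(d)] <- FALSE
  d
}

#' Subset a Ct matrix by sample and/or probe identifiers
#'
#' @param x A `ct_matrix`.
#' @param samples,probes Character vectors of identifiers to keep (order
#'   respected); `NULL` keeps all.
#' @return A `ct_matrix`.
#' @export
ct_subset <- function(x, samples = NULL, probes = NULL) {
  s <- samples %||% rownames(x$ct)
  p <- probes %||% colnames(x$ct)
  missing_s <- setdiff(s, rownames(x$ct))
  missing_p <- setdiff(p, colnames(x$ct))
  if (length(missing_s) || length(missing_p)) {
    stop_mirvote("mirvote_integrity_error", "unknown identifiers: %s",
                 paste(c(missing_s, missing_p), collapse = ", "))
  }
  ct_matrix(x$ct[s, p, drop = FALSE], x$detection_limit)
}
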