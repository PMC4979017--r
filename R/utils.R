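#' Derive a reproducible substream seed
#'
#' Stochastic stages (bootstrap replicates, cross-validation partitions,
#' cohort simulation) each draw their own seed deterministically from a single
#' top-level seed plus a stream label, so stage-level results are reproducible
#' independently of execution order.
#'
#' @param seed Integer top-level seed.
#' @param stream Integer or character stream label.
#' @return An integer in `[0, 2^31 - 2]`, suitable for [set.seed()].
#' @export
#' @examples
#' substream_seed(1, 1)
#' substream_seed(1, "bootstrap")
substream_seed <- function(seed, stream) {
  stopifnot(length(seed) == 1, is.numeric(seed), is.finite(seed))
  if (is.character(stream)) {
    stream <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  }
  stopifnot(length(stream) == 1, is.numeric(stream), is.finite(stream))
  m <- 2147483647 # 2^31 - 1, Park-Miller modulus
  s <- (as.numeric(seed) %% m) * 48271 %% m
  as.integer((s + as.numeric(stream) * 69621) %% m)
}

# Polynomial rolling hash over a character serialization; a lightweight
# content fingerprint used to assert that frozen parameters are not silently
# refit. Not cryptographic; collision resistance is irrelevant here.
fingerprint <- function(x) {
  txt <- paste(deparse(x, control = c("keepNA", "niceNames", "showAttributes")),
               collapse = "\n")
  bytes <- utf8ToInt(txt)
  m <- 2147483647
  h <- 0
  # chunked Horner evaluation keeps the loop short for long serializations
  for (chunk in split(bytes, ceiling(seq_along(bytes) / 512))) {
    for (b in chunk) h <- (h * 131 + b) %% m
  }
  sprintf("%08x", as.integer(h))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

trimws_all <- function(x) trimws(as.character(x))

stop_mirvote <- function(class, msg, ...) {
  stop(errorCondition(sprintf(msg, ...), class = c(class, "mirvote_error")))
}
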