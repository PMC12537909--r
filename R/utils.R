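#' Derive a reproducible sub-stream seed from a global seed
#'
#' Stage seeds are derived deterministically from one global seed so that
#' individual pipeline stages can be rerun in isolation with identical
#' results.  The derivation hashes the stage label into an integer offset
#' and folds it into the global seed modulo 2^31 - 1.
#'
#' @param seed Integer global seed.
#' @param label Character stage label (e.g. `"lfq"`, `"impute"`).
#' @return A single integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label))
  m <- 2147483647  # 2^31 - 1, Mersenne prime
  h <- 0
  for (cc in utf8ToInt(label)) h <- (h * 131 + cc) %% m
  as.integer((abs(seed) %% m * 31 + h) %% (m - 1) + 1)
}

#' Write a data frame as tab-separated values
#'
#' Canonical tabular dialect of the package: header row, tab delimiter,
#' missing values as empty fields, no quoting, no row names.
#'
#' @param x Data frame.
#' @param path Output path.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
}

#' Read a tab-separated table written by [write_tsv()]
#'
#' @param path Input path.
#' @return Data frame with empty fields read as `NA`.
#' @export
read_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", na.strings = "", check.names = FALSE,
                    stringsAsFactors = FALSE)
}

#' MD5 hash of an R object via its canonical JSON serialization
#'
#' Used to stamp run reports with the configuration that produced them.
#'
#' @param x A list-like object convertible to JSON.
#' @return Character scalar MD5 digest.
#' @export
config_hash <- function(x) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null",
                              force = TRUE), tmp)
  unname(tools::md5sum(tmp))
}

# Pairwise Euclidean distances between rows of two matrices (micrometres).
pairwise_dist <- function(a, b) {
  stopifnot(ncol(a) == ncol(b))
  d2 <- matrix(0, nrow(a), nrow(b))
  for (j in seq_len(ncol(a))) d2 <- d2 + outer(a[, j], b[, j], "-")^2
  sqrt(d2)
}
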