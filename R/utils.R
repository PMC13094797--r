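#' @keywords internal
"_PACKAGE"

# -- small shared helpers ----------------------------------------------------

#' MD5 digest of a file
#'
#' Submission identity and idempotency keys are content digests; two byte
#' identical files always share a digest.
#'
#' @param path Path to an existing file.
#' @return Lower-case hex digest string.
#' @export
file_digest <- function(path) {
  stopifnot(file.exists(path))
  unname(tools::md5sum(path))
}

# digest of an in-memory character scalar
content_digest <- function(x) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeChar(paste(x, collapse = "\n"), tmp, eos = NULL, useBytes = TRUE)
  unname(tools::md5sum(tmp))
}

#' Read a delimited submission file
#'
#' All cells are read as character strings; QC and typed interpretation are
#' downstream concerns. RFC-4180 quoting is honoured by the base reader.
#'
#' @param path CSV file with a mandatory header row.
#' @return A data.frame of character columns (possibly 0-row).
#' @export
read_submission <- function(path) {
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                        na.strings = NULL, fileEncoding = "UTF-8")
  df
}

# deterministic CSV writer (LF endings, no row names, minimal quoting)
write_csv_file <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE, eol = "\n",
                   fileEncoding = "UTF-8")
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_scalar_chr <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

# strict ISO-8601 calendar date check: pattern, then real calendar date
iso_date_pattern <- function(x) grepl("^\\d{4}-\\d{2}-\\d{2}$", x)

iso_date_valid <- function(x) {
  ok <- iso_date_pattern(x)
  ok[ok] <- !is.na(as.Date(x[ok], format = "%Y-%m-%d"))
  ok
}

# integer literal (optional sign, digits only)
is_integer_literal <- function(x) grepl("^[+-]?\\d+$", x)

# decimal literal (plain or with fraction; no exponent in submissions)
is_decimal_literal <- function(x) grepl("^[+-]?(\\d+\\.?\\d*|\\.\\d+)$", x)

# a typed condition constructor used across modules
sf_error <- function(class, message, ...) {
  structure(class = c(class, "studyflow_error", "error", "condition"),
            list(message = message, call = NULL, ...))
}

sf_stop <- function(class, message, ...) stop(sf_error(class, message, ...))
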