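# Privacy-minimization transforms.
#
# Identifiability of participants is reduced at the data layer itself:
# dates of birth are retained only to the month, residential geography only
# as 3-digit ZIP prefixes (which encode larger areas), and directly
# identifying fields are dropped. Transforms are idempotent and fail closed:
# a malformed value is never passed through under a truncation rule.

PRIVACY_TRANSFORMS <- c("truncate_date_to_month", "truncate_zip_to_3", "drop", "pass")

#' Construct a privacy rule
#'
#' @param table,field The field the rule covers.
#' @param transform One of `truncate_date_to_month`, `truncate_zip_to_3`,
#'   `drop`, `pass`.
#' @param applied_at When the transform runs: `import`, `report`, or `both`.
#' @return A `privacy_rule` object.
#' @export
privacy_rule <- function(table, field, transform, applied_at = "import") {
  if (!transform %in% PRIVACY_TRANSFORMS)
    sf_stop("config_error", sprintf("unknown privacy transform '%s'", transform))
  if (!applied_at %in% c("import", "report", "both"))
    sf_stop("config_error", sprintf("unknown privacy stage '%s'", applied_at))
  structure(list(table = table, field = field, transform = transform,
                 applied_at = applied_at), class = "privacy_rule")
}

#' Apply a privacy transform to values
#'
#' * `truncate_date_to_month`: `"1985-06-17"` becomes `"1985-06"`; an
#'   already month-level value passes unchanged (idempotent).
#' * `truncate_zip_to_3`: keeps the first 3 digits of a 5- or 9-digit US ZIP
#'   (`"94115"` becomes `"941"`); non-US postal formats fail closed.
#' * `drop`: always the empty string.
#' * `pass`: identity.
#'
#' Empty strings (missing data) pass through every transform unchanged.
#' Malformed non-empty input under a truncation rule raises a privacy error
#' rather than passing the value through.
#'
#' @param value Character vector of raw values.
#' @param rule A [privacy_rule()], or a transform name.
#' @return Transformed character vector, same length.
#' @export
apply_privacy <- function(value, rule) {
  transform <- if (inherits(rule, "privacy_rule")) rule$transform else rule
  if (!transform %in% PRIVACY_TRANSFORMS)
    sf_stop("config_error", sprintf("unknown privacy transform '%s'", transform))
  out <- as.character(value)
  blank <- !nzchar(out)
  switch(transform,
    pass = out,
    drop = { out[] <- ""; out },
    truncate_date_to_month = {
      month_ok <- grepl("^\\d{4}-(0[1-9]|1[0-2])$", out)
      full <- iso_date_valid(out)
      bad <- !blank & !month_ok & !full
      if (any(bad))
        sf_stop("privacy_error", sprintf(
          "cannot truncate non-date value(s) to month: %s",
          paste(unique(out[bad]), collapse = ", ")))
      out[full] <- substr(out[full], 1, 7)
      out
    },
    truncate_zip_to_3 = {
      zip_ok <- grepl("^\\d{3}$|^\\d{5}$|^\\d{9}$|^\\d{5}-\\d{4}$", out)
      bad <- !blank & !zip_ok
      if (any(bad))
        sf_stop("privacy_error", sprintf(
          "cannot truncate non-ZIP value(s): %s",
          paste(unique(out[bad]), collapse = ", ")))
      out[!blank] <- substr(out[!blank], 1, 3)
      out
    })
}

# privacy rules declared on dictionary fields
config_privacy_rules <- function(cfg) {
  rules <- list()
  for (ts in cfg$dictionaries) {
    for (f in ts$fields) {
      if (!is.null(f$privacy))
        rules[[length(rules) + 1L]] <-
          privacy_rule(ts$name, f$name, f$privacy, f$privacy_applied_at)
      else if (f$pii_class == "direct")
        # direct identifiers without an explicit override are always dropped
        rules[[length(rules) + 1L]] <- privacy_rule(ts$name, f$name, "drop", "import")
    }
  }
  rules
}

# the storage-side shape of a field after import-time privacy transforms
storage_field_spec <- function(f) {
  if (is.null(f$privacy) && f$pii_class != "direct") return(f)
  transform <- f$privacy %||% "drop"
  at <- f$privacy_applied_at %||% "import"
  if (!at %in% c("import", "both")) return(f)
  if (transform == "truncate_date_to_month") {
    f$type <- "month"            # storage-only type: YYYY-MM
    f$max_length <- 7L
    f$date_bounds <- NULL
  } else if (transform == "truncate_zip_to_3") {
    f$max_length <- 3L
  } else if (transform == "drop") {
    f$required <- FALSE
    f$type <- "text"
    f$max_length <- 0L           # nothing may be stored
    f$allowed_codes <- NULL
  }
  f
}
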