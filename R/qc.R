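# Rule-based quality control of tabular submissions.
#
# Every submission is validated cell by cell against the study dictionary:
# data type, length, calendar-date validity and bounds, enumerated codes,
# required fields, duplicate primary keys, and orphaned foreign keys. The
# outcome is an itemized, byte-reproducible report plus an atomic
# accepted/rejected verdict -- a rejected submission is returned to the
# submitter in full for correction and resubmission.

empty_issues <- function() {
  data.frame(kind = character(), table = character(), row = integer(),
             field = character(), observed = character(), expected = character(),
             severity = character(), stringsAsFactors = FALSE)
}

new_issue <- function(kind, table, row, field, observed, expected, policy) {
  data.frame(kind = kind, table = table, row = as.integer(row), field = field,
             observed = observed, expected = expected,
             severity = unname(policy[[kind]]), stringsAsFactors = FALSE)
}

#' Validate one row against its table schema
#'
#' Checks run per field in dictionary order: REQUIRED (an empty cell in a
#' required field), then TYPE, then LENGTH / DATE / ENUM. A failed TYPE check
#' suppresses that field's downstream checks for the row, so each cell yields
#' at most one root cause. Empty optional cells are valid and skip all checks.
#'
#' Dates are accepted in ISO-8601 (`YYYY-MM-DD`) only: a value that does not
#' match the pattern is a TYPE issue; a pattern-conformant value that is not
#' a real calendar date, or falls outside the field's declared bounds, is a
#' DATE issue.
#'
#' @param row Named character vector (or 1-row list) of cell values; missing
#'   cells are empty strings.
#' @param schema The [table_schema()].
#' @param row_ordinal 1-based row number in the submitted file (header
#'   excluded).
#' @param policy Named severity vector (kind -> reject/warn); defaults to the
#'   package policy.
#' @return A data.frame of issues (possibly 0-row), one per violated
#'   constraint.
#' @export
check_row <- function(row, schema, row_ordinal, policy = DEFAULT_QC_POLICY) {
  issues <- list()
  for (f in schema$fields) {
    v <- row[[f$name]]
    v <- if (is.null(v) || is.na(v)) "" else as.character(v)
    if (!nzchar(v)) {
      if (f$required)
        issues[[length(issues) + 1L]] <- new_issue(
          "REQUIRED", schema$name, row_ordinal, f$name, "",
          "non-empty value required", policy)
      next
    }
    # TYPE: one root cause per cell -- a type failure suppresses the rest
    type_ok <- switch(f$type,
      integer = is_integer_literal(v),
      decimal = is_decimal_literal(v),
      date = iso_date_pattern(v),
      datetime = grepl("^\\d{4}-\\d{2}-\\d{2}[T ]\\d{2}:\\d{2}(:\\d{2})?$", v),
      TRUE)
    if (!type_ok) {
      issues[[length(issues) + 1L]] <- new_issue(
        "TYPE", schema$name, row_ordinal, f$name, v,
        sprintf("value of type %s", f$type), policy)
      next
    }
    if (!is.na(f$max_length) && nchar(v, type = "chars") > f$max_length)
      issues[[length(issues) + 1L]] <- new_issue(
        "LENGTH", schema$name, row_ordinal, f$name, v,
        sprintf("at most %d characters", f$max_length), policy)
    if (f$type %in% c("date", "datetime")) {
      dpart <- substr(v, 1, 10)
      if (!iso_date_valid(dpart)) {
        issues[[length(issues) + 1L]] <- new_issue(
          "DATE", schema$name, row_ordinal, f$name, v,
          "a real calendar date", policy)
      } else if (!is.null(f$date_bounds) &&
                 (dpart < f$date_bounds[1] || dpart > f$date_bounds[2])) {
        issues[[length(issues) + 1L]] <- new_issue(
          "DATE", schema$name, row_ordinal, f$name, v,
          sprintf("date within [%s, %s]", f$date_bounds[1], f$date_bounds[2]), policy)
      }
    }
    if (f$type == "code" && !v %in% f$allowed_codes)
      issues[[length(issues) + 1L]] <- new_issue(
        "ENUM", schema$name, row_ordinal, f$name, v,
        sprintf("one of {%s}", paste(f$allowed_codes, collapse = ",")), policy)
  }
  if (length(issues) == 0) empty_issues() else do.call(rbind, issues)
}

#' Key checks over a whole table
#'
#' Duplicate primary keys: the first occurrence of a key is never flagged;
#' every later occurrence is. For append-only tables a key already present
#' in the study store is also a duplicate. Foreign keys must resolve in the
#' referenced key set (keys accepted earlier in the same submission plus the
#' store's).
#'
#' @param rows Data.frame of character cells (a parsed submission table).
#' @param schema The [table_schema()]; must declare a primary key.
#' @param context Named list: table name -> character vector of known primary
#'   keys (from the study store and/or co-submitted tables).
#' @param policy Severity policy.
#' @return Issue data.frame.
#' @export
check_keys <- function(rows, schema, context = list(), policy = DEFAULT_QC_POLICY) {
  if (length(schema$primary_key) == 0)
    sf_stop("usage_error", sprintf("table '%s' has no primary key", schema$name))
  issues <- list()
  n <- nrow(rows)
  if (n == 0) return(empty_issues())
  pk <- do.call(paste, c(unname(rows[schema$primary_key]), sep = "\r"))
  dup <- duplicated(pk)
  if (schema$append_only && !is.null(context[[schema$name]]))
    dup <- dup | pk %in% context[[schema$name]]
  pk_field <- paste(schema$primary_key, collapse = "+")
  for (i in which(dup)) {
    issues[[length(issues) + 1L]] <- new_issue(
      "DUP_KEY", schema$name, i, pk_field, gsub("\r", "+", pk[i], fixed = TRUE),
      "unique primary key", policy)
  }
  for (f in schema$fields) {
    if (f$key != "foreign") next
    known <- context[[f$foreign_target[1]]] %||% character()
    vals <- rows[[f$name]]
    if (is.null(vals)) next
    orphan <- nzchar(vals) & !vals %in% known
    for (i in which(orphan)) {
      issues[[length(issues) + 1L]] <- new_issue(
        "FK_ORPHAN", schema$name, i, f$name, vals[i],
        sprintf("existing %s.%s", f$foreign_target[1], f$foreign_target[2]), policy)
    }
  }
  if (length(issues) == 0) empty_issues() else do.call(rbind, issues)
}

# header reconciliation: declared-but-absent and undeclared columns
check_header <- function(cols, schema, policy) {
  issues <- list()
  for (m in setdiff(names(schema$fields), cols))
    issues[[length(issues) + 1L]] <- new_issue(
      "MISSING_COLUMN", schema$name, 0L, m, "",
      "declared column present in header", policy)
  for (u in setdiff(cols, names(schema$fields)))
    issues[[length(issues) + 1L]] <- new_issue(
      "UNKNOWN_COLUMN", schema$name, 0L, u, u,
      "only dictionary columns in header", policy)
  if (length(issues) == 0) empty_issues() else do.call(rbind, issues)
}

finalize_report <- function(submission_id, issues, checked_rows) {
  o <- order(issues$table, issues$row, issues$field, issues$kind, method = "radix")
  issues <- issues[o, , drop = FALSE]
  rownames(issues) <- NULL
  counts <- table(factor(issues$kind, levels = ISSUE_KINDS))
  verdict <- if (any(issues$severity == "reject")) "rejected" else "accepted"
  structure(list(submission_id = submission_id, issues = issues,
                 verdict = verdict,
                 counts = stats::setNames(as.integer(counts), names(counts)),
                 checked_rows = as.integer(checked_rows)),
            class = "validation_report")
}

#' @export
format.validation_report <- function(x, ...) {
  sprintf("<validation_report %s: %s, %d issue(s) over %d row(s)>",
          x$submission_id, x$verdict, nrow(x$issues), x$checked_rows)
}

#' @export
print.validation_report <- function(x, ...) { cat(format(x), "\n"); invisible(x) }

#' Validate a full submission against the study dictionary
#'
#' A submission is one or more delimited files, one per dictionary table.
#' Headers are reconciled first (MISSING_COLUMN / UNKNOWN_COLUMN, table-level
#' issues at row 0), then every row passes [check_row()], then [check_keys()]
#' runs with key context drawn from the study store plus tables of the same
#' submission at lower dependency levels. Issues are ordered (table, row,
#' field) so a report is byte-reproducible. The verdict is atomic: one
#' reject-severity issue rejects the whole submission.
#'
#' @param files Named list/character vector: table name -> file path. In-memory
#'   data frames of character columns are also accepted in place of paths.
#' @param config The [load_config()] result.
#' @param db Optional study store handle supplying primary-key context.
#' @param submission_id Identifier for the report; defaults to a digest of
#'   the file set.
#' @return A `validation_report`.
#' @export
validate_submission <- function(files, config, db = NULL, submission_id = NULL) {
  stopifnot(length(files) >= 1, !is.null(names(files)))
  unknown_tables <- setdiff(names(files), names(config$dictionaries))
  if (length(unknown_tables) > 0)
    sf_stop("usage_error", sprintf("submission names unknown table(s): %s",
                                   paste(unknown_tables, collapse = ", ")))
  # read everything first; unreadable files are transport errors, not findings
  tables <- lapply(files, function(f) {
    if (is.data.frame(f)) return(f)
    if (!file.exists(f)) sf_stop("transport_error", sprintf("cannot read %s", f))
    tryCatch(read_submission(f),
             error = function(e) sf_stop("transport_error", sprintf(
               "cannot parse %s: %s", f, conditionMessage(e))))
  })
  if (is.null(submission_id)) {
    digs <- vapply(seq_along(files), function(i) {
      f <- files[[i]]
      if (is.data.frame(f)) {
        tmp <- tempfile(fileext = ".csv")
        on.exit(unlink(tmp), add = TRUE)
        write_csv_file(f, tmp)
        file_digest(tmp)
      } else file_digest(f)
    }, "")
    submission_id <- content_digest(paste(names(files), digs, collapse = ";"))
  }
  policy <- config$qc_policy
  # process in dependency-level order so FK context sees co-submitted parents
  lv <- vapply(names(tables), function(nm) config$dictionaries[[nm]]$level, 1L)
  tab_order <- names(tables)[order(lv, names(tables), method = "radix")]
  context <- if (!is.null(db)) db_key_context(db) else list()
  all_issues <- list(empty_issues())
  checked <- 0L
  for (nm in tab_order) {
    schema <- config$dictionaries[[nm]]
    rows <- tables[[nm]]
    all_issues[[length(all_issues) + 1L]] <- check_header(colnames(rows), schema, policy)
    n <- nrow(rows)
    checked <- checked + n
    if (n > 0) {
      known <- colnames(rows)[colnames(rows) %in% names(schema$fields)]
      cells <- lapply(stats::setNames(known, known), function(cn) {
        v <- rows[[cn]]; v[is.na(v)] <- ""; as.character(v)
      })
      for (i in seq_len(n)) {
        rowvals <- lapply(cells, `[[`, i)
        all_issues[[length(all_issues) + 1L]] <- check_row(rowvals, schema, i, policy)
      }
    }
    all_issues[[length(all_issues) + 1L]] <- check_keys(rows, schema, context, policy)
    # expose this table's keys (file order, first occurrence wins) to
    # higher-level tables of the same submission
    if (n > 0 && all(schema$primary_key %in% colnames(rows))) {
      pk <- do.call(paste, c(unname(rows[schema$primary_key]), sep = "\r"))
      context[[nm]] <- unique(c(context[[nm]] %||% character(), pk))
    }
  }
  finalize_report(submission_id, do.call(rbind, all_issues), checked)
}

#' Render a validation report
#'
#' The delimited form carries one line per issue with every issue attribute
#' plus the submission id and verdict, and parses back losslessly with
#' [parse_report_csv()]. The human-readable form groups issues by table and
#' kind with counts.
#'
#' @param report A `validation_report`.
#' @param format `"delimited"` or `"human"`.
#' @return Character vector of output lines.
#' @export
render_report <- function(report, format = c("delimited", "human")) {
  format <- match.arg(format)
  if (format == "delimited") {
    df <- report$issues
    df$submission_id <- rep(report$submission_id, nrow(df))
    df$verdict <- rep(report$verdict, nrow(df))
    con <- textConnection("out", "w", local = TRUE)
    utils::write.csv(df, con, row.names = FALSE)
    close(con)
    return(out)
  }
  lines <- c(sprintf("Submission %s: %s", report$submission_id, toupper(report$verdict)),
             sprintf("Rows checked: %d; issues: %d", report$checked_rows, nrow(report$issues)))
  if (nrow(report$issues) > 0) {
    agg <- stats::aggregate(list(n = report$issues$row),
                            by = list(table = report$issues$table, kind = report$issues$kind),
                            FUN = length)
    agg <- agg[order(agg$table, agg$kind), ]
    lines <- c(lines, sprintf("  %-12s %-14s %d", agg$table, agg$kind, agg$n))
  }
  lines
}

#' Parse a delimited validation report back into a `validation_report`
#'
#' @param lines Character vector produced by `render_report(., "delimited")`,
#'   or a path to such a file.
#' @return A `validation_report` equal (issues, verdict, id) to the original.
#' @export
parse_report_csv <- function(lines) {
  if (length(lines) == 1 && file.exists(lines)) lines <- readLines(lines)
  df <- utils::read.csv(text = lines, colClasses = "character", na.strings = NULL)
  if (nrow(df) == 0)   # header-only: an accepted, issue-free report
    return(finalize_report(NA_character_, empty_issues(), checked_rows = NA_integer_))
  id <- df$submission_id[1]
  df$row <- as.integer(df$row)
  issues <- df[, c("kind", "table", "row", "field", "observed", "expected", "severity")]
  finalize_report(id, issues, checked_rows = NA_integer_)
}

# write the delimited report next to a submission; returns the path
write_report_file <- function(report, path) {
  writeLines(render_report(report, "delimited"), path, useBytes = TRUE)
  invisible(path)
}
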