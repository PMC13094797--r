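# Configuration-driven reporting.
#
# Each report is declared in the project configuration: which fields to
# extract from which tables, an ordered list of transforms from a small
# closed vocabulary (rename, lookup recode, constant, cross-field map,
# privacy), the outbound target schema, and report-specific cross-field QC
# hooks. Outbound rows are themselves validated against the target schema --
# a report is a valid submission to its recipient's second QC stage -- and a
# report is only emitted when its own verdict is accepted.

TRANSFORM_KINDS <- c("rename", "lookup_recode", "constant", "cross_field", "privacy")

parse_report_yaml <- function(y) {
  transforms <- lapply(y$transforms %||% list(), function(tr) {
    if (!tr$kind %in% TRANSFORM_KINDS)
      sf_stop("config_error", sprintf("report '%s': unknown transform kind '%s'",
                                      y$name, tr$kind))
    tr
  })
  hooks <- lapply(y$qc_hooks %||% list(), function(h) {
    if (!identical(h$kind, "required_when"))
      sf_stop("config_error", sprintf("report '%s': unknown qc hook kind '%s'",
                                      y$name, h$kind))
    h
  })
  target <- parse_schema_yaml(paste0("report_", y$name), y$target_schema)
  structure(list(name = y$name,
                 source = lapply(y$source, function(s)
                   list(table = s$table, fields = as.character(s$fields))),
                 transforms = transforms, qc_hooks = hooks,
                 target_schema = target,
                 destination = y$destination %||% NULL),
            class = "report_spec")
}

report_spec_yaml <- function(r) {
  field_yaml <- function(f) {
    out <- list(name = f$name, type = f$type)
    if (!is.na(f$max_length)) out$max_length <- f$max_length
    if (!is.null(f$allowed_codes)) out$allowed_codes <- as.list(f$allowed_codes)
    if (f$required) out$required <- TRUE
    if (f$key != "none") out$key <- f$key
    if (!is.null(f$date_bounds)) out$date_bounds <- as.list(f$date_bounds)
    out
  }
  list(name = r$name,
       source = lapply(r$source, function(s)
         list(table = s$table, fields = as.list(s$fields))),
       transforms = r$transforms,
       qc_hooks = r$qc_hooks,
       target_schema = list(level = r$target_schema$level,
                            fields = unname(lapply(r$target_schema$fields, field_yaml))),
       destination = r$destination)
}

#' Digest of a report specification
#'
#' Transform order is semantically significant; permuting declared transforms
#' changes this digest, so a reordering is always detected as a spec change.
#'
#' @param spec A report spec from the configuration.
#' @return Hex digest string.
#' @export
report_spec_digest <- function(spec) {
  content_digest(yaml::as.yaml(report_spec_yaml(spec)))
}

# resolve a report spec by name or pass one through
get_report_spec <- function(spec, config) {
  if (is.character(spec)) {
    got <- config$reports[[spec]]
    if (is.null(got)) sf_stop("usage_error", sprintf("no report '%s' configured", spec))
    return(got)
  }
  spec
}

apply_transform <- function(rows, tr, config, db) {
  switch(tr$kind,
    rename = {
      if (!tr$field %in% colnames(rows))
        sf_stop("report_spec_error", sprintf("rename: no working column '%s'", tr$field))
      colnames(rows)[colnames(rows) == tr$field] <- tr$to
      rows
    },
    lookup_recode = {
      lk <- config$lookups[[tr$lookup]]
      if (is.null(lk)) sf_stop("report_spec_error", sprintf("unknown lookup '%s'", tr$lookup))
      if (!tr$field %in% colnames(rows))
        sf_stop("report_spec_error", sprintf("lookup_recode: no working column '%s'", tr$field))
      rows[[tr$to %||% paste0(tr$field, "_group")]] <-
        resolve_lookup(lk, rows[[tr$field]], tr$version %||% NULL)
      rows
    },
    constant = { rows[[tr$to]] <- tr$value; rows },
    cross_field = {
      need <- c(tr$when_field, tr$value_field)
      miss <- setdiff(need, colnames(rows))
      if (length(miss) > 0)
        sf_stop("report_spec_error", sprintf("cross_field: missing column(s) %s",
                                             paste(miss, collapse = ", ")))
      rows[[tr$to]] <- ifelse(rows[[tr$when_field]] == tr$equals,
                              rows[[tr$value_field]], tr$else_value %||% "")
      rows
    },
    privacy = {
      if (!tr$field %in% colnames(rows))
        sf_stop("report_spec_error", sprintf("privacy: no working column '%s'", tr$field))
      rows[[tr$field]] <- apply_privacy(rows[[tr$field]], tr$transform)
      rows
    })
}

# cross-field hooks: declarative predicates checked row-wise on outbound rows
apply_hooks <- function(rows, hooks, table, policy) {
  issues <- list(empty_issues())
  for (h in hooks) {
    need <- c(h$field, h$when_field)
    miss <- setdiff(need, colnames(rows))
    if (length(miss) > 0)
      sf_stop("report_spec_error", sprintf(
        "qc hook references absent field(s): %s", paste(miss, collapse = ", ")))
    viol <- rows[[h$when_field]] == h$equals & !nzchar(rows[[h$field]])
    for (i in which(viol))
      issues[[length(issues) + 1L]] <- new_issue(
        "REQUIRED", table, i, h$field, "",
        sprintf("'%s' required when %s = %s", h$field, h$when_field, h$equals),
        policy)
  }
  do.call(rbind, issues)
}

#' Build a report from the study store
#'
#' Extracts the declared source fields (multiple source tables are joined
#' child-to-parent through the dictionary's foreign keys), applies the
#' declared transforms in order, then validates the outbound rows against
#' the report's target schema and its cross-field QC hooks. Rows are
#' returned only when the report's own verdict is accepted; the validation
#' report is returned either way.
#'
#' Hooks referencing a field absent from the working rows fail at build
#' start, before any row is processed.
#'
#' @param spec Report name (in the configuration) or a report spec.
#' @param config Project configuration.
#' @param db Store handle.
#' @return List: `rows` (data.frame, or `NULL` when withheld), `report`
#'   (a `validation_report`), `spec_digest`.
#' @export
build_report <- function(spec, config, db) {
  spec <- get_report_spec(spec, config)
  # extraction: first source anchors; later sources join via a foreign key
  base_src <- spec$source[[1]]
  rows <- db_table(db, base_src$table)
  rows <- rows[base_src$fields]
  if (length(spec$source) > 1) {
    anchor_schema <- config$dictionaries[[base_src$table]]
    anchor_full <- db_table(db, base_src$table)
    for (src in spec$source[-1]) {
      fk <- Filter(function(f) f$key == "foreign" && f$foreign_target[1] == src$table,
                   anchor_schema$fields)
      if (length(fk) == 0)
        sf_stop("report_spec_error", sprintf(
          "report '%s': no foreign key from '%s' to '%s'",
          spec$name, base_src$table, src$table))
      fk <- fk[[1]]
      parent <- db_table(db, src$table)
      m <- match(anchor_full[[fk$name]], parent[[fk$foreign_target[2]]])
      for (fld in src$fields) {
        v <- parent[[fld]][m]
        v[is.na(v)] <- ""
        rows[[fld]] <- v
      }
    }
  }
  for (tr in spec$transforms) rows <- apply_transform(rows, tr, config, db)
  # keep target columns, in target order
  target_cols <- names(spec$target_schema$fields)
  miss <- setdiff(target_cols, colnames(rows))
  if (length(miss) > 0)
    sf_stop("report_spec_error", sprintf(
      "report '%s' produces no column(s): %s", spec$name, paste(miss, collapse = ", ")))
  rows <- rows[target_cols]
  # hooks fail fast on absent fields even with zero rows
  hook_issues <- apply_hooks(rows, spec$qc_hooks, spec$target_schema$name, config$qc_policy)
  # outbound files stand alone: foreign-key roles borrowed from the study
  # dictionary cannot resolve outside the store and are not re-checked here
  standalone <- spec$target_schema
  standalone$fields <- lapply(standalone$fields, function(f) {
    if (f$key == "foreign") { f$key <- "none"; f$foreign_target <- NULL }
    f
  })
  spec$target_schema <- standalone
  qc <- validate_submission(stats::setNames(list(rows), spec$target_schema$name),
                            structure(list(dictionaries = stats::setNames(
                                             list(spec$target_schema),
                                             spec$target_schema$name),
                                           qc_policy = config$qc_policy,
                                           lookups = config$lookups,
                                           buckets = list(), reports = list()),
                                      class = "project_config"),
                            submission_id = paste0("report:", spec$name))
  report <- finalize_report(qc$submission_id, rbind(qc$issues, hook_issues),
                            qc$checked_rows)
  list(rows = if (report$verdict == "accepted") rows else NULL,
       report = report, spec_digest = report_spec_digest(spec))
}

#' Write built report rows to a destination
#'
#' CSV in target-schema column order with RFC-4180 quoting, written to a
#' temporary file and renamed into place so a partial file is never visible.
#' Writing into a bucket's download directory models onward transfer to the
#' data coordinating center.
#'
#' @param rows Accepted rows from [build_report()].
#' @param spec Report spec or name.
#' @param destination Directory or file path; a bucket object's download
#'   directory is also accepted.
#' @param config Project configuration.
#' @return File receipt: list with `path`, `digest`, `rows`.
#' @export
write_report <- function(rows, spec, destination, config) {
  if (is.null(rows)) sf_stop("usage_error", "report was withheld; nothing to write")
  spec <- get_report_spec(spec, config)
  if (inherits(destination, "bucket")) destination <- destination$download_dir
  path <- if (dir.exists(destination))
    file.path(destination, paste0(spec$name, ".csv")) else destination
  dir_ok <- dir.exists(dirname(path))
  if (!dir_ok) sf_stop("transport_error", sprintf("unwritable destination: %s", path))
  tmp <- paste0(path, ".part")
  write_csv_file(rows, tmp)
  ok <- file.rename(tmp, path)
  if (!ok) { unlink(tmp); sf_stop("transport_error", sprintf("cannot write %s", path)) }
  list(path = path, digest = file_digest(path), rows = nrow(rows))
}
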