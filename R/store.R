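# The canonical study database.
#
# An embedded relational store: one relation per dictionary table, with the
# dictionary's constraints (type, length, nullability, enumerated codes,
# primary and foreign keys) materialized at the storage layer. The store
# enforces these constraints itself, in a code path deliberately separate
# from the QC engine, so that it acts as a redundant, passive QC line: a row
# the dictionary forbids is refused even when inserted directly.
#
# Imports are transactional (all-or-nothing) and idempotent by submission
# digest, so the archive of accepted submissions is replayable for audit.

#' Open a study store
#'
#' @param dir Optional directory of a previously saved store ([db_save()]);
#'   when given, relations are reloaded from it.
#' @return A `study_db` handle (an environment).
#' @export
db_open <- function(dir = NULL) {
  db <- new.env(parent = emptyenv())
  db$tables <- list()        # table name -> data.frame of character columns
  db$storage <- list()       # table name -> storage table_schema
  db$lookups <- list()       # lookup name -> lookup_table
  db$derived <- list()       # "<table>.<lookup>" -> recode relation
  db$imported <- character() # submission digests already committed
  db$processed <- character()# intake file digests already handled
  db$id_changes <- data.frame(table = character(), old_id = character(),
                              new_id = character(), effective_date = character(),
                              stringsAsFactors = FALSE)
  db$audit <- data.frame(table = character(), key = character(),
                         action = character(), submission_id = character(),
                         stringsAsFactors = FALSE)
  db$survey <- NULL
  class(db) <- c("study_db", "environment")
  if (!is.null(dir)) db_load_into(db, dir)
  db
}

#' @export
format.study_db <- function(x, ...) {
  sprintf("<study_db: %d relation(s), %d committed import(s)>",
          length(x$tables), length(x$imported))
}

#' @export
print.study_db <- function(x, ...) { cat(format(x), "\n"); invisible(x) }

#' Materialize the study schema
#'
#' Creates one relation per dictionary table (with the dictionary's
#' constraints attached at the storage layer), the lookup relations, the
#' identifier-change relation, and the long-format survey relations.
#' Import-stage privacy transforms reshape the stored column: a month-level
#' date column stores `YYYY-MM`, a truncated ZIP stores 3 characters.
#'
#' @param config A [load_config()] result with at least one table.
#' @param db A [db_open()] handle.
#' @return `db`, invisibly.
#' @export
create_schema <- function(config, db) {
  if (length(config$dictionaries) == 0)
    sf_stop("config_error", "a study must have at least one table")
  for (ts in config$dictionaries) {
    storage_fields <- lapply(ts$fields, storage_field_spec)
    storage <- ts
    storage$fields <- storage_fields
    if (!is.null(db$tables[[ts$name]])) {
      if (!identical(colnames(db$tables[[ts$name]]), names(ts$fields)))
        sf_stop("migration_error", sprintf(
          "existing relation '%s' is incompatible with the dictionary", ts$name))
    } else {
      df <- as.data.frame(stats::setNames(
        rep(list(character()), length(ts$fields)), names(ts$fields)),
        stringsAsFactors = FALSE, check.names = FALSE)
      db$tables[[ts$name]] <- df
    }
    db$storage[[ts$name]] <- storage
  }
  db$lookups <- config$lookups
  if (is.null(db$survey)) db$survey <- survey_relations()
  invisible(db)
}

# ---- the materialized constraint engine ------------------------------------
# Column-wise validation, independent of qc_engine::check_row by design.

storage_violation <- function(table, row, field, value, why) {
  sf_stop("constraint_violation",
          sprintf("relation '%s' refused row %d: column '%s' value '%s' (%s)",
                  table, row, field, value, why),
          table = table, row = row, field = field)
}

check_column_storage <- function(values, f, table) {
  bad_at <- function(ok, why) {
    i <- which(!ok)[1]
    if (!is.na(i)) storage_violation(table, i, f$name, values[i], why)
  }
  present <- nzchar(values)
  if (f$required) bad_at(present, "NOT NULL")
  v <- values[present]
  idx <- which(present)
  bad_sub <- function(ok, why) {
    i <- idx[which(!ok)[1]]
    if (length(i) == 1 && !is.na(i)) storage_violation(table, i, f$name, values[i], why)
  }
  if (!is.na(f$max_length)) bad_sub(nchar(v) <= f$max_length, "length constraint")
  switch(f$type,
    integer = bad_sub(!is.na(suppressWarnings(as.integer(v))) &
                        grepl("^[+-]?[0-9]+$", v), "integer column"),
    decimal = bad_sub(!is.na(suppressWarnings(as.numeric(v))) &
                        !grepl("[eE]", v), "numeric column"),
    date = {
      d <- as.Date(v, format = "%Y-%m-%d")
      ok <- !is.na(d) & grepl("^\\d{4}-\\d{2}-\\d{2}$", v)
      if (!is.null(f$date_bounds))
        ok <- ok & !is.na(d) & d >= as.Date(f$date_bounds[1]) & d <= as.Date(f$date_bounds[2])
      bad_sub(ok, "date column")
    },
    month = bad_sub(grepl("^\\d{4}-(0[1-9]|1[0-2])$", v), "year-month column"),
    code = bad_sub(v %in% f$allowed_codes, "enumerated check constraint"),
    NULL)
  invisible(TRUE)
}

pk_string <- function(df, pk) do.call(paste, c(unname(df[pk]), sep = "\r"))

#' Insert rows directly into a relation
#'
#' The storage layer's own constraint check: every column constraint, primary
#' key uniqueness (within the batch and against stored rows) and foreign key
#' resolution are enforced here, independently of the QC engine. The first
#' violation aborts the whole insert (nothing is written).
#'
#' @param db Store handle.
#' @param table Relation name.
#' @param rows Data.frame of character cells with the relation's columns
#'   (missing optional columns are filled empty).
#' @return Number of rows written, invisibly.
#' @export
db_insert_rows <- function(db, table, rows) {
  storage <- db$storage[[table]]
  if (is.null(storage)) sf_stop("usage_error", sprintf("no relation '%s'", table))
  cols <- names(storage$fields)
  for (m in setdiff(cols, colnames(rows))) rows[[m]] <- ""
  extra <- setdiff(colnames(rows), cols)
  if (length(extra) > 0)
    sf_stop("constraint_violation", sprintf(
      "relation '%s' has no column(s): %s", table, paste(extra, collapse = ", ")))
  rows <- rows[cols]
  for (cn in cols) {
    v <- rows[[cn]]; v[is.na(v)] <- ""; rows[[cn]] <- as.character(v)
  }
  n <- nrow(rows)
  if (n == 0) return(invisible(0L))
  for (f in storage$fields) check_column_storage(rows[[f$name]], f, table)
  # primary key: required and unique
  pkv <- pk_string(rows, storage$primary_key)
  blank <- !nzchar(gsub("\r", "", pkv, fixed = TRUE))
  if (any(blank)) storage_violation(table, which(blank)[1],
                                    paste(storage$primary_key, collapse = "+"),
                                    "", "PRIMARY KEY NOT NULL")
  dup <- duplicated(pkv) | pkv %in% pk_string(db$tables[[table]], storage$primary_key)
  if (any(dup)) storage_violation(table, which(dup)[1],
                                  paste(storage$primary_key, collapse = "+"),
                                  gsub("\r", "+", pkv[which(dup)[1]], fixed = TRUE),
                                  "PRIMARY KEY unique")
  # foreign keys resolve against stored parent relations
  for (f in storage$fields) {
    if (f$key != "foreign") next
    parent <- db$tables[[f$foreign_target[1]]]
    known <- if (is.null(parent)) character() else parent[[f$foreign_target[2]]]
    vals <- rows[[f$name]]
    orphan <- nzchar(vals) & !vals %in% known
    if (any(orphan)) storage_violation(table, which(orphan)[1], f$name,
                                       vals[which(orphan)[1]], "FOREIGN KEY")
  }
  db$tables[[table]] <- rbind(db$tables[[table]], rows)
  invisible(n)
}

# delete-then-insert used by upserting imports (audited by the caller)
db_replace_rows <- function(db, table, rows) {
  storage <- db$storage[[table]]
  pkv <- pk_string(rows, storage$primary_key)
  existing <- pk_string(db$tables[[table]], storage$primary_key)
  keep <- !existing %in% pkv
  db$tables[[table]] <- db$tables[[table]][keep, , drop = FALSE]
  db_insert_rows(db, table, rows)
}

#' Number of rows in a relation
#' @param db Store handle.
#' @param table Relation name.
#' @export
db_nrow <- function(db, table) nrow(db$tables[[table]] %||% data.frame())

#' Fetch a relation as a data.frame
#' @param db Store handle.
#' @param table Relation name.
#' @export
db_table <- function(db, table) {
  t <- db$tables[[table]]
  if (is.null(t)) sf_stop("usage_error", sprintf("no relation '%s'", table))
  t
}

# primary-key context for the QC engine; superseded identifiers whose change
# chain ends at a stored key are accepted references (canonicalized on import)
db_key_context <- function(db) {
  ctx <- list()
  for (nm in names(db$tables)) {
    st <- db$storage[[nm]]
    if (is.null(st) || nrow(db$tables[[nm]]) == 0) next
    keys <- pk_string(db$tables[[nm]], st$primary_key)
    old <- db$id_changes$old_id[db$id_changes$table == nm]
    if (length(old) > 0) {
      resolved <- vapply(old, function(id) resolve_identifier(nm, id, db), "")
      keys <- c(keys, old[resolved %in% keys])
    }
    ctx[[nm]] <- keys
  }
  ctx
}

# ---- transactional import ---------------------------------------------------

import_result <- function(submission_id, attempted, written, outcome, detail = NULL) {
  structure(list(submission_id = submission_id,
                 rows_attempted = as.integer(attempted),
                 rows_written = as.integer(written),
                 outcome = outcome, detail = detail),
            class = "import_result")
}

#' @export
format.import_result <- function(x, ...) {
  sprintf("<import %s: %s, %d/%d row(s)>",
          x$submission_id, x$outcome, x$rows_written, x$rows_attempted)
}

#' @export
print.import_result <- function(x, ...) { cat(format(x), "\n"); invisible(x) }

#' Import an accepted submission into the study store
#'
#' All rows of all files are written in one transaction: a mid-import
#' constraint violation rolls everything back (`rows_written = 0`) and
#' identifies the violating row. Re-importing an already-committed
#' submission id is a no-op with outcome `committed` and `rows_written = 0`,
#' making the submission archive replayable. Import-stage privacy transforms
#' are applied before storage; foreign keys pointing at a table with recorded
#' identifier changes are canonicalized through [resolve_identifier()], the
#' original preserved in the change trail.
#'
#' For tables declared `append_only: false`, rows whose primary key already
#' exists upsert the stored row, and the replacement is recorded in the audit
#' relation.
#'
#' @param files Named list: table name -> path or character data.frame.
#' @param report The submission's accepted `validation_report`.
#' @param config Project configuration.
#' @param db Store handle.
#' @return An `import_result`.
#' @export
import_submission <- function(files, report, config, db) {
  if (!inherits(report, "validation_report") || report$verdict != "accepted")
    sf_stop("usage_error", "import requires an accepted validation report")
  sid <- report$submission_id
  tables <- lapply(files, function(f) if (is.data.frame(f)) f else read_submission(f))
  attempted <- sum(vapply(tables, nrow, 0L))
  if (sid %in% db$imported)
    return(import_result(sid, attempted, 0L, "committed", "already imported"))

  snapshot <- list(tables = db$tables, audit = db$audit)
  lv <- vapply(names(tables), function(nm) config$dictionaries[[nm]]$level, 1L)
  ord <- names(tables)[order(lv, names(tables), method = "radix")]
  written <- 0L
  res <- tryCatch({
    for (nm in ord) {
      rows <- tables[[nm]]
      schema <- config$dictionaries[[nm]]
      rows <- rows[intersect(colnames(rows), names(schema$fields))]
      # import-stage privacy
      for (f in schema$fields) {
        at <- f$privacy_applied_at %||% "import"
        transform <- f$privacy %||% (if (f$pii_class == "direct") "drop" else NULL)
        if (!is.null(transform) && at %in% c("import", "both") &&
            f$name %in% colnames(rows))
          rows[[f$name]] <- apply_privacy(rows[[f$name]], transform)
      }
      # canonicalize foreign keys through the identifier-change trail
      for (f in schema$fields) {
        if (f$key == "foreign" && f$name %in% colnames(rows) &&
            any(db$id_changes$table == f$foreign_target[1])) {
          rows[[f$name]] <- vapply(rows[[f$name]], function(id)
            if (nzchar(id)) resolve_identifier(f$foreign_target[1], id, db) else id, "")
        }
      }
      if (schema$append_only || db_nrow(db, nm) == 0) {
        written <- written + db_insert_rows(db, nm, rows)
      } else {
        pkv <- pk_string(rows[schema$primary_key], schema$primary_key)
        existing <- pk_string(db$tables[[nm]], schema$primary_key)
        upd <- pkv %in% existing
        if (any(upd))
          db$audit <- rbind(db$audit, data.frame(
            table = nm, key = gsub("\r", "+", pkv[upd], fixed = TRUE),
            action = "upsert", submission_id = sid, stringsAsFactors = FALSE))
        written <- written + db_replace_rows(db, nm, rows)
      }
    }
    db$imported <- c(db$imported, sid)
    import_result(sid, attempted, attempted, "committed")
  }, constraint_violation = function(e) {
    db$tables <- snapshot$tables
    db$audit <- snapshot$audit
    import_result(sid, attempted, 0L, "rolled_back", conditionMessage(e))
  })
  res
}

# ---- lookup recoding --------------------------------------------------------

#' Recode a stored column through a lookup table
#'
#' Writes (or refreshes) a derived relation holding the study grouping for
#' every row of the source table; the original column is never touched.
#' Unmapped originals receive the [UNMAPPED] sentinel and are counted.
#'
#' @param table,field Source column; must match the lookup's declared source.
#' @param lookup A [lookup_table()] or its name in the store.
#' @param db Store handle.
#' @param version Lookup version (default: latest).
#' @return List with `relation` (name of the derived relation), `n`,
#'   `unmapped`, `changed` (rows whose grouping differs from the previous
#'   recode, `NA` on first run).
#' @export
recode <- function(table, field, lookup, db, version = NULL) {
  if (is.character(lookup)) lookup <- db$lookups[[lookup]]
  if (is.null(lookup)) sf_stop("usage_error", "unknown lookup")
  if (!identical(lookup$source, c(table, field)))
    sf_stop("usage_error", sprintf("lookup '%s' does not source (%s, %s)",
                                   lookup$name, table, field))
  t <- db_table(db, table)
  if (!field %in% colnames(t))
    sf_stop("usage_error", sprintf("no column '%s' in '%s'", field, table))
  version <- version %||% lookup$latest
  st <- db$storage[[table]]
  groups <- resolve_lookup(lookup, t[[field]], version)
  rel_name <- paste0(table, ".", lookup$name)
  new_rel <- data.frame(key = pk_string(t, st$primary_key),
                        original = t[[field]], group = groups,
                        version = as.integer(version), stringsAsFactors = FALSE)
  old_rel <- db$derived[[rel_name]]
  changed <- if (is.null(old_rel)) NA_integer_ else {
    m <- match(new_rel$key, old_rel$key)
    sum(is.na(m) | new_rel$group != old_rel$group[m])
  }
  db$derived[[rel_name]] <- new_rel
  list(relation = rel_name, n = nrow(new_rel),
       unmapped = sum(groups == UNMAPPED), changed = changed)
}

# ---- identifier-change tracking --------------------------------------------

#' Record a change of identifier
#'
#' @param db Store handle.
#' @param table Table whose identifiers changed.
#' @param old_id,new_id The change.
#' @param effective_date ISO date.
#' @export
record_identifier_change <- function(db, table, old_id, new_id, effective_date) {
  db$id_changes <- rbind(db$id_changes, data.frame(
    table = table, old_id = old_id, new_id = new_id,
    effective_date = effective_date, stringsAsFactors = FALSE))
  invisible(db)
}

#' Resolve an identifier to its canonical terminus
#'
#' Follows the identifier-change chain (old -> new -> newer ...) to its end;
#' identity when no change is recorded. A cycle is a data-integrity error.
#'
#' @param table Table name.
#' @param id Identifier to resolve.
#' @param db Store handle.
#' @return The canonical identifier.
#' @export
resolve_identifier <- function(table, id, db) {
  ch <- db$id_changes[db$id_changes$table == table, , drop = FALSE]
  if (nrow(ch) == 0) return(id)
  seen <- character()
  cur <- id
  repeat {
    nxt <- ch$new_id[match(cur, ch$old_id)]
    if (is.na(nxt)) return(cur)
    if (nxt %in% c(seen, cur))
      sf_stop("integrity_error", sprintf("identifier change cycle at '%s'", nxt))
    seen <- c(seen, cur)
    cur <- nxt
  }
}

# ---- persistence and inspection ---------------------------------------------

#' Export a relation to CSV
#' @param db Store handle.
#' @param table Relation name.
#' @param path Destination file.
#' @export
db_export_csv <- function(db, table, path) {
  write_csv_file(db_table(db, table), path)
}

#' Save a store to a directory of plain-text files
#' @param db Store handle.
#' @param dir Destination directory (created if needed).
#' @export
db_save <- function(db, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(db$tables)) write_csv_file(db$tables[[nm]], file.path(dir, paste0("table__", nm, ".csv")))
  for (nm in names(db$derived)) write_csv_file(db$derived[[nm]], file.path(dir, paste0("derived__", nm, ".csv")))
  write_csv_file(db$id_changes, file.path(dir, "id_changes.csv"))
  write_csv_file(db$audit, file.path(dir, "audit.csv"))
  if (!is.null(db$survey))
    for (nm in names(db$survey)) write_csv_file(db$survey[[nm]], file.path(dir, paste0("survey__", nm, ".csv")))
  jsonlite::write_json(list(imported = db$imported, processed = db$processed),
                       file.path(dir, "meta.json"))
  invisible(dir)
}

db_load_into <- function(db, dir) {
  for (f in list.files(dir, pattern = "^table__.*\\.csv$")) {
    nm <- sub("^table__(.*)\\.csv$", "\\1", f)
    db$tables[[nm]] <- read_submission(file.path(dir, f))
  }
  for (f in list.files(dir, pattern = "^derived__.*\\.csv$")) {
    nm <- sub("^derived__(.*)\\.csv$", "\\1", f)
    db$derived[[nm]] <- read_submission(file.path(dir, f))
  }
  for (f in list.files(dir, pattern = "^survey__.*\\.csv$")) {
    nm <- sub("^survey__(.*)\\.csv$", "\\1", f)
    if (is.null(db$survey)) db$survey <- survey_relations()
    db$survey[[nm]] <- read_submission(file.path(dir, f))
  }
  if (file.exists(file.path(dir, "id_changes.csv")))
    db$id_changes <- read_submission(file.path(dir, "id_changes.csv"))
  if (file.exists(file.path(dir, "meta.json"))) {
    meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
    db$imported <- as.character(meta$imported %||% character())
    db$processed <- as.character(meta$processed %||% character())
  }
  invisible(db)
}

#' Schema DDL dump for inspection
#'
#' A human-readable `CREATE TABLE`-style rendering of the materialized
#' schema, for review against the data dictionary.
#'
#' @param config Project configuration.
#' @return Character vector of DDL lines.
#' @export
db_ddl <- function(config) {
  out <- character()
  for (ts in config$dictionaries) {
    cols <- vapply(ts$fields, function(f) {
      sf <- storage_field_spec(f)
      bits <- c(sprintf("  %s %s", sf$name, toupper(sf$type)),
                if (!is.na(sf$max_length)) sprintf("(%d)", sf$max_length),
                if (sf$required) " NOT NULL",
                if (!is.null(sf$allowed_codes))
                  sprintf(" CHECK IN (%s)", paste(sf$allowed_codes, collapse = ",")),
                if (sf$key == "foreign")
                  sprintf(" REFERENCES %s(%s)", sf$foreign_target[1], sf$foreign_target[2]))
      paste(bits, collapse = "")
    }, "")
    out <- c(out, sprintf("CREATE TABLE %s (", ts$name),
             paste0(cols, ","),
             sprintf("  PRIMARY KEY (%s)", paste(ts$primary_key, collapse = ", ")),
             ");")
  }
  out
}
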