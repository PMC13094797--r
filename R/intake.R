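# Per-organization intake buckets.
#
# Every submitting organization exchanges files through a bucket with three
# directories -- upload, download, archive. Submitters drop files in upload;
# accepted submissions move to archive (timestamped, digest-suffixed) and are
# imported; rejected submissions come back in download together with the
# itemized QC report. Transport here is a local-filesystem abstraction; a
# remote transport (sFTP and the like) would implement the same
# list/get/put/delete surface but is deliberately out of scope.
#
# A polling pass (run_cycle) is idempotent per file digest, so it is safe as
# a cron job or behind a listener: reprocessing never double-imports.

#' Initialize intake buckets
#'
#' Creates `<root>/<org_id>/{upload,download,archive}` for every bucket in
#' the configuration.
#'
#' @param config Project configuration.
#' @param root Directory under which buckets live.
#' @return Named list of bucket objects.
#' @export
init_buckets <- function(config, root) {
  buckets <- lapply(config$buckets, function(b) {
    base <- file.path(root, b$org_id)
    dirs <- file.path(base, c("upload", "download", "archive"))
    for (d in dirs) dir.create(d, recursive = TRUE, showWarnings = FALSE)
    structure(list(org_id = b$org_id, upload_dir = dirs[1], download_dir = dirs[2],
                   archive_dir = dirs[3], expected_tables = b$expected_tables),
              class = "bucket")
  })
  names(buckets) <- vapply(buckets, function(b) b$org_id, "")
  buckets
}

#' @export
format.bucket <- function(x, ...) sprintf("<bucket %s>", x$org_id)

#' @export
print.bucket <- function(x, ...) { cat(format(x), "\n"); invisible(x) }

#' List new files in a bucket's upload directory
#'
#' Files already handled (tracked by content digest in the store) are not
#' returned: re-dropping a byte-identical file after acceptance is a no-op.
#' Ordering is stable by (mtime, name).
#'
#' @param bucket A bucket from [init_buckets()].
#' @param db Store handle carrying the processed-digest registry.
#' @return Character vector of file names (not paths).
#' @export
scan_bucket <- function(bucket, db) {
  if (!dir.exists(bucket$upload_dir))
    sf_stop("transport_error", sprintf("unreadable upload directory: %s", bucket$upload_dir))
  files <- list.files(bucket$upload_dir)
  if (length(files) == 0) return(character())
  paths <- file.path(bucket$upload_dir, files)
  info <- file.info(paths)
  files <- files[order(info$mtime, files, method = "radix")]
  digs <- vapply(file.path(bucket$upload_dir, files), file_digest, "")
  files[!digs %in% db$processed]
}

# table a submission file carries: "<table>__anything.csv" or "<table>.csv"
infer_table <- function(file, config) {
  base <- sub("\\.csv$", "", basename(file))
  table <- sub("__.*$", "", base)
  if (table %in% names(config$dictionaries)) table else NA_character_
}

intake_event <- function(bucket, file, disposition, report = NULL, note = NULL) {
  structure(list(bucket = bucket$org_id, file = file,
                 detected_at = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                 disposition = disposition, report = report, note = note),
            class = "intake_event")
}

#' @export
format.intake_event <- function(x, ...) {
  sprintf("<intake %s/%s: %s>", x$bucket, x$file, x$disposition)
}

#' @export
print.intake_event <- function(x, ...) { cat(format(x), "\n"); invisible(x) }

#' Process one uploaded submission file
#'
#' Runs QC and routes the file. Accepted: moved to the archive (name
#' suffixed with receipt timestamp and digest), rows imported in one
#' transaction, acceptance notification emitted. Rejected: the itemized
#' report plus the original file are placed in the download directory for
#' the submitter, and a rejection notification carries the report. An
#' unreadable or unrecognizable file is rejected with a single table-level
#' issue rather than crashing. If the import itself fails after acceptance,
#' the event is left `pending` with an alert -- the file stays in upload and
#' is recoverable (the digest is not marked processed).
#'
#' @param bucket Bucket object.
#' @param file File name within the bucket's upload directory.
#' @param config Project configuration.
#' @param db Store handle.
#' @param sinks List of notification sinks (see [sink_memory()]).
#' @return An `intake_event`.
#' @export
process_submission <- function(bucket, file, config, db, sinks = list()) {
  src <- file.path(bucket$upload_dir, file)
  if (!file.exists(src))
    sf_stop("transport_error", sprintf("no such upload: %s", src))
  dig <- file_digest(src)
  table <- infer_table(file, config)
  report <- NULL
  if (is.na(table) || file.size(src) == 0) {
    issues <- new_issue("MISSING_COLUMN", if (is.na(table)) "?" else table, 0L, "",
                        "", "readable, non-empty CSV named <table>[__suffix].csv",
                        config$qc_policy)
    report <- finalize_report(dig, issues, 0L)
  } else {
    report <- tryCatch(
      validate_submission(stats::setNames(list(src), table), config, db,
                          submission_id = dig),
      transport_error = function(e) {
        finalize_report(dig, new_issue("MISSING_COLUMN", table, 0L, "", "",
                                       paste("readable CSV:", conditionMessage(e)),
                                       config$qc_policy), 0L)
      })
  }
  if (report$verdict == "accepted") {
    imp <- tryCatch(
      import_submission(stats::setNames(list(src), table), report, config, db),
      error = function(e) e)
    ok <- inherits(imp, "import_result") && imp$outcome == "committed"
    if (!ok) {
      ev <- intake_event(bucket, file, "pending", report,
                         note = if (inherits(imp, "import_result")) imp$detail
                                else conditionMessage(imp))
      notify_all(sinks, list(kind = "alert", org = bucket$org_id, file = file,
                             body = sprintf("import failed, submission held: %s", ev$note)))
      return(ev)
    }
    stamp <- format(Sys.time(), "%Y%m%dT%H%M%S")
    dest <- file.path(bucket$archive_dir,
                      sprintf("%s.%s.%s", basename(file), stamp, substr(dig, 1, 8)))
    file.copy(src, dest, overwrite = TRUE)
    unlink(src)
    db$processed <- c(db$processed, dig)
    notify_all(sinks, list(kind = "acceptance", org = bucket$org_id, file = file,
                           body = sprintf("submission accepted (%d rows)", imp$rows_written)))
    intake_event(bucket, file, "accepted", report)
  } else {
    rep_path <- file.path(bucket$download_dir, paste0(basename(file), ".qc_report.csv"))
    write_report_file(report, rep_path)
    file.copy(src, file.path(bucket$download_dir, basename(file)), overwrite = TRUE)
    unlink(src)
    db$processed <- c(db$processed, dig)
    notify_all(sinks, list(kind = "rejection", org = bucket$org_id, file = file,
                           body = sprintf("submission rejected: %d issue(s)", nrow(report$issues)),
                           attachment = rep_path))
    intake_event(bucket, file, "rejected", report)
  }
}

#' One polling pass over all buckets
#'
#' Processes every new file in every bucket. Files are handled in dependency
#' -level order of their tables (parents before children) then (mtime, name),
#' so a donor file dropped alongside a donation file is imported first. A
#' failure on one file is contained: it never blocks other files or buckets.
#' Idempotent per digest: an immediate second pass returns no events.
#'
#' @param config Project configuration.
#' @param db Store handle.
#' @param root Bucket root directory.
#' @param sinks Notification sinks.
#' @return List of `intake_event`s in processing order.
#' @export
run_cycle <- function(config, db, root, sinks = list()) {
  buckets <- init_buckets(config, root)
  events <- list()
  for (b in buckets) {
    files <- tryCatch(scan_bucket(b, db), studyflow_error = function(e) character())
    if (length(files) == 0) next
    lvl <- vapply(files, function(f) {
      t <- infer_table(f, config)
      if (is.na(t)) 999L else config$dictionaries[[t]]$level
    }, 1L)
    files <- files[order(lvl, seq_along(files))]
    for (f in files) {
      ev <- tryCatch(process_submission(b, f, config, db, sinks),
                     error = function(e) intake_event(b, f, "pending", NULL,
                                                      note = conditionMessage(e)))
      events[[length(events) + 1L]] <- ev
    }
  }
  events
}

#' Poll buckets on an interval
#'
#' A portable polling listener (no OS file-system hooks): runs [run_cycle()]
#' every `interval` seconds for `max_cycles` passes.
#'
#' @param config,db,root,sinks As in [run_cycle()].
#' @param interval Seconds between passes.
#' @param max_cycles Number of passes before returning.
#' @return All events observed, in order.
#' @export
watch_buckets <- function(config, db, root, sinks = list(), interval = 5, max_cycles = 10) {
  events <- list()
  for (i in seq_len(max_cycles)) {
    events <- c(events, run_cycle(config, db, root, sinks))
    if (i < max_cycles) Sys.sleep(interval)
  }
  events
}

# ---- notification sinks -----------------------------------------------------
# Real email/cloud notification is infrastructure; sinks are a pluggable
# interface with two built-ins (in-memory and line-delimited file).

#' In-memory notification sink
#'
#' Records every delivered message; query with [sink_messages()]. Useful in
#' tests and interactive runs.
#' @export
sink_memory <- function() {
  e <- new.env(parent = emptyenv())
  e$messages <- list()
  structure(list(env = e), class = c("sink_memory", "notification_sink"))
}

#' Line-delimited file notification sink
#' @param path Log file; one JSON record per message.
#' @export
sink_file <- function(path) {
  structure(list(path = path), class = c("sink_file", "notification_sink"))
}

#' Deliver a message through a sink (extension point)
#'
#' Implement a `deliver.<class>` method to plug in a new transport (email,
#' chat, ticketing); [notify()] adds retry and undelivered handling on top.
#'
#' @param sink A notification sink object.
#' @param message Named list message.
#' @export
deliver <- function(sink, message) UseMethod("deliver")

#' @export
deliver.sink_memory <- function(sink, message) {
  sink$env$messages[[length(sink$env$messages) + 1L]] <- message
  invisible(TRUE)
}

#' @export
deliver.sink_file <- function(sink, message) {
  cat(jsonlite::toJSON(message, auto_unbox = TRUE), "\n",
      file = sink$path, append = TRUE, sep = "")
  invisible(TRUE)
}

#' Messages recorded by a sink
#' @param sink A sink object.
#' @export
sink_messages <- function(sink) {
  if (inherits(sink, "sink_memory")) return(sink$env$messages)
  if (inherits(sink, "sink_file") && file.exists(sink$path))
    return(lapply(readLines(sink$path), function(l) jsonlite::fromJSON(l)))
  list()
}

#' Deliver a message to one sink
#'
#' A failing sink is retried once, then recorded as undelivered; delivery
#' problems never change a submission's disposition.
#'
#' @param sink Sink object.
#' @param message Named list: `kind`, `org`, `file`, `body`, optional
#'   `attachment`.
#' @return Delivery record: list with `delivered`, `attempts`, `message`.
#' @export
notify <- function(sink, message) {
  attempts <- 0L
  ok <- FALSE
  while (attempts < 2L && !ok) {
    attempts <- attempts + 1L
    ok <- tryCatch({ deliver(sink, message); TRUE }, error = function(e) FALSE)
  }
  list(delivered = ok, attempts = attempts, message = message)
}

notify_all <- function(sinks, message) {
  lapply(sinks, notify, message = message)
}
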