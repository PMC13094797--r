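# Bucket intake workflow: scanning, routing, notification, idempotency.

drop_file <- function(from, bucket_root, org, name) {
  dest <- file.path(bucket_root, org, "upload", name)
  dir.create(dirname(dest), recursive = TRUE, showWarnings = FALSE)
  file.copy(from, dest, overwrite = TRUE)
  dest
}

test_that("bucket initialization creates the three distinct directories", {
  root <- tempfile()
  buckets <- init_buckets(demo_config(), root)
  expect_named(buckets, c("org1", "org2"))
  for (b in buckets) {
    dirs <- c(b$upload_dir, b$download_dir, b$archive_dir)
    expect_length(unique(dirs), 3)
    expect_true(all(dir.exists(dirs)))
  }
})

test_that("scan returns unprocessed files in stable order and skips known digests", {
  root <- tempfile()
  fx <- small_study()
  buckets <- init_buckets(demo_config(), root)
  db <- fresh_db()
  expect_equal(scan_bucket(buckets$org1, db), character())
  drop_file(fx$study$files$org1$donor, root, "org1", "donor__a.csv")
  Sys.sleep(0.02)
  drop_file(fx$study$files$org1$donation, root, "org1", "donation__b.csv")
  got <- scan_bucket(buckets$org1, db)
  expect_equal(got, c("donor__a.csv", "donation__b.csv"))
  # mark the first processed by digest; re-dropping the same content is a no-op
  db$processed <- file_digest(file.path(root, "org1/upload/donor__a.csv"))
  expect_equal(scan_bucket(buckets$org1, db), "donation__b.csv")
})

test_that("a clean submission is archived and imported; a corrupted one returns a report", {
  root <- tempfile()
  cfg <- demo_config()
  fx <- small_study()
  buckets <- init_buckets(cfg, root)
  db <- fresh_db()
  snk <- sink_memory()

  drop_file(fx$study$files$org1$donor, root, "org1", "donor__jan.csv")
  ev <- process_submission(buckets$org1, "donor__jan.csv", cfg, db, list(snk))
  expect_equal(ev$disposition, "accepted")
  expect_length(list.files(buckets$org1$upload_dir), 0)
  arch <- list.files(buckets$org1$archive_dir)
  expect_length(arch, 1)
  expect_match(arch, "^donor__jan\\.csv\\.")   # receipt timestamp + digest suffix
  expect_gt(db_nrow(db, "donor"), 0)

  drop_file(fx$corrupted$files$org2$donor, root, "org2", "donor__jan.csv")
  ev2 <- process_submission(buckets$org2, "donor__jan.csv", cfg, db, list(snk))
  expect_equal(ev2$disposition, "rejected")
  dl <- list.files(buckets$org2$download_dir)
  expect_setequal(dl, c("donor__jan.csv", "donor__jan.csv.qc_report.csv"))
  # the returned report carries exactly the ledger's issues for that table
  back <- parse_report_csv(file.path(buckets$org2$download_dir, "donor__jan.csv.qc_report.csv"))
  led <- fx$corrupted$ledger
  led <- led[led$org == "org2" & led$table == "donor", c("kind", "table", "row", "field")]
  expect_equal(issue_key(back$issues[, c("kind", "table", "row", "field")]),
               issue_key(led))

  kinds <- vapply(sink_messages(snk), `[[`, "", "kind")
  expect_equal(kinds, c("acceptance", "rejection"))
  expect_true(!is.null(sink_messages(snk)[[2]]$attachment))
})

test_that("a zero-byte file is rejected with a table-level issue, not a crash", {
  root <- tempfile()
  cfg <- demo_config()
  buckets <- init_buckets(cfg, root)
  db <- fresh_db()
  writeLines(character(), file.path(buckets$org1$upload_dir, "donor__empty.csv"))
  ev <- process_submission(buckets$org1, "donor__empty.csv", cfg, db)
  expect_equal(ev$disposition, "rejected")
  expect_equal(nrow(ev$report$issues), 1)
  expect_equal(ev$report$issues$row, 0L)
})

test_that("run_cycle processes all buckets, conserves files, and is idempotent", {
  root <- tempfile()
  cfg <- demo_config()
  fx <- small_study()
  db <- fresh_db()
  # 2 buckets x 2 files: one clean donor + one corrupted donor each (disjoint
  # id namespaces per org keep submissions self-contained)
  drop_file(fx$study$files$org1$donor, root, "org1", "donor__clean.csv")
  drop_file(fx$corrupted$files$org1$donation, root, "org1", "donation__bad.csv")
  drop_file(fx$study$files$org2$donor, root, "org2", "donor__clean.csv")
  drop_file(fx$corrupted$files$org2$donor, root, "org2", "donor__bad.csv")
  snk <- sink_memory()
  events <- run_cycle(cfg, db, root, list(snk))
  expect_length(events, 4)
  disp <- vapply(events, `[[`, "", "disposition")
  expect_equal(sum(disp == "accepted"), 2)
  expect_equal(sum(disp == "rejected"), 2)
  # donor files processed before donation files within a bucket
  org1_events <- Filter(function(e) e$bucket == "org1", events)
  expect_match(org1_events[[1]]$file, "^donor")
  # file conservation: upload dirs empty; each file in exactly one place
  for (org in c("org1", "org2")) {
    expect_length(list.files(file.path(root, org, "upload")), 0)
  }
  expect_length(list.files(file.path(root, "org1", "archive")), 1)
  expect_length(list.files(file.path(root, "org2", "archive")), 1)
  # second cycle: nothing new
  expect_length(run_cycle(cfg, db, root, list(snk)), 0)
})

test_that("an import failure after acceptance leaves the event pending and recoverable", {
  root <- tempfile()
  cfg <- demo_config()
  cfg$qc_policy["ENUM"] <- "warn"   # QC passes; the store's check refuses
  db <- db_open(); create_schema(cfg, db)
  buckets <- init_buckets(cfg, root)
  donors <- data.frame(donor_id = sprintf("D%06d", 1:5), birth_date = "1985-06-17",
                       blood_group = c("A+", "ZZ", "O-", "B+", "A-"),
                       stringsAsFactors = FALSE)
  p <- file.path(buckets$org1$upload_dir, "donor__risky.csv")
  studyflow:::write_csv_file(donors, p)
  snk <- sink_memory()
  ev <- process_submission(buckets$org1, "donor__risky.csv", cfg, db, list(snk))
  expect_equal(ev$disposition, "pending")
  expect_equal(db_nrow(db, "donor"), 0)                       # nothing half-imported
  expect_true(file.exists(p))                                 # recoverable in upload
  expect_equal(sink_messages(snk)[[1]]$kind, "alert")
  # after the interruption cause is fixed, the same file processes normally
  donors$blood_group[2] <- "B-"
  studyflow:::write_csv_file(donors, p)
  ev2 <- process_submission(buckets$org1, "donor__risky.csv", cfg, db, list(snk))
  expect_equal(ev2$disposition, "accepted")
  expect_equal(db_nrow(db, "donor"), 5)
})

test_that("notification failures are retried once and never change disposition", {
  # a sink that always fails
  failing <- structure(list(), class = c("sink_broken", "notification_sink"))
  registerS3method("deliver", "sink_broken", function(sink, message) stop("down"),
                   envir = asNamespace("studyflow"))
  rec <- notify(failing, list(kind = "acceptance", org = "x", file = "f", body = "b"))
  expect_false(rec$delivered)
  expect_equal(rec$attempts, 2)

  # the same sink attached to a real acceptance still yields an accepted event
  root <- tempfile()
  cfg <- demo_config()
  fx <- small_study()
  buckets <- init_buckets(cfg, root)
  db <- fresh_db()
  drop_file(fx$study$files$org1$donor, root, "org1", "donor__x.csv")
  ev <- process_submission(buckets$org1, "donor__x.csv", cfg, db, list(failing))
  expect_equal(ev$disposition, "accepted")
})

test_that("file sink records messages as line-delimited JSON", {
  p <- tempfile()
  s <- sink_file(p)
  notify(s, list(kind = "acceptance", org = "org1", file = "f.csv", body = "ok"))
  notify(s, list(kind = "rejection", org = "org2", file = "g.csv", body = "bad"))
  msgs <- sink_messages(s)
  expect_length(msgs, 2)
  expect_equal(msgs[[2]]$kind, "rejection")
})
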