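# Study store: materialized constraints, transactional import, recoding,
# identifier chains.

test_that("create_schema materializes one relation per table plus support relations", {
  db <- fresh_db()
  expect_setequal(names(db$tables), c("donor", "donation", "testing"))
  expect_length(db$lookups, 2)
  expect_equal(nrow(db$id_changes), 0)
  expect_named(db$survey, c("questions", "responses", "answers"))
  # DDL dump reflects constraints
  ddl <- db_ddl(demo_config())
  expect_true(any(grepl("CREATE TABLE donor", ddl)))
  expect_true(any(grepl("REFERENCES donor", ddl)))
})

test_that("an empty dictionary cannot back a study", {
  db <- db_open()
  cfg <- demo_config()
  cfg$dictionaries <- list()
  expect_error(create_schema(cfg, db), class = "config_error")
})

test_that("the store itself refuses dictionary-violating direct inserts", {
  db <- fresh_db()
  good <- data.frame(donor_id = "D0000001", birth_date = "1985-06",
                     blood_group = "A+", stringsAsFactors = FALSE)
  expect_equal(db_insert_rows(db, "donor", good), 1L)
  # out-of-enumeration code
  bad <- good; bad$donor_id <- "D0000002"; bad$blood_group <- "Q+"
  expect_error(db_insert_rows(db, "donor", bad), class = "constraint_violation")
  # duplicate primary key
  expect_error(db_insert_rows(db, "donor", good), class = "constraint_violation")
  # orphan foreign key
  don <- data.frame(donation_id = "N1", donor_id = "D9999999",
                    visit_date = "2021-01-01", zip_code = "941",
                    race = "W", ethnicity = "N", sex = "F", stringsAsFactors = FALSE)
  expect_error(db_insert_rows(db, "donation", don), class = "constraint_violation")
  # nothing was written by any refused insert
  expect_equal(db_nrow(db, "donor"), 1)
  expect_equal(db_nrow(db, "donation"), 0)
})

test_that("accepted submissions import atomically and idempotently", {
  fx <- small_study()
  cfg <- demo_config()
  db <- fresh_db()
  files <- fx$study$files$org1
  rep <- validate_submission(files, cfg, db)
  expect_equal(rep$verdict, "accepted")
  imp <- import_submission(files, rep, cfg, db)
  expect_equal(imp$outcome, "committed")
  expect_equal(imp$rows_written, imp$rows_attempted)
  n_before <- vapply(names(files), function(t) db_nrow(db, t), 0L)
  # re-import: no-op, committed, zero rows, counts unchanged
  imp2 <- import_submission(files, rep, cfg, db)
  expect_equal(imp2$outcome, "committed")
  expect_equal(imp2$rows_written, 0L)
  expect_equal(vapply(names(files), function(t) db_nrow(db, t), 0L), n_before)
  # importing with a rejected report is a usage error
  bad_rep <- rep; bad_rep$verdict <- "rejected"
  expect_error(import_submission(files, bad_rep, cfg, db), class = "usage_error")
})

test_that("a row passing a downgraded QC policy still rolls back the whole import", {
  # ENUM downgraded to warn: QC accepts the file, but the materialized
  # enumerated check refuses it mid-import; the store must hold nothing
  p <- tempfile(fileext = ".yml")
  cfg <- demo_config()
  cfg$qc_policy["ENUM"] <- "warn"
  write_config(cfg, p)
  cfg2 <- load_config(p)
  expect_equal(unname(cfg2$qc_policy["ENUM"]), "warn")

  db <- db_open(); create_schema(cfg2, db)
  donors <- data.frame(donor_id = sprintf("D%06d", 1:100),
                       birth_date = "1985-06-17",
                       blood_group = c(rep("A+", 56), "ZZ", rep("O-", 43)),
                       stringsAsFactors = FALSE)
  rep <- validate_submission(list(donor = donors), cfg2, db)
  expect_equal(rep$verdict, "accepted")       # ENUM issue is warn-only
  expect_equal(sum(rep$issues$kind == "ENUM"), 1)
  imp <- import_submission(list(donor = donors), rep, cfg2, db)
  expect_equal(imp$outcome, "rolled_back")
  expect_equal(imp$rows_written, 0L)
  expect_match(imp$detail, "blood_group")
  expect_equal(db_nrow(db, "donor"), 0)
  # the failed submission is not marked imported; a corrected retry commits
  donors$blood_group[57] <- "B+"
  rep2 <- validate_submission(list(donor = donors), cfg2, db)
  imp2 <- import_submission(list(donor = donors), rep2, cfg2, db)
  expect_equal(imp2$outcome, "committed")
  expect_equal(db_nrow(db, "donor"), 100)
})

test_that("row conservation: committed row counts accumulate exactly", {
  fx <- small_study()
  cfg <- demo_config()
  db <- fresh_db()
  written <- 0L
  for (org in fx$study$orgs) {
    files <- fx$study$files[[org]]
    rep <- validate_submission(files, cfg, db)
    imp <- import_submission(files, rep, cfg, db)
    expect_equal(imp$outcome, "committed")
    written <- written + imp$rows_written
  }
  total <- sum(vapply(names(db$tables), function(t) db_nrow(db, t), 0L))
  expect_equal(total, written)
})

test_that("import-time privacy truncation is applied and the original shape refused", {
  cfg <- demo_config()
  db <- fresh_db()
  donors <- data.frame(donor_id = "D0000001", birth_date = "1985-06-17",
                       blood_group = "A+", stringsAsFactors = FALSE)
  rep <- validate_submission(list(donor = donors), cfg, db)
  imp <- import_submission(list(donor = donors), rep, cfg, db)
  expect_equal(imp$outcome, "committed")
  expect_equal(db_table(db, "donor")$birth_date, "1985-06")  # month level only
  # the storage column no longer admits full dates on direct insertion
  full <- data.frame(donor_id = "D0000002", birth_date = "1990-01-15",
                     blood_group = "O+", stringsAsFactors = FALSE)
  expect_error(db_insert_rows(db, "donor", full), class = "constraint_violation")
})

test_that("recode preserves originals, counts unmapped, and tracks version changes", {
  cfg <- demo_config()
  db <- fresh_db()
  donors <- data.frame(donor_id = sprintf("D%02d", 1:4), birth_date = "1985-06",
                       blood_group = "A+", stringsAsFactors = FALSE)
  db_insert_rows(db, "donor", donors)
  don <- data.frame(donation_id = sprintf("N%02d", 1:4),
                    donor_id = donors$donor_id,
                    visit_date = "2021-01-01", zip_code = "941",
                    race = c("W", "A", "P", ""), ethnicity = "N", sex = "F",
                    stringsAsFactors = FALSE)
  db_insert_rows(db, "donation", don)
  before <- db_table(db, "donation")$race
  r1 <- recode("donation", "race", "race_group", db, version = 1)
  expect_equal(r1$unmapped, 1)       # the blank cell has no mapping
  expect_identical(db_table(db, "donation")$race, before)  # originals untouched
  rel <- db$derived[[r1$relation]]
  expect_equal(rel$group[rel$original == "A"], "Asian")
  # version 2 regroups A and P only
  r2 <- recode("donation", "race", "race_group", db, version = 2)
  expect_equal(r2$changed, 2)
  rel2 <- db$derived[[r2$relation]]
  expect_equal(rel2$group[rel2$original == "P"], "Asian or Pacific Islander")
  # wrong source is a usage error
  expect_error(recode("donation", "sex", "race_group", db), class = "usage_error")
})

test_that("identifier chains resolve to their terminus and detect cycles", {
  db <- fresh_db()
  expect_equal(resolve_identifier("donor", "D1", db), "D1")  # identity
  record_identifier_change(db, "donor", "D1", "D9", "2022-01-01")
  record_identifier_change(db, "donor", "D9", "D12", "2023-01-01")
  expect_equal(resolve_identifier("donor", "D1", db), "D12")
  expect_equal(resolve_identifier("donor", "D9", db), "D12")
  record_identifier_change(db, "donor", "D12", "D1", "2024-01-01")
  expect_error(resolve_identifier("donor", "D1", db), class = "integrity_error")
})

test_that("resolver agrees with a brute-force path walk on random acyclic chains", {
  set.seed(31)
  db <- fresh_db()
  # build a random forest of chains over 300 nodes: node i may point to a
  # strictly higher node, guaranteeing acyclicity
  n <- 300
  nxt <- rep(NA_integer_, n)
  for (i in seq_len(n - 1)) {
    if (stats::runif(1) < 0.6) nxt[i] <- sample((i + 1):n, 1)
  }
  for (i in which(!is.na(nxt)))
    record_identifier_change(db, "donor", paste0("D", i), paste0("D", nxt[i]), "2024-01-01")
  walk <- function(i) { while (!is.na(nxt[i])) i <- nxt[i]; paste0("D", i) }
  for (i in sample(n, 50)) {
    expect_equal(resolve_identifier("donor", paste0("D", i), db), walk(i))
  }
})

test_that("donation rows referencing a changed donor id are stored canonically", {
  cfg <- demo_config()
  db <- fresh_db()
  donors <- data.frame(donor_id = c("D0000009"), birth_date = "1985-06",
                       blood_group = "A+", stringsAsFactors = FALSE)
  db_insert_rows(db, "donor", donors)
  record_identifier_change(db, "donor", "D0000001", "D0000009", "2023-06-01")
  don <- data.frame(donation_id = "N0000001", donor_id = "D0000001",
                    visit_date = "2021-01-01", zip_code = "94115",
                    race = "W", ethnicity = "N", sex = "F", stringsAsFactors = FALSE)
  # QC accepts the superseded id: its change chain ends at a stored donor
  rep <- validate_submission(list(donation = don), cfg, db)
  expect_equal(rep$verdict, "accepted")
  imp <- import_submission(list(donation = don), rep, cfg, db)
  expect_equal(imp$outcome, "committed")
  expect_equal(db_table(db, "donation")$donor_id, "D0000009")  # canonical id
  # original association preserved in the change trail
  expect_true(any(db$id_changes$old_id == "D0000001"))
})

test_that("non-append-only tables upsert with an audit trail", {
  cfg <- demo_config()   # donor is declared append_only: false
  db <- fresh_db()
  v1 <- data.frame(donor_id = "D0000001", birth_date = "1985-06-17",
                   blood_group = "A+", stringsAsFactors = FALSE)
  rep1 <- validate_submission(list(donor = v1), cfg, db)
  import_submission(list(donor = v1), rep1, cfg, db)
  v2 <- v1; v2$blood_group <- "B+"
  rep2 <- validate_submission(list(donor = v2), cfg, db)
  expect_equal(rep2$verdict, "accepted")  # refresh, not a duplicate
  imp <- import_submission(list(donor = v2), rep2, cfg, db)
  expect_equal(imp$outcome, "committed")
  expect_equal(db_nrow(db, "donor"), 1)
  expect_equal(db_table(db, "donor")$blood_group, "B+")
  expect_equal(db$audit$action, "upsert")
})

test_that("a store survives save and reload", {
  fx <- small_study()
  cfg <- demo_config()
  db <- fresh_db()
  files <- fx$study$files$org1
  rep <- validate_submission(files, cfg, db)
  import_submission(files, rep, cfg, db)
  dir <- tempfile()
  db_save(db, dir)
  db2 <- db_open(dir)
  create_schema(cfg, db2)
  t1 <- db_table(db, "donation"); rownames(t1) <- NULL
  t2 <- db_table(db2, "donation"); rownames(t2) <- NULL
  expect_equal(t2, t1)
  expect_equal(db2$imported, db$imported)
})
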