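# QC engine: row checks, key checks, whole-submission validation, report
# rendering.

test_that("check_row flags type, enum and length violations, one root cause per cell", {
  s <- mini_schema()
  base <- list(visit_id = "V001", age = "41", sex = "F",
               visit_date = "2021-06-01", note = "ok")

  r <- check_row(modifyList(base, list(age = "forty")), s, 1)
  expect_equal(r$kind, "TYPE")
  expect_equal(r$field, "age")

  r <- check_row(modifyList(base, list(sex = "X")), s, 2)
  expect_equal(r$kind, "ENUM")
  expect_equal(r$row, 2L)

  r <- check_row(modifyList(base, list(note = "toolongnote")), s, 1)
  expect_equal(r$kind, "LENGTH")

  # a TYPE failure suppresses downstream checks for that cell: this value is
  # non-numeric AND over-long, but only TYPE is reported
  r <- check_row(modifyList(base, list(age = "fortyfortyforty")), s, 1)
  expect_equal(r$kind, "TYPE")

  # empty required cell: REQUIRED only, nothing else for that cell
  r <- check_row(modifyList(base, list(visit_date = "")), s, 1)
  expect_equal(r$kind, "REQUIRED")

  # empty optional cell is valid
  r <- check_row(modifyList(base, list(sex = "", age = "", note = "")), s, 1)
  expect_equal(nrow(r), 0)
})

test_that("date checks agree with an enumeration oracle for calendar validity", {
  s <- mini_schema()
  base <- list(visit_id = "V001", age = "41", sex = "F",
               visit_date = "2021-06-01", note = "ok")
  # oracle: the set of real dates in a month, by enumeration
  feb2020 <- format(seq(as.Date("2020-02-01"), as.Date("2020-03-01") - 1, by = "day"),
                    "%Y-%m-%d")
  expect_false("2020-02-30" %in% feb2020)
  r <- check_row(modifyList(base, list(visit_date = "2020-02-30")), s, 1)
  expect_equal(r$kind, "DATE")
  expect_match(r$expected, "calendar")
  # every real date in-bounds passes
  for (d in c("2020-02-29", "2024-12-31", "2020-01-01")) {
    expect_equal(nrow(check_row(modifyList(base, list(visit_date = d)), s, 1)), 0)
  }
  # valid calendar date outside declared bounds
  r <- check_row(modifyList(base, list(visit_date = "2019-12-31")), s, 1)
  expect_equal(r$kind, "DATE")
  expect_match(r$expected, "within")
  # non-ISO date is a TYPE problem, not DATE
  r <- check_row(modifyList(base, list(visit_date = "06/01/2021")), s, 1)
  expect_equal(r$kind, "TYPE")
})

test_that("duplicate keys: first occurrence clean, later occurrences flagged", {
  s <- mini_schema()
  rows <- mini_rows(4)
  rows$visit_id <- c("1", "2", "2", "3")
  r <- check_keys(rows, s)
  expect_equal(r$kind, "DUP_KEY")
  expect_equal(r$row, 3L)
  # keys known to the store also count for append-only tables
  r2 <- check_keys(rows, s, context = list(visit = "3"))
  expect_setequal(r2$row, c(3L, 4L))
  expect_equal(nrow(check_keys(rows[0, ], s)), 0)   # empty table: vacuous
})

test_that("foreign-key orphans match a brute-force set difference", {
  cfg <- demo_config()
  don <- data.frame(
    donation_id = sprintf("N%03d", 1:10),
    donor_id = rep(c("7", "8"), 5),
    visit_date = "2021-05-05", zip_code = "94115",
    race = "W", ethnicity = "N", sex = "F", stringsAsFactors = FALSE)
  r <- check_keys(don, cfg$dictionaries$donation, context = list(donor = "7"))
  oracle <- which(!don$donor_id %in% "7")
  expect_equal(r$row[r$kind == "FK_ORPHAN"], oracle)
  expect_equal(sum(r$kind == "FK_ORPHAN"), length(oracle))
})

test_that("check_keys requires a primary key", {
  s <- mini_schema()
  s$primary_key <- character()
  expect_error(check_keys(mini_rows(2), s), class = "usage_error")
})

test_that("validate_submission reconciles headers and orders issues reproducibly", {
  p <- mini_config_yaml(tempfile(fileext = ".yml"))
  cfg <- load_config(p)
  rows <- mini_rows(3)
  rows$note <- NULL
  rows$surprise <- "x"
  rep <- validate_submission(list(visit = rows), cfg)
  expect_equal(rep$verdict, "rejected")   # MISSING_COLUMN rejects by default
  expect_true(any(rep$issues$kind == "MISSING_COLUMN" & rep$issues$row == 0))
  expect_true(any(rep$issues$kind == "UNKNOWN_COLUMN" & rep$issues$row == 0))
  expect_equal(unique(rep$issues$severity[rep$issues$kind == "UNKNOWN_COLUMN"]), "warn")
  # issue ordering is (table, row, field)
  o <- order(rep$issues$table, rep$issues$row, rep$issues$field, method = "radix")
  expect_equal(o, seq_len(nrow(rep$issues)))
  # counts account for every issue
  expect_equal(sum(rep$counts), nrow(rep$issues))
})

test_that("an unknown-column-only submission is accepted (warn severity)", {
  p <- mini_config_yaml(tempfile(fileext = ".yml"))
  cfg <- load_config(p)
  rows <- mini_rows(3)
  rows$surprise <- "x"
  rep <- validate_submission(list(visit = rows), cfg)
  expect_equal(rep$verdict, "accepted")
  expect_equal(nrow(rep$issues), 1)
})

test_that("verdict monotonicity: reject-severity issues flip, warn issues never do", {
  p <- mini_config_yaml(tempfile(fileext = ".yml"))
  cfg <- load_config(p)
  clean <- mini_rows(5)
  expect_equal(validate_submission(list(visit = clean), cfg)$verdict, "accepted")
  # add one reject-severity violation
  bad <- clean; bad$age[3] <- "not-a-number"
  expect_equal(validate_submission(list(visit = bad), cfg)$verdict, "rejected")
  # warn-only issue leaves the verdict accepted (previous test) even stacked
  warned <- clean; warned$extra1 <- "a"; warned$extra2 <- "b"
  expect_equal(validate_submission(list(visit = warned), cfg)$verdict, "accepted")
})

test_that("permuting row order permutes ordinals but preserves the issue multiset", {
  p <- mini_config_yaml(tempfile(fileext = ".yml"))
  cfg <- load_config(p)
  rows <- mini_rows(8)
  rows$age[c(2, 5)] <- "bad"
  rows$sex[7] <- "Z"
  set.seed(9)
  perm <- sample(nrow(rows))
  rep1 <- validate_submission(list(visit = rows), cfg)
  rep2 <- validate_submission(list(visit = rows[perm, , drop = FALSE]), cfg)
  # same (kind, field, observed) multiset; rows relabeled by the permutation
  k1 <- sort(paste(rep1$issues$kind, rep1$issues$field, rep1$issues$observed))
  k2 <- sort(paste(rep2$issues$kind, rep2$issues$field, rep2$issues$observed))
  expect_equal(k1, k2)
  expect_equal(sort(match(rep1$issues$row, perm)), sort(rep2$issues$row))
})

test_that("delimited report rendering round-trips losslessly", {
  p <- mini_config_yaml(tempfile(fileext = ".yml"))
  cfg <- load_config(p)
  rows <- mini_rows(5)
  rows$age[2] <- "x"; rows$sex[4] <- "Q"; rows$visit_date[5] <- ""
  rep <- validate_submission(list(visit = rows), cfg, submission_id = "sub-42")
  lines <- render_report(rep, "delimited")
  expect_length(lines, nrow(rep$issues) + 1)  # header + one line per issue
  back <- parse_report_csv(lines)
  expect_equal(back$issues, rep$issues)
  expect_equal(back$verdict, rep$verdict)
  expect_equal(back$submission_id, "sub-42")
  # empty report renders header only
  clean_rep <- validate_submission(list(visit = mini_rows(2)), cfg)
  expect_length(render_report(clean_rep, "delimited"), 1)
  # human-readable form names the verdict and groups by table/kind
  h <- render_report(rep, "human")
  expect_match(h[1], "REJECTED")
  expect_true(any(grepl("TYPE", h)))
})

test_that("unreadable files are transport errors, not validation findings", {
  p <- mini_config_yaml(tempfile(fileext = ".yml"))
  cfg <- load_config(p)
  expect_error(validate_submission(list(visit = "/nonexistent/file.csv"), cfg),
               class = "transport_error")
  expect_error(validate_submission(list(nosuch = mini_rows(1)), cfg),
               class = "usage_error")
})
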