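# Shared fixtures, all built in code at test time.

demo_config_path <- function() {
  system.file("extdata", "demo", "config.yml", package = "studyflow")
}

demo_config <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- load_config(demo_config_path())
    cache
  }
})

# a minimal one-table dictionary used by unit tests
mini_schema <- function() {
  table_schema("visit", list(
    field_spec("visit_id", "text", max_length = 8, required = TRUE, key = "primary"),
    field_spec("age", "integer", max_length = 3),
    field_spec("sex", "code", allowed_codes = c("M", "F", "O"), max_length = 1),
    field_spec("visit_date", "date", required = TRUE,
               date_bounds = c("2020-01-01", "2024-12-31")),
    field_spec("note", "text", max_length = 5)
  ))
}

mini_config_yaml <- function(path) {
  writeLines(c(
    "study_id: mini",
    "dictionaries:",
    "  visit:",
    "    level: 1",
    "    fields:",
    "      - {name: visit_id, type: text, max_length: 8, required: true, key: primary}",
    "      - {name: age, type: integer, max_length: 3}",
    "      - name: sex",
    "        type: code",
    "        max_length: 1",
    "        allowed_codes: ['M', 'F', 'O']",
    "      - name: visit_date",
    "        type: date",
    "        required: true",
    "        date_bounds: ['2020-01-01', '2024-12-31']",
    "      - {name: note, type: text, max_length: 5}"
  ), path)
  path
}

# a tiny in-memory submission for the mini schema
mini_rows <- function(n = 3) {
  data.frame(
    visit_id = sprintf("V%03d", seq_len(n)),
    age = as.character(20 + seq_len(n)),
    sex = rep_len(c("M", "F", "O"), n),
    visit_date = rep_len(c("2021-06-01", "2022-03-15", "2023-11-30"), n),
    note = rep_len("ok", n),
    stringsAsFactors = FALSE
  )
}

# small simulated study shared across tests (seed fixed; built once per run)
small_study <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      dir <- file.path(tempdir(), "studyflow_small_study")
      sim <- sim_config(seed = 101, n_orgs = 2, n_donors = 60)
      st <- generate_study(sim, demo_config(), file.path(dir, "clean"))
      co <- corrupt_study(st, demo_config(), file.path(dir, "corrupted"))
      cache <<- list(sim = sim, study = st, corrupted = co)
    }
    cache
  }
})

issue_key <- function(d) sort(paste(d$kind, d$table, d$row, d$field, sep = "|"))

fresh_db <- function(cfg = demo_config()) {
  db <- db_open()
  create_schema(cfg, db)
  db
}
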