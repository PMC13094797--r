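# Seedable simulator of a complete multicenter study.
#
# Emulates what multiple blood collection organizations would submit --
# donor tables (time-invariant characteristics), donation tables (per-visit
# records referencing donors), testing tables (assay results referencing
# donations) -- plus multi-round survey-platform exports with question churn
# and consent flags. Generation is driven entirely by the project
# dictionary: field values are drawn from each field's declared type,
# length, bounds and codes, so the clean output passes QC with zero issues
# by construction. A companion corruption pass injects dictionary
# violations cell by cell and records every one in a ground-truth ledger,
# giving the QC engine an exactly known target.
#
# All identifiers come from a fictional namespace; nothing resembling real
# personal data is generated.

#' Simulation configuration
#'
#' @param seed Integer seed; identical (seed, config, dictionary) triples
#'   produce byte-identical files and ledgers.
#' @param n_orgs Number of submitting organizations.
#' @param n_donors Total donors across organizations (split evenly).
#' @param donations_per_donor `c(mean, dispersion)` of a negative-binomial
#'   count of donations per donor.
#' @param n_rounds Survey rounds.
#' @param n_questions Questions per survey round.
#' @param question_churn Fraction of questions replaced each round (0..1).
#' @param consent_rate Probability a respondent consents.
#' @param error_rate Per-cell corruption probability for [corrupt_study()].
#' @param error_mix Named weights over injectable issue kinds (any subset of
#'   TYPE, LENGTH, DATE, ENUM, REQUIRED, DUP_KEY, FK_ORPHAN).
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L, n_orgs = 2L, n_donors = 500L,
                       donations_per_donor = c(2, 5), n_rounds = 3L,
                       n_questions = 10L, question_churn = 0.3,
                       consent_rate = 0.8, error_rate = 0.02,
                       error_mix = c(TYPE = 1, LENGTH = 1, DATE = 1, ENUM = 1,
                                     REQUIRED = 1, DUP_KEY = 1, FK_ORPHAN = 1)) {
  injectable <- c("TYPE", "LENGTH", "DATE", "ENUM", "REQUIRED", "DUP_KEY", "FK_ORPHAN")
  if (length(setdiff(names(error_mix), injectable)) > 0)
    sf_stop("config_error", sprintf("error_mix names unknown kind(s): %s",
                                    paste(setdiff(names(error_mix), injectable), collapse = ", ")))
  if (question_churn < 0 || question_churn > 1)
    sf_stop("config_error", "question_churn must be within [0, 1]")
  if (consent_rate < 0 || consent_rate > 1)
    sf_stop("config_error", "consent_rate must be within [0, 1]")
  structure(list(seed = as.integer(seed), n_orgs = as.integer(n_orgs),
                 n_donors = as.integer(n_donors),
                 donations_per_donor = donations_per_donor,
                 n_rounds = as.integer(n_rounds), n_questions = as.integer(n_questions),
                 question_churn = question_churn, consent_rate = consent_rate,
                 error_rate = error_rate, error_mix = error_mix),
            class = "sim_config")
}

rand_date <- function(n, bounds) {
  lo <- as.Date(bounds[1]); hi <- as.Date(bounds[2])
  format(lo + sample.int(as.integer(hi - lo) + 1L, n, replace = TRUE) - 1L, "%Y-%m-%d")
}

# one dictionary-valid value vector for a non-key field
gen_field_values <- function(f, n) {
  switch(f$type,
    code = sample(f$allowed_codes, n, replace = TRUE),
    date = rand_date(n, f$date_bounds %||% c("2000-01-01", "2024-12-31")),
    datetime = paste0(rand_date(n, c("2020-01-01", "2024-12-31")), "T",
                      sprintf("%02d:%02d", sample(0:23, n, TRUE), sample(0:59, n, TRUE))),
    integer = as.character(sample.int(500L, n, replace = TRUE)),
    decimal = sprintf("%.2f", stats::runif(n, 0, 250)),
    text = {
      # zip-like fields get digit strings, everything else letter tokens
      if (grepl("zip|postal", f$name)) {
        sprintf("%05d", sample.int(99999L, n, replace = TRUE))
      } else {
        len <- min(8L, f$max_length %||% 8L, na.rm = TRUE)
        replicate(n, paste(sample(LETTERS, max(len, 1L), replace = TRUE), collapse = ""))
      }
    })
}

#' Generate a clean simulated multicenter study
#'
#' Level-1 tables get one row per donor (ids namespaced per organization);
#' each level-2 row count per parent is drawn from the configured
#' negative-binomial; level-3+ tables get one row per parent. Field values
#' are drawn from the dictionary (codes from the enumerated sets, dates
#' within bounds, lengths respected), so every generated file is accepted by
#' QC with zero issues. Survey rounds share `1 - question_churn` of their
#' questions with the previous round (same key and text); replaced questions
#' are new. Raw survey exports deliberately include answers for some
#' non-consenting respondents, emulating consent withdrawn after answers
#' were given -- the ingest consent gate must suppress them.
#'
#' @param sim A [sim_config()].
#' @param config Project configuration (the dictionary drives generation).
#' @param out_dir Directory for the generated CSV files.
#' @return A `sim_study` list: `files[[org]][[table]]` paths,
#'   `surveys[[round]]` (path, questions, equivalency map), and the
#'   expected consent/answer accounting.
#' @export
generate_study <- function(sim, config, out_dir) {
  set.seed(sim$seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tabs <- config$dictionaries[order(vapply(config$dictionaries, `[[`, 1L, "level"))]
  orgs <- sprintf("org%d", seq_len(sim$n_orgs))
  per_org <- max(1L, sim$n_donors %/% sim$n_orgs)
  files <- list()
  all_tables <- list()

  for (oi in seq_along(orgs)) {
    org <- orgs[oi]
    org_dir <- file.path(out_dir, org)
    dir.create(org_dir, showWarnings = FALSE, recursive = TRUE)
    tables <- list()
    for (ts in tabs) {
      if (ts$level == 1) {
        n <- per_org
        parent_keys <- NULL
      } else {
        fk <- Filter(function(f) f$key == "foreign", ts$fields)[[1]]
        parent <- tables[[fk$foreign_target[1]]]
        counts <- if (ts$level == 2) {
          stats::rnbinom(nrow(parent), mu = sim$donations_per_donor[1],
                         size = sim$donations_per_donor[2])
        } else rep(1L, nrow(parent))
        parent_keys <- rep(parent[[fk$foreign_target[2]]], counts)
        n <- length(parent_keys)
      }
      df <- as.data.frame(stats::setNames(rep(list(character(n)), length(ts$fields)),
                                          names(ts$fields)),
                          stringsAsFactors = FALSE, check.names = FALSE)
      for (f in ts$fields) {
        if (f$key == "primary") {
          df[[f$name]] <- sprintf("%s%d%06d", toupper(substr(ts$name, 1, 1)), oi, seq_len(n))
        } else if (f$key == "foreign") {
          df[[f$name]] <- parent_keys
        } else {
          df[[f$name]] <- if (n > 0) gen_field_values(f, n) else character()
        }
      }
      tables[[ts$name]] <- df
      path <- file.path(org_dir, paste0(ts$name, ".csv"))
      write_csv_file(df, path)
      files[[org]][[ts$name]] <- path
    }
    all_tables[[org]] <- tables
  }

  # ---- survey rounds --------------------------------------------------------
  surveys <- list()
  root_tab <- tabs[[1]]
  donor_ids <- unlist(lapply(all_tables, function(t)
    t[[root_tab$name]][[root_tab$primary_key[1]]]), use.names = FALSE)
  # respondents: a stable subset of donors
  respondents <- sort(sample(donor_ids, min(length(donor_ids), max(20L, length(donor_ids) %/% 2L))))
  survey_dir <- file.path(out_dir, "surveys")
  dir.create(survey_dir, showWarnings = FALSE)
  prev_questions <- NULL
  qcounter <- 0L
  for (r in seq_len(sim$n_rounds)) {
    if (is.null(prev_questions)) {
      kept <- list()
      n_new <- sim$n_questions
    } else {
      n_keep <- round(sim$n_questions * (1 - sim$question_churn))
      kept <- prev_questions[seq_len(n_keep)]
      n_new <- sim$n_questions - n_keep
    }
    new_q <- lapply(seq_len(n_new), function(i) {
      qcounter <<- qcounter + 1L
      k <- sprintf("q_%03d", qcounter)
      domain <- if (qcounter %% 3 == 0) c("yes", "no", "unsure") else NULL
      list(key = k, text = sprintf("Study question %d, wording for round %d", qcounter, r),
           answer_domain = domain)
    })
    questions <- c(kept, new_q)
    rounds_label <- sprintf("round%d", r)
    responded <- respondents[stats::runif(length(respondents)) < 0.8]
    consent <- stats::runif(length(responded)) < sim$consent_rate
    complete <- stats::runif(length(responded)) < 0.9
    export <- data.frame(respondent_id = responded,
                         completed = ifelse(complete, "true", "false"),
                         consented = ifelse(consent, "true", "false"),
                         stringsAsFactors = FALSE)
    adversarial <- 0L
    for (q in questions) {
      ans <- character(length(responded))
      # consented + completed answer most questions; half the non-consenters
      # still have raw answers in the export (late withdrawal)
      answered <- (consent & complete & stats::runif(length(responded)) < 0.9) |
                  (!consent & stats::runif(length(responded)) < 0.5)
      vals <- if (!is.null(q$answer_domain))
        sample(q$answer_domain, length(responded), replace = TRUE)
      else sprintf("free answer %d", sample.int(50L, length(responded), replace = TRUE))
      ans[answered] <- vals[answered]
      adversarial <- adversarial + sum(answered & !consent)
      export[[q$key]] <- ans
    }
    path <- file.path(survey_dir, paste0(rounds_label, ".csv"))
    write_csv_file(export, path)
    surveys[[rounds_label]] <- list(
      path = path, questions = questions,
      round = rounds_label,
      adversarial_answers = adversarial,
      n_responded = length(responded), n_consented = sum(consent))
    prev_questions <- questions
  }

  structure(list(sim = sim, orgs = orgs, files = files, surveys = surveys,
                 out_dir = out_dir),
            class = "sim_study")
}

# corruption token generators -- each guaranteed to violate exactly the
# targeted constraint and nothing else on that cell
corrupt_value <- function(kind, f, schema) {
  switch(kind,
    TYPE = "##bad##",
    LENGTH = strrep("X", (f$max_length %||% 8L) + 3L),
    DATE = {
      if (!is.null(f$date_bounds) && stats::runif(1) < 0.5) {
        format(as.Date(f$date_bounds[1]) - sample.int(200L, 1L), "%Y-%m-%d")
      } else {
        sprintf("%04d-02-30", sample(1990:2024, 1))
      }
    },
    ENUM = {
      tok <- "#"
      while (tok %in% f$allowed_codes) tok <- paste0(tok, "#")
      if (!is.na(f$max_length)) substr(strrep("#", f$max_length), 1, f$max_length) else tok
    },
    REQUIRED = "",
    FK_ORPHAN = {
      base <- "XORPH"
      if (!is.na(f$max_length)) substr(paste0(base, "99999"), 1, f$max_length)
      else paste0(base, "99999")
    })
}

eligible_kinds <- function(f, mix) {
  kinds <- names(mix)[mix > 0]
  ok <- vapply(kinds, function(k) switch(k,
    TYPE = f$key == "none" && f$type %in% c("integer", "decimal", "date", "datetime"),
    LENGTH = f$key == "none" && f$type == "text" && !is.na(f$max_length) &&
             is.null(f$privacy),
    DATE = f$key == "none" && f$type == "date",
    ENUM = f$key == "none" && f$type == "code",
    REQUIRED = f$key == "none" && f$required,
    DUP_KEY = f$key == "primary",
    FK_ORPHAN = f$key == "foreign"), TRUE)
  kinds[ok]
}

empty_ledger <- function() {
  data.frame(org = character(), kind = character(), table = character(),
             row = integer(), field = character(), original = character(),
             corrupted = character(), stringsAsFactors = FALSE)
}

#' Inject dictionary violations into generated files
#'
#' Walks every cell of every clean file in deterministic order; each cell is
#' independently corrupted with probability `error_rate`, with the issue
#' kind drawn from `error_mix` restricted to kinds the cell's field can
#' express (a date cell cannot carry an ENUM violation). Primary-key draws
#' append a duplicate copy of the row's clean original (so a duplicated key
#' never cascades into other violations); foreign-key draws rewrite the
#' reference to an identifier outside any parent key set. The returned
#' ledger records every injected corruption exactly once and is the ground
#' truth the QC engine is measured against. Each cell-level entry is
#' self-checked at generation time by running the row checker on the
#' corrupted row.
#'
#' @param study A `sim_study` from [generate_study()].
#' @param config Project configuration.
#' @param out_dir Directory for the corrupted files (mirrors the clean
#'   layout).
#' @param self_check Run the QC row checker on every injected cell
#'   corruption (default `TRUE`).
#' @return List: `files` (corrupted file map), `ledger` (data.frame with
#'   org, kind, table, row, field, original, corrupted).
#' @export
corrupt_study <- function(study, config, out_dir, self_check = TRUE) {
  sim <- study$sim
  # decouple the corruption stream from the generation stream
  set.seed(sim$seed + 1000003L)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  mix <- sim$error_mix
  ledger_rows <- list()
  files <- list()
  for (org in study$orgs) {
    org_dir <- file.path(out_dir, org)
    dir.create(org_dir, showWarnings = FALSE, recursive = TRUE)
    for (tab in names(study$files[[org]])) {
      schema <- config$dictionaries[[tab]]
      clean <- read_submission(study$files[[org]][[tab]])
      df <- clean
      dup_sources <- integer()
      n <- nrow(df)
      for (f in schema$fields) {
        elig <- eligible_kinds(f, mix)
        if (length(elig) == 0 || n == 0) next
        hit <- which(stats::runif(n) < sim$error_rate)
        for (i in hit) {
          kind <- if (length(elig) == 1) elig else
            sample(elig, 1L, prob = mix[elig] / sum(mix[elig]))
          if (kind == "DUP_KEY") {
            dup_sources <- c(dup_sources, i)
          } else {
            orig <- df[[f$name]][i]
            bad <- corrupt_value(kind, f, schema)
            df[[f$name]][i] <- bad
            ledger_rows[[length(ledger_rows) + 1L]] <- data.frame(
              org = org, kind = kind, table = tab, row = i, field = f$name,
              original = orig, corrupted = bad, stringsAsFactors = FALSE)
            if (self_check && kind != "FK_ORPHAN") {
              found <- check_row(as.list(df[i, , drop = FALSE]), schema, i, config$qc_policy)
              if (!any(found$kind == kind & found$field == f$name))
                sf_stop("integrity_error", sprintf(
                  "self-check failed: injected %s at (%s, %d, %s) not detected",
                  kind, tab, i, f$name))
            }
          }
        }
      }
      # append duplicate-key rows (clean originals) after all cell edits
      for (i in dup_sources) {
        df <- rbind(df, clean[i, , drop = FALSE])
        ledger_rows[[length(ledger_rows) + 1L]] <- data.frame(
          org = org, kind = "DUP_KEY", table = tab, row = nrow(df),
          field = paste(schema$primary_key, collapse = "+"),
          original = "",
          corrupted = paste(unlist(clean[i, schema$primary_key]), collapse = "+"),
          stringsAsFactors = FALSE)
      }
      path <- file.path(org_dir, paste0(tab, ".csv"))
      write_csv_file(df, path)
      files[[org]][[tab]] <- path
    }
  }
  ledger <- if (length(ledger_rows) == 0) empty_ledger() else do.call(rbind, ledger_rows)
  list(files = files, ledger = ledger)
}
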