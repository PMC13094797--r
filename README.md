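# studyflow

Configuration-driven data management for multicenter epidemiologic studies.

## The problem

Multicenter studies — the motivating case is a nationwide blood-donor
serosurveillance cohort — receive recurring tabular submissions (donor
rosters, donation events, laboratory results) from many collection
organizations, plus multi-round electronic surveys whose questions change
between rounds. Each delivery must be quality-controlled against a shared
data dictionary, accepted or rejected atomically, imported into a canonical
study database, recoded to study-specific groupings, and re-exported to a
data coordinating center in its own reporting dictionary — all while storing
as little personally identifying information as possible.

`studyflow` implements that pipeline for R users. One project-wide YAML
configuration file holds everything study-specific: the data dictionaries
(field types, lengths, enumerated codes, primary/foreign keys, PII classes),
the QC severity policy, versioned lookup tables, per-organization intake
buckets, and report specifications. The code never hard-codes a study table;
adapting the system to a new study means editing the configuration, not the
package.

## What's inside

| Module | What it does |
|---|---|
| configuration | `load_config()` parses and cross-validates the project file; `diff_dictionaries()` reviews dictionary updates; `resolve_lookup()` applies versioned recodes |
| QC engine | `check_row()`, `check_keys()`, `validate_submission()` emit an itemized, byte-reproducible issue report (`TYPE`, `LENGTH`, `DATE`, `ENUM`, `REQUIRED`, `DUP_KEY`, `FK_ORPHAN`, column reconciliation) with an atomic accept/reject verdict |
| study store | an embedded relational store whose materialized constraints re-refuse anything the dictionary forbids (a redundant, passive second QC line); transactional, idempotent `import_submission()`; `recode()`; donor identifier-change tracking |
| intake workflow | per-organization `upload/download/archive` buckets, digest-tracked scanning, accept-to-archive / reject-with-report routing, pluggable notification sinks |
| survey manager | long-format question/response/answer store with cross-round question equivalency and a structural consent gate |
| reporting | `build_report()` extracts, transforms (rename, lookup recode, constant, cross-field, privacy) and re-validates outbound files against a reporting dictionary |
| privacy | `apply_privacy()`: month-level dates, 3-digit ZIP prefixes, drops; idempotent and fail-closed |
| simulator | `generate_study()` / `corrupt_study()`: a seedable synthetic multicenter study with controlled error injection and a ground-truth ledger |

A thin command-line wrapper (`inst/cli/studyflow`, driving the exported
`main()`) exposes `init`, `validate`, `simulate`, `run-once`, `watch`,
`report` and `survey` subcommands for cron-style operation.

## Worked example

```r
library(studyflow)

cfg <- load_config(system.file("extdata/demo/config.yml", package = "studyflow"))

# simulate a 2-organization study and inject dictionary violations
sim   <- sim_config(seed = 7, n_orgs = 2, n_donors = 100)
study <- generate_study(sim, cfg, "clean")
bad   <- corrupt_study(study, cfg, "corrupted")

db <- db_open(); create_schema(cfg, db)

validate_submission(study$files$org1, cfg, db)
#> <validation_report f9b8afba...: accepted, 0 issue(s) over 246 row(s)>

rep <- validate_submission(bad$files$org1, cfg, db)
rep
#> <validation_report 93314af4...: rejected, 22 issue(s) over 252 row(s)>
```

The 22 itemized issues are exactly the 22 corruptions the ledger recorded
for that organization — the QC engine's detection is measured against known
ground truth, not against itself. Importing the clean submission:

```r
import_submission(study$files$org1, validate_submission(study$files$org1, cfg, db), cfg, db)
#> <import f9b8afba...: committed, 246/246 row(s)>
head(db_table(db, "donor")$birth_date, 2)
#> [1] "1991-05" "1932-07"     # dates of birth stored at month level only
```

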