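---
title: "Configuration-driven management of multicenter study data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Configuration-driven management of multicenter study data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(studyflow)
```

## The setting

A multicenter epidemiologic study — the archetype here is a nationwide
blood-donor cohort — receives recurring deliveries of donor, donation and
laboratory-testing tables from several collection organizations, together
with multi-round electronic donor surveys. The operational problem is not
statistical: it is keeping heterogeneous, frequently revised tabular
deliveries consistent with a shared data dictionary, with a full audit trail,
at a data volume where spreadsheets fail. `studyflow` treats this as a
workflow problem: every delivery passes through *intake → QC → store →
recode → report*, and every study-specific fact — table shapes, allowable
codes, key relationships, severity policy, report layouts — lives in a
single project-wide YAML configuration, never in code.

This vignette explains the design of each stage, the parameters that
matter, the numerical and procedural choices made where the design was
genuinely open, and what the package's synthetic-data tests do and do not
demonstrate about real deployments.

## The data dictionary and configuration

The dictionary is a machine-readable YAML sub-schema: tables → ordered
fields → attributes. Each field carries a semantic type (`text`, `integer`,
`decimal`, `date`, `datetime`, `code`), an optional maximum length, the
enumerated code set for `code` fields, a required flag, a key role
(`primary`/`foreign` with a resolvable target), a PII class and optional
calendar bounds for dates. Tables carry a *dependency level* — level-1
tables stand alone; a level-2 table's foreign keys point at level-1 tables —
which fixes processing order everywhere (validation context, import order,
intake sequencing).

`load_config()` validates *exhaustively*: every dangling foreign key, lookup
source, bucket table and report field is collected and reported in one
failure, because a configuration author fixing references one at a time is
the slowest possible loop. Unknown top-level keys warn rather than fail, so
configurations written for older package versions keep running. Per-user
configuration files shallow-merge over the project file — the project file
defines the study, the user file overrides local concerns (paths,
credentials); a deep merge was rejected because partial overrides of a
dictionary would silently fork the study's definition.

Lookup tables are versioned append-only mappings from source values to study
groupings (e.g. organization-specific race codes to the study's analytic
groups). Originals are never overwritten: `recode()` writes a derived
relation keyed by primary key, so stakeholders can revise groupings by
adding a version and re-running, and any prior interpretation remains
reconstructable.

## The QC engine

`validate_submission()` reconciles the header (missing/unknown columns are
table-level issues at row 0), then checks every cell, then the keys. The
checks per field run in a fixed order — REQUIRED on empty cells, then TYPE,
then LENGTH/DATE/ENUM — with one deliberate suppression rule: a failed TYPE
check suppresses that cell's downstream checks. A cell containing `"forty"`
in an integer column is one actionable problem, not three; itemized reports
are meant to be worked through by a submitting organization.

Dates are accepted in ISO-8601 only. A value that does not match
`YYYY-MM-DD` is a TYPE issue; a pattern-valid value that is not a real
calendar date (`2020-02-30`) or falls outside the field's declared bounds is
a DATE issue. Local date formats are deliberately not tolerated at QC time:
format normalization is a transform concern for whichever intake adapter
produced the file, and tolerating ambiguity (is `03/04/2021` March or
April?) would make reports non-deterministic.

Key checks are order-deterministic: the first occurrence of a duplicated
primary key is never flagged, later occurrences are; foreign keys resolve
against the store's keys plus co-submitted lower-level tables, and —
because donor identifiers genuinely change over a cohort's lifetime — a
superseded identifier whose recorded change chain ends at a stored key is
accepted and canonicalized at import.

The verdict is atomic (one reject-severity issue rejects the file) because
partial acceptance would make resubmission semantics ambiguous. Severity is
configurable per issue kind; the default policy rejects everything except
unknown extra columns, which warn — extra columns are a tolerable dialect
difference, absent declared columns are not. Issues are sorted
(table, row, field), making a report byte-reproducible for a given file.

Cross-field rules ("result value required when the interpretation is
positive") exist in reporting specifications as declared predicates
(`required_when`); their violations are emitted as REQUIRED-kind issues to
keep the issue vocabulary closed. Arbitrary code hooks are an extension
point, not a configuration feature: a rule you cannot declare is a rule you
should review in code.

## The study store as a second QC line

The store materializes the dictionary at the storage layer: per-column type,
length, nullability and enumerated checks, plus primary-key uniqueness and
foreign-key resolution, enforced in a code path intentionally separate from
the QC engine. This redundancy is the point — if a policy change downgrades
a check to a warning, or a bug lets a bad row through QC, the store still
refuses it. The package ships this store as an embedded relational layer
over data frames with CSV/JSON persistence; the surface (`db_open`,
`create_schema`, `db_insert_rows`, `import_submission`, …) is a thin
interface behind which a server-backed engine could sit unchanged.

Imports are all-or-nothing: all rows of all files in one transaction, with a
mid-import constraint violation rolling everything back and identifying the
violating row. The store never holds half a submission, so "row count"
always means "sum of committed imports". Imports are also idempotent, keyed
on the submission's content digest: replaying the archive is safe, which is
what makes the archive an audit mechanism rather than just a backup. Donor
tables are declared `append_only: false` and refresh by upsert with an audit
record — cohort donor attributes are periodically re-delivered in full, and
versioning every quarterly refresh as new rows would conflate delivery
cadence with data change.

## Privacy minimization

Fields classed as indirectly identifying carry a declared transform applied
at import (and/or reporting): dates of birth truncate to `YYYY-MM` (month
level), ZIP codes to their first 3 digits (which encode larger areas);
directly identifying fields without an explicit override are dropped.
Transforms are idempotent and fail closed — a malformed value under a
truncation rule is an error, never passed through — and the storage column
adopts the *transformed* shape, so even a direct insert cannot land a full
date of birth in the store. Month-level dates serialize as `YYYY-MM`
(a serialization had to be chosen; ISO prefix ordering keeps string
comparisons meaningful), and non-US postal codes are dropped rather than
truncated because a 3-character prefix of an arbitrary postal format has no
guaranteed coarsening semantics.

## Intake buckets

Each organization exchanges files through an `upload/download/archive`
bucket. A polling pass (`run_cycle()`) — polling rather than OS file-system
hooks, for portability — picks up new uploads in dependency-level order,
validates, and routes: accepted files move to the archive with a receipt
timestamp and digest appended to the name (uploads are frequently re-sent
under identical names; the archive must never overwrite), and are imported;
rejected files return to the download directory together with the itemized
report. Processing is tracked by content digest, so re-dropping an identical
file, or running the cycle twice, is a no-op — and an import failure after
QC acceptance leaves the file in upload, unmarked, with an alert: recoverable,
never silently lost, never double-imported. Notification is a pluggable sink
interface (in-memory and line-delimited-file sinks ship; mail or chat
transports implement one method); a failing sink is retried once and then
recorded as undelivered without ever affecting a disposition.

## Survey data

Survey questions change between rounds, so the store is long-format: a
question registry (one row per question per round, equivalent questions
across rounds sharing a question ID), one response row per respondent per
round with completion and consent flags, and one answer row per answered
question. No schema change ever accompanies a new round — the tests assert
that registering rounds leaves every relation's columns untouched.

Question equivalency is *curated*: the study team supplies, at round
registration, the mapping from new question keys to existing question IDs;
the only automation is an exact-text match against earlier rounds. Semantic
matching of reworded questions was deliberately not attempted — a wrong
silent match would corrupt longitudinal analyses invisibly, which is a far
worse failure mode than asking a curator for one mapping entry per reworded
question.

The consent gate is structural, not procedural: answer rows may only
reference consented responses, and ingest suppresses (and counts) any
answers present in a raw platform export for non-consenting respondents.
This covers the late-withdrawal case where the platform export still carries
answers given before consent was withdrawn; such respondents remain recorded
as having responded, flagged non-consenting, with zero stored answers. The
`completed` flag is taken from the platform export and never derived from
answer counts — an incomplete response with many answers and a complete one
with few are both real. Answers violating a question's declared answer
domain are itemized and not stored, mirroring the submission-side ENUM
policy.

Analytic tables are derived, never primary: `derive_analytic()` pivots the
requested question IDs and rounds to one row per (respondent, round), and
the pivot is lossless — melting the wide table reproduces the underlying
answer relation exactly, which the tests assert on randomized fixtures.

## Reporting

A report specification declares sources (fields from tables, joined
child-to-parent through the dictionary's foreign keys), an *ordered* list of
transforms from a closed vocabulary (rename, lookup recode, constant,
cross-field map, privacy), a target schema, and cross-field QC hooks.
Outbound rows are validated against the target schema — an emitted report is
itself a valid submission to its recipient's second QC stage — and a report
with any reject-severity finding is withheld entirely. Transform order is
semantically significant and therefore part of the specification's digest:
permuting transforms is a detectable spec change, never a silent reorder.
Files are written to a temporary name and renamed into place, so a partial
report is never visible to a transfer process. Report scheduling cadences
are configuration labels only; no scheduler is embedded.

## The synthetic study and what the tests show

`generate_study()` emulates the structure of multicenter submissions
directly from the dictionary: field values are drawn from each field's
declared codes, bounds and lengths, so clean output passes QC with zero
issues *by construction* — that is asserted, not assumed. Default study
conditions: 2 organizations, 500 donors split evenly, donations per donor
negative-binomial with mean 2 and dispersion 5 (a donor typically gives a
couple of times over a study window, with a long tail of frequent donors),
one testing row per donation, 3 survey rounds of 10 questions with 30%
question churn per round, 80% consent, and a 2% per-cell corruption rate.
Half of each organization's donors are survey respondents, and half of the
non-consenting respondents still carry raw answers in the export — the
adversarial late-withdrawal case the consent gate must absorb.

`corrupt_study()` walks every cell in deterministic order and corrupts each
with the configured probability, drawing the issue kind from the configured
mix restricted to kinds the field can express. Two corruptions are row-level
by construction: duplicated primary keys append a *clean copy* of the row
(overwriting another row's key could orphan children and cascade into
issues the ledger never recorded), and foreign-key orphaning rewrites the
reference to an identifier outside any generated namespace. One corruption
per cell at most; every injection is recorded exactly once in the ledger and
cell-level injections are self-checked against the row checker at generation
time. The central property the acceptance tests then measure is *ledger
equivalence*: over 20 seeds at the default study conditions, the QC engine's
issue multiset equals the injected ledger exactly — 100% precision and
recall for the seven injectable kinds.

What this does not show: the generator's values are dictionary-valid, not
epidemiologically calibrated — no seroprevalence dynamics, no realistic
donation seasonality, no correlated missingness, and no real-world CSV
dialect quirks (encodings, embedded newlines beyond RFC-4180, vendor
headers). Passing the synthetic suite demonstrates the *mechanism* —
detection, routing, atomicity, consent gating, determinism — not robustness
to every artifact of a particular operational data system.

## Numerical and procedural details

* Problem sizes in the test suite: the ledger-equivalence property runs 20
  seeds at 2 organizations × 500 donors; survey properties use 50
  respondents over 3 rounds; the store-refusal property uses 100 engineered
  rows. These sizes give every issue kind hundreds of opportunities to
  occur while keeping the default suite under a minute.
* Determinism: all generation flows from a single integer seed through R's
  default RNG; the corruption pass re-seeds from a fixed offset of the study
  seed so that adding survey rounds never perturbs which cells corrupt.
  Files are written with LF endings and fixed quoting, so determinism is
  byte-level.
* Digests are MD5 — identity and idempotency keys, not cryptographic
  integrity.
* Ties and degenerate inputs: empty tables validate vacuously; zero-byte or
  unrecognizable uploads reject with a single table-level issue; an empty
  dictionary refuses to create a schema; identifier-change cycles are
  data-integrity errors (the resolver refuses rather than picking a
  terminus).
* Exit codes of the command-line wrapper are stable: 0 success, 1 validation
  rejection, 2 configuration failure, 3 transport/IO failure, 64 usage.

## Known limitations

The embedded store is single-process and in-memory between explicit
saves; multi-user deployment, replication and row-level governance are out
of scope (per-table extract allow-lists in report specifications are the
only governance primitive). Transport is a local-filesystem abstraction —
a remote transport would implement the same surface, but none ships. There
is no statistical QC (outlier detection, imputation, fuzzy code matching)
and no analysis layer: primary analysis belongs downstream of the reporting
boundary.
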