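# Project configuration and data dictionaries.
#
# Everything study-specific -- table dictionaries, lookup tables, QC policy,
# intake buckets, report specifications -- lives in one YAML file. The code in
# this package never hard-codes a study table or field.

SEMANTIC_TYPES <- c("text", "integer", "decimal", "date", "datetime", "code")
KEY_ROLES <- c("none", "primary", "foreign")
PII_CLASSES <- c("none", "indirect", "direct")
ISSUE_KINDS <- c("TYPE", "LENGTH", "DATE", "ENUM", "REQUIRED",
                 "DUP_KEY", "FK_ORPHAN", "UNKNOWN_COLUMN", "MISSING_COLUMN")

# default per-kind severities; a config's qc_policy overrides per kind
DEFAULT_QC_POLICY <- c(
  TYPE = "reject", LENGTH = "reject", DATE = "reject", ENUM = "reject",
  REQUIRED = "reject", DUP_KEY = "reject", FK_ORPHAN = "reject",
  MISSING_COLUMN = "reject", UNKNOWN_COLUMN = "warn"
)

#' Construct a field specification
#'
#' One dictionary entry: the name, semantic type, maximum length, allowable
#' codes for enumerated fields, key role, and privacy class of a single field.
#'
#' @param name Field identifier (lower_snake_case).
#' @param type One of `text`, `integer`, `decimal`, `date`, `datetime`, `code`.
#' @param max_length Positive integer, or `NA` for unbounded.
#' @param allowed_codes Character vector of allowable codes; required exactly
#'   when `type = "code"`.
#' @param required Must the cell be non-empty?
#' @param key One of `none`, `primary`, `foreign`.
#' @param foreign_target For foreign keys, `c(table, field)`.
#' @param pii_class One of `none`, `indirect`, `direct`.
#' @param date_bounds Optional `c(min, max)` ISO dates for date fields.
#' @param privacy Optional privacy transform name (see [privacy_rule()]).
#' @param privacy_applied_at Where the transform applies: `import`, `report`
#'   or `both`.
#' @return A `field_spec` object.
#' @export
field_spec <- function(name, type = "text", max_length = NA, allowed_codes = NULL,
                       required = FALSE, key = "none", foreign_target = NULL,
                       pii_class = "none", date_bounds = NULL,
                       privacy = NULL, privacy_applied_at = "import") {
  stopifnot(is_scalar_chr(name))
  if (!type %in% SEMANTIC_TYPES)
    sf_stop("config_error", sprintf("field '%s': unknown type '%s'", name, type))
  if (!key %in% KEY_ROLES)
    sf_stop("config_error", sprintf("field '%s': unknown key role '%s'", name, key))
  if (!pii_class %in% PII_CLASSES)
    sf_stop("config_error", sprintf("field '%s': unknown pii_class '%s'", name, pii_class))
  if (!is.na(max_length) && (!is.numeric(max_length) || max_length < 1))
    sf_stop("config_error", sprintf("field '%s': max_length must be >= 1", name))
  has_codes <- !is.null(allowed_codes) && length(allowed_codes) > 0
  if (has_codes != (type == "code"))
    sf_stop("config_error", sprintf(
      "field '%s': allowed_codes must be given exactly when type is 'code'", name))
  if (key == "foreign" && (is.null(foreign_target) || length(foreign_target) != 2))
    sf_stop("config_error", sprintf(
      "field '%s': foreign key needs foreign_target (table, field)", name))
  if (!is.null(date_bounds)) {
    if (length(date_bounds) != 2 || !all(iso_date_valid(date_bounds)))
      sf_stop("config_error", sprintf("field '%s': date_bounds must be 2 ISO dates", name))
  }
  structure(list(
    name = name, type = type,
    max_length = if (is.na(max_length)) NA_integer_ else as.integer(max_length),
    allowed_codes = if (has_codes) as.character(allowed_codes) else NULL,
    required = isTRUE(required), key = key,
    foreign_target = if (!is.null(foreign_target)) as.character(foreign_target) else NULL,
    pii_class = pii_class,
    date_bounds = if (!is.null(date_bounds)) as.character(date_bounds) else NULL,
    privacy = privacy, privacy_applied_at = privacy_applied_at
  ), class = "field_spec")
}

#' Construct a table schema
#'
#' @param name Table identifier.
#' @param fields Ordered list of [field_spec()] objects.
#' @param level Dependency level: level-1 tables stand alone, higher levels
#'   reference lower ones through foreign keys.
#' @param append_only If `TRUE`, a primary key already present in the store is
#'   a duplicate; if `FALSE`, re-imports upsert (with audit) by key.
#' @return A `table_schema` object.
#' @export
table_schema <- function(name, fields, level = 1L, append_only = TRUE) {
  stopifnot(is_scalar_chr(name), length(fields) >= 1)
  fnames <- vapply(fields, function(f) f$name, "")
  if (anyDuplicated(fnames))
    sf_stop("config_error", sprintf("table '%s': duplicate field names", name))
  pk <- fnames[vapply(fields, function(f) f$key == "primary", TRUE)]
  if (length(pk) == 0)
    sf_stop("config_error", sprintf("table '%s': no primary key declared", name))
  names(fields) <- fnames
  structure(list(name = name, fields = fields, level = as.integer(level),
                 append_only = isTRUE(append_only), primary_key = pk),
            class = "table_schema")
}

#' @export
format.table_schema <- function(x, ...) {
  sprintf("<table_schema '%s': %d fields, level %d, pk = %s>",
          x$name, length(x$fields), x$level, paste(x$primary_key, collapse = "+"))
}

#' @export
print.table_schema <- function(x, ...) { cat(format(x), "\n"); invisible(x) }

#' Construct a versioned lookup table
#'
#' A lookup (reference) table maps original source values to study-specific
#' groupings. Originals are never overwritten: recoding writes a derived
#' column. Versions are monotonically increasing; stakeholders revise
#' groupings by adding a version, never by editing history.
#'
#' @param name Lookup identifier.
#' @param source `c(table, field)` the lookup applies to.
#' @param versions Named list: one `list(version =, mapping =)` per entry,
#'   `mapping` a named character vector (original -> study group).
#' @return A `lookup_table` object.
#' @export
lookup_table <- function(name, source, versions) {
  stopifnot(is_scalar_chr(name), length(source) == 2)
  vnum <- vapply(versions, function(v) as.integer(v$version), 1L)
  if (is.unsorted(vnum, strictly = TRUE))
    sf_stop("config_error", sprintf("lookup '%s': versions must strictly increase", name))
  for (v in versions) {
    if (anyDuplicated(names(v$mapping)))
      sf_stop("config_error", sprintf(
        "lookup '%s' v%s: an original value appears twice", name, v$version))
  }
  structure(list(name = name, source = as.character(source), versions = versions,
                 latest = max(vnum)),
            class = "lookup_table")
}

#' Sentinel for values a lookup does not map
#'
#' Unknown original values are data, not errors; they resolve to this
#' distinguished sentinel and are counted by [recode()].
#' @export
UNMAPPED <- "__unmapped__"

#' Resolve a value through a lookup table
#'
#' @param lookup A [lookup_table()].
#' @param value Character vector of original values.
#' @param version Lookup version; defaults to the latest.
#' @return Study groups, with [UNMAPPED] for unknown values. Never errors on
#'   unknown values.
#' @export
resolve_lookup <- function(lookup, value, version = NULL) {
  version <- version %||% lookup$latest
  vs <- Filter(function(v) as.integer(v$version) == as.integer(version), lookup$versions)
  if (length(vs) == 0)
    sf_stop("usage_error", sprintf("lookup '%s' has no version %s", lookup$name, version))
  m <- vs[[1]]$mapping
  out <- unname(m[value])
  out[is.na(out)] <- UNMAPPED
  out
}

# ---- YAML parsing -----------------------------------------------------------

parse_field_yaml <- function(y, table) {
  tryCatch(
    field_spec(
      name = y$name, type = y$type %||% "text",
      max_length = y$max_length %||% NA,
      allowed_codes = y$allowed_codes,
      required = isTRUE(y$required),
      key = y$key %||% "none",
      foreign_target = if (!is.null(y$references))
        c(y$references$table, y$references$field) else NULL,
      pii_class = y$pii_class %||% "none",
      date_bounds = y$date_bounds,
      privacy = y$privacy,
      privacy_applied_at = y$privacy_applied_at %||% "import"
    ),
    studyflow_error = function(e)
      sf_stop("config_error", sprintf("table '%s': %s", table, conditionMessage(e)))
  )
}

parse_schema_yaml <- function(name, y) {
  fields <- lapply(y$fields, parse_field_yaml, table = name)
  table_schema(name, fields, level = y$level %||% 1L,
               append_only = !identical(y$append_only, FALSE))
}

KNOWN_TOP_KEYS <- c("study_id", "qc_policy", "dictionaries", "lookups",
                    "buckets", "reports", "paths", "credentials")

#' Load and validate the project configuration
#'
#' Parses the single project-wide YAML file, builds every table schema,
#' lookup, bucket and report specification, and cross-validates all
#' references. Validation collects *every* unresolved reference before
#' failing, so a configuration author sees the complete list at once.
#'
#' Unknown top-level keys are warnings, not errors: old configurations keep
#' running on newer code.
#'
#' @param path Path to the YAML configuration file.
#' @param override Optional path to a per-user configuration file; its
#'   top-level keys shallow-merge over (replace) the project file's.
#' @return A `project_config` object with elements `study_id`,
#'   `dictionaries`, `lookups`, `qc_policy`, `buckets`, `reports`, `paths`.
#' @export
load_config <- function(path, override = NULL) {
  if (!file.exists(path))
    sf_stop("transport_error", sprintf("config file not found: %s", path))
  y <- tryCatch(yaml::read_yaml(path),
                error = function(e) sf_stop("config_syntax_error", sprintf(
                  "configuration syntax failure in %s: %s", path, conditionMessage(e))))
  if (!is.null(override)) {
    ov <- tryCatch(yaml::read_yaml(override),
                   error = function(e) sf_stop("config_syntax_error", sprintf(
                     "configuration syntax failure in %s: %s", override, conditionMessage(e))))
    for (k in names(ov)) y[[k]] <- ov[[k]]
  }
  unknown <- setdiff(names(y), KNOWN_TOP_KEYS)
  if (length(unknown) > 0)
    warning(sprintf("ignoring unknown configuration keys: %s",
                    paste(unknown, collapse = ", ")), call. = FALSE)
  if (is.null(y$dictionaries) || length(y$dictionaries) == 0)
    sf_stop("config_error", "a study must declare at least one table")

  dictionaries <- lapply(names(y$dictionaries), function(nm)
    parse_schema_yaml(nm, y$dictionaries[[nm]]))
  names(dictionaries) <- names(y$dictionaries)

  lookups <- lapply(y$lookups %||% list(), function(l) {
    versions <- lapply(l$versions, function(v)
      list(version = as.integer(v$version),
           mapping = vapply(v$mapping, as.character, "")))
    lookup_table(l$name, c(l$source$table, l$source$field), versions)
  })
  if (length(lookups) > 0)
    names(lookups) <- vapply(lookups, function(l) l$name, "")

  qc_policy <- DEFAULT_QC_POLICY
  for (k in names(y$qc_policy %||% list())) {
    if (!k %in% ISSUE_KINDS)
      sf_stop("config_error", sprintf("qc_policy: unknown check kind '%s'", k))
    sev <- y$qc_policy[[k]]
    if (!sev %in% c("reject", "warn"))
      sf_stop("config_error", sprintf("qc_policy: severity must be reject/warn, got '%s'", sev))
    qc_policy[[k]] <- sev
  }

  buckets <- lapply(y$buckets %||% list(), function(b)
    list(org_id = b$org_id,
         expected_tables = as.character(b$expected_tables %||% character()),
         schedule = b$schedule %||% "ad hoc"))
  reports <- lapply(y$reports %||% list(), parse_report_yaml)
  if (length(reports) > 0)
    names(reports) <- vapply(reports, function(r) r$name, "")

  cfg <- structure(list(
    study_id = y$study_id %||% "unnamed_study",
    dictionaries = dictionaries, lookups = lookups, qc_policy = qc_policy,
    buckets = buckets, reports = reports,
    paths = y$paths %||% list(), credentials = y$credentials %||% list()
  ), class = "project_config")

  dangling <- config_dangling_refs(cfg)
  if (length(dangling) > 0)
    sf_stop("config_consistency_error",
            paste0("configuration consistency failure; unresolved references:\n  ",
                   paste(dangling, collapse = "\n  ")),
            dangling = dangling)
  cfg
}

# every cross-reference, checked exhaustively; returns human-readable lines
config_dangling_refs <- function(cfg) {
  bad <- character()
  for (ts in cfg$dictionaries) {
    for (f in ts$fields) {
      if (f$key == "foreign") {
        tgt <- f$foreign_target
        if (is.null(cfg$dictionaries[[tgt[1]]]) ||
            is.null(cfg$dictionaries[[tgt[1]]]$fields[[tgt[2]]]))
          bad <- c(bad, sprintf("foreign key (%s, %s) -> (%s, %s)",
                                ts$name, f$name, tgt[1], tgt[2]))
      }
    }
  }
  for (l in cfg$lookups) {
    if (is.null(cfg$dictionaries[[l$source[1]]]) ||
        is.null(cfg$dictionaries[[l$source[1]]]$fields[[l$source[2]]]))
      bad <- c(bad, sprintf("lookup '%s' source (%s, %s)", l$name, l$source[1], l$source[2]))
  }
  for (b in cfg$buckets) {
    miss <- setdiff(b$expected_tables, names(cfg$dictionaries))
    for (m in miss) bad <- c(bad, sprintf("bucket '%s' expects unknown table '%s'", b$org_id, m))
  }
  for (r in cfg$reports) {
    for (src in r$source) {
      if (is.null(cfg$dictionaries[[src$table]])) {
        bad <- c(bad, sprintf("report '%s' source table '%s'", r$name, src$table))
      } else {
        miss <- setdiff(src$fields, names(cfg$dictionaries[[src$table]]$fields))
        for (m in miss)
          bad <- c(bad, sprintf("report '%s' field (%s, %s)", r$name, src$table, m))
      }
    }
    for (tr in r$transforms) {
      if (identical(tr$kind, "lookup_recode") && is.null(cfg$lookups[[tr$lookup]]))
        bad <- c(bad, sprintf("report '%s' transform lookup '%s'", r$name, tr$lookup))
    }
  }
  bad
}

#' Serialize a project configuration back to YAML
#'
#' `load_config(write_config(cfg))` is semantically identical to `cfg`
#' (round-trip stability).
#'
#' @param cfg A `project_config`.
#' @param path Destination file.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  field_yaml <- function(f) {
    out <- list(name = f$name, type = f$type)
    if (!is.na(f$max_length)) out$max_length <- f$max_length
    if (!is.null(f$allowed_codes)) out$allowed_codes <- as.list(f$allowed_codes)
    if (f$required) out$required <- TRUE
    if (f$key != "none") out$key <- f$key
    if (!is.null(f$foreign_target))
      out$references <- list(table = f$foreign_target[1], field = f$foreign_target[2])
    if (f$pii_class != "none") out$pii_class <- f$pii_class
    if (!is.null(f$date_bounds)) out$date_bounds <- as.list(f$date_bounds)
    if (!is.null(f$privacy)) {
      out$privacy <- f$privacy
      out$privacy_applied_at <- f$privacy_applied_at
    }
    out
  }
  y <- list(
    study_id = cfg$study_id,
    qc_policy = as.list(cfg$qc_policy),
    dictionaries = lapply(cfg$dictionaries, function(ts) {
      out <- list(level = ts$level, fields = lapply(ts$fields, field_yaml))
      if (!ts$append_only) out$append_only <- FALSE
      out$fields <- unname(out$fields)
      out
    }),
    lookups = unname(lapply(cfg$lookups, function(l) list(
      name = l$name, source = list(table = l$source[1], field = l$source[2]),
      versions = lapply(l$versions, function(v)
        list(version = v$version, mapping = as.list(v$mapping)))
    ))),
    buckets = unname(lapply(cfg$buckets, function(b) list(
      org_id = b$org_id, expected_tables = as.list(b$expected_tables),
      schedule = b$schedule
    ))),
    reports = unname(lapply(cfg$reports, report_spec_yaml)),
    paths = cfg$paths, credentials = cfg$credentials
  )
  yaml::write_yaml(y, path)
  invisible(path)
}

# ---- dictionary diffing -----------------------------------------------------

FIELD_ATTRS <- c("type", "max_length", "allowed_codes", "required", "key",
                 "foreign_target", "pii_class", "date_bounds", "privacy",
                 "privacy_applied_at")

#' Diff two versions of a table schema
#'
#' Dictionary updates are routine in a running study; the diff makes a
#' dictionary change reviewable before the configuration is edited.
#'
#' @param old,new Two [table_schema()] objects sharing a table name.
#' @return A data.frame with columns `change` (`added`/`removed`/`modified`),
#'   `field`, and `attribute` (the modified attribute, or `NA`). Zero rows iff
#'   the schemas are identical.
#' @export
diff_dictionaries <- function(old, new) {
  if (!identical(old$name, new$name))
    sf_stop("usage_error", sprintf("schemas name different tables: '%s' vs '%s'",
                                   old$name, new$name))
  rows <- list()
  add <- function(change, field, attribute = NA_character_)
    rows[[length(rows) + 1L]] <<- data.frame(change = change, field = field,
                                             attribute = attribute,
                                             stringsAsFactors = FALSE)
  for (f in setdiff(names(new$fields), names(old$fields))) add("added", f)
  for (f in setdiff(names(old$fields), names(new$fields))) add("removed", f)
  for (f in intersect(names(old$fields), names(new$fields))) {
    for (a in FIELD_ATTRS) {
      if (!identical(old$fields[[f]][[a]], new$fields[[f]][[a]]))
        add("modified", f, a)
    }
  }
  if (length(rows) == 0)
    return(data.frame(change = character(), field = character(),
                      attribute = character(), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Apply a dictionary change-list to an old schema
#'
#' The inverse operation of [diff_dictionaries()]: applying its change-list
#' to the old schema (given the new one as the attribute source) reproduces
#' the new schema exactly.
#'
#' @param old The old [table_schema()].
#' @param changes Change-list from [diff_dictionaries()].
#' @param new The new schema, supplying attribute values and field order.
#' @return A `table_schema` identical to `new`.
#' @export
apply_dictionary_diff <- function(old, changes, new) {
  fields <- old$fields
  for (i in seq_len(nrow(changes))) {
    ch <- changes[i, ]
    if (ch$change == "added") fields[[ch$field]] <- new$fields[[ch$field]]
    if (ch$change == "removed") fields[[ch$field]] <- NULL
    if (ch$change == "modified")
      fields[[ch$field]][[ch$attribute]] <- new$fields[[ch$field]][[ch$attribute]]
  }
  fields <- fields[names(new$fields)]
  table_schema(old$name, fields, level = new$level, append_only = new$append_only)
}
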