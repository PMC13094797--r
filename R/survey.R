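# Long-format survey store with cross-round question equivalency and a
# consent gate.
#
# Survey questions change between rounds, so the store is long: a question
# registry (every question ever asked, with equivalent questions across
# rounds sharing one question ID), one response row per respondent per round
# (with completion and consent flags), and one answer row per answered
# question. No schema change is ever needed when a round adds or rewords
# questions. The consent gate is structural: answer rows can only reference
# consented responses, so a non-consenting respondent (including late
# withdrawal, where the raw platform export still carries their answers) is
# recorded as having responded but contributes zero stored answers.

survey_relations <- function() {
  list(
    questions = data.frame(question_id = character(), round = character(),
                           key = character(), text = character(),
                           answer_domain = character(), stringsAsFactors = FALSE),
    responses = data.frame(response_id = character(), respondent_id = character(),
                           round = character(), completed = character(),
                           consented = character(), stringsAsFactors = FALSE),
    answers = data.frame(response_id = character(), question_id = character(),
                         answer = character(), stringsAsFactors = FALSE)
  )
}

next_question_ids <- function(db, n) {
  existing <- db$survey$questions$question_id
  top <- if (length(existing) == 0) 0L else
    max(as.integer(sub("^Q", "", unique(existing))))
  sprintf("Q%04d", top + seq_len(n))
}

#' Register a survey round's questions
#'
#' Equivalency across rounds is curated: the `equivalency_map` names, for
#' each question key of the new round that repeats or rewords an earlier
#' question, the existing question ID it is equivalent to. Keys absent from
#' the map (and not matching an earlier round's question text exactly) are
#' new questions and receive fresh IDs. Exact-text matches to an earlier
#' round are applied automatically as a convenience; semantic matching of
#' reworded questions is never attempted.
#'
#' @param db Store handle (schema created).
#' @param round New round label.
#' @param questions List of `list(key =, text =, answer_domain = NULL)`;
#'   `key` is the column name used by the platform export,
#'   `answer_domain` an optional character vector of allowed codes.
#' @param equivalency_map Named character vector: question key -> existing
#'   question ID.
#' @return Data.frame of the registered questions, with a `new` flag.
#' @export
register_round <- function(db, round, questions, equivalency_map = character()) {
  reg <- db$survey$questions
  if (round %in% reg$round)
    sf_stop("usage_error", sprintf("round '%s' already registered", round))
  keys <- vapply(questions, function(q) q$key, "")
  if (anyDuplicated(keys))
    sf_stop("usage_error", "duplicate question keys within the round")
  mapped <- unname(equivalency_map[keys])
  bad <- !is.na(mapped) & !mapped %in% reg$question_id
  if (any(bad))
    sf_stop("usage_error", sprintf("equivalency map names unknown question id(s): %s",
                                   paste(mapped[bad], collapse = ", ")))
  # exact-text fallback for unmapped keys
  for (i in which(is.na(mapped))) {
    hit <- reg$question_id[match(questions[[i]]$text, reg$text)]
    if (!is.na(hit)) mapped[i] <- hit
  }
  if (anyDuplicated(stats::na.omit(mapped)))
    sf_stop("usage_error", "two questions in one round map to the same question id")
  is_new <- is.na(mapped)
  mapped[is_new] <- next_question_ids(db, sum(is_new))
  rows <- data.frame(
    question_id = mapped, round = round, key = keys,
    text = vapply(questions, function(q) q$text, ""),
    answer_domain = vapply(questions, function(q)
      paste(q$answer_domain %||% character(), collapse = "|"), ""),
    stringsAsFactors = FALSE)
  db$survey$questions <- rbind(reg, rows)
  rows$new <- is_new
  rows
}

round_registry <- function(db, round) {
  r <- db$survey$questions[db$survey$questions$round == round, , drop = FALSE]
  if (nrow(r) == 0) sf_stop("usage_error", sprintf("round '%s' not registered", round))
  r
}

#' Ingest a raw survey-platform export
#'
#' Accepts either a wide export (columns `respondent_id`, `completed`,
#' `consented`, plus one column per question key) or a long export (columns
#' `respondent_id`, `completed`, `consented`, `question`, `answer`). Writes
#' one response row per respondent (first occurrence of a duplicate
#' respondent wins; later ones are rejected), and answer rows only for
#' consented respondents -- answers present in the export for non-consenters
#' are suppressed and counted, covering consent withdrawn late in the
#' process. Answers for unregistered questions, and answers outside a
#' question's declared answer domain, are rejected and itemized.
#'
#' @param db Store handle.
#' @param export Data.frame or CSV path (the raw platform export).
#' @param round Registered round label.
#' @param format `"wide"` or `"long"`.
#' @return Ingest summary: counts of responses written, answers stored,
#'   answers suppressed by the consent gate, and itemized rejections.
#' @export
ingest_responses <- function(db, export, round, format = c("wide", "long")) {
  format <- match.arg(format)
  if (is.character(export)) export <- read_submission(export)
  reg <- round_registry(db, round)
  rejections <- character()
  summary0 <- list(responses = 0L, answers = 0L, suppressed = 0L, rejections = character())
  if (nrow(export) == 0) return(summary0)

  # normalize the platform export into one respondent frame + candidate
  # answers in long form (the export itself may be wide or long)
  if (format == "wide") {
    resp_df <- export[c("respondent_id", "completed", "consented")]
    qcols <- setdiff(colnames(export), c("respondent_id", "completed", "consented", "round"))
    long <- do.call(rbind, lapply(qcols, function(k)
      data.frame(respondent_id = export$respondent_id, key = k,
                 answer = export[[k]], stringsAsFactors = FALSE)))
    if (is.null(long)) long <- data.frame(respondent_id = character(), key = character(),
                                          answer = character(), stringsAsFactors = FALSE)
  } else {
    need <- c("respondent_id", "completed", "consented", "question", "answer")
    if (!all(need %in% colnames(export)))
      sf_stop("usage_error", "long export needs respondent_id/completed/consented/question/answer columns")
    resp_df <- export[!duplicated(export$respondent_id),
                      c("respondent_id", "completed", "consented")]
    long <- data.frame(respondent_id = export$respondent_id, key = export$question,
                       answer = export$answer, stringsAsFactors = FALSE)
  }

  dup <- duplicated(resp_df$respondent_id)
  if (any(dup)) {
    rejections <- c(rejections, sprintf(
      "duplicate (respondent '%s', round '%s'): later occurrence rejected, first kept",
      resp_df$respondent_id[dup], round))
    resp_df <- resp_df[!dup, , drop = FALSE]
  }
  prior <- db$survey$responses
  clash <- resp_df$respondent_id %in% prior$respondent_id[prior$round == round]
  if (any(clash)) {
    rejections <- c(rejections, sprintf(
      "respondent '%s' already has a response for round '%s'",
      resp_df$respondent_id[clash], round))
    resp_df <- resp_df[!clash, , drop = FALSE]
  }
  long <- long[long$respondent_id %in% resp_df$respondent_id, , drop = FALSE]
  if (nrow(resp_df) == 0)
    return(list(responses = 0L, answers = 0L, suppressed = 0L, rejections = rejections))

  consented <- tolower(resp_df$consented) %in% c("true", "1", "yes", "y")
  completed <- tolower(resp_df$completed) %in% c("true", "1", "yes", "y")
  response_id <- paste0("R_", round, "_", resp_df$respondent_id)
  long$i <- match(long$respondent_id, resp_df$respondent_id)

  long <- long[nzchar(long$answer), , drop = FALSE]
  qid <- reg$question_id[match(long$key, reg$key)]
  unreg <- is.na(qid)
  if (any(unreg)) {
    rejections <- c(rejections, sprintf(
      "answer to unregistered question '%s' (respondent '%s') rejected",
      long$key[unreg], long$respondent_id[unreg]))
    long <- long[!unreg, , drop = FALSE]; qid <- qid[!unreg]
  }
  # answer-domain validation (enumerated check, mirroring submission QC)
  dom <- reg$answer_domain[match(qid, reg$question_id)]
  bad_dom <- nzchar(dom) & !mapply(function(a, d)
    a %in% strsplit(d, "|", fixed = TRUE)[[1]], long$answer, dom)
  if (any(bad_dom)) {
    rejections <- c(rejections, sprintf(
      "answer '%s' outside domain of question '%s' rejected",
      long$answer[bad_dom], long$key[bad_dom]))
    long <- long[!bad_dom, , drop = FALSE]; qid <- qid[!bad_dom]
  }
  # the consent gate: suppress everything from non-consenters
  gated <- !consented[long$i]
  suppressed <- sum(gated)
  long <- long[!gated, , drop = FALSE]; qid <- qid[!gated]

  db$survey$responses <- rbind(db$survey$responses, data.frame(
    response_id = response_id, respondent_id = resp_df$respondent_id,
    round = round, completed = ifelse(completed, "true", "false"),
    consented = ifelse(consented, "true", "false"), stringsAsFactors = FALSE))
  n_ans <- 0L
  if (nrow(long) > 0) {
    ans <- data.frame(response_id = response_id[long$i], question_id = qid,
                      answer = long$answer, stringsAsFactors = FALSE)
    ans <- ans[!duplicated(ans[c("response_id", "question_id")]), , drop = FALSE]
    db$survey$answers <- rbind(db$survey$answers, ans)
    n_ans <- nrow(ans)
  }
  list(responses = nrow(resp_df), answers = n_ans,
       suppressed = suppressed, rejections = rejections)
}

#' Derive a wide analytic table from the long survey store
#'
#' One row per (respondent, round), one column per requested question ID,
#' empty cells where unanswered; only consented responses appear. The pivot
#' is lossless: [melt_analytic()] on the result reproduces the underlying
#' answer rows restricted to the request.
#'
#' @param db Store handle.
#' @param question_ids Question IDs to include (must exist).
#' @param rounds Round labels to include.
#' @return Data.frame `respondent_id`, `round`, then one column per
#'   question ID.
#' @export
derive_analytic <- function(db, question_ids, rounds) {
  reg <- db$survey$questions
  unknown <- setdiff(question_ids, reg$question_id)
  if (length(unknown) > 0)
    sf_stop("usage_error", sprintf("unknown question id(s): %s",
                                   paste(unknown, collapse = ", ")))
  question_ids <- sort(unique(question_ids))
  resp <- db$survey$responses
  resp <- resp[resp$round %in% rounds & resp$consented == "true", , drop = FALSE]
  ans <- db$survey$answers
  ans <- ans[ans$response_id %in% resp$response_id &
               ans$question_id %in% question_ids, , drop = FALSE]
  wide <- data.frame(respondent_id = resp$respondent_id, round = resp$round,
                     stringsAsFactors = FALSE)
  for (q in question_ids) {
    a <- ans[ans$question_id == q, , drop = FALSE]
    wide[[q]] <- a$answer[match(resp$response_id, a$response_id)]
    wide[[q]][is.na(wide[[q]])] <- ""
  }
  wide <- wide[order(wide$round, wide$respondent_id, method = "radix"), , drop = FALSE]
  rownames(wide) <- NULL
  wide
}

#' Melt an analytic table back to long answer rows
#'
#' The inverse of [derive_analytic()], used to verify the pivot is lossless.
#'
#' @param wide Output of [derive_analytic()].
#' @return Data.frame `response_id`, `question_id`, `answer` (non-empty cells
#'   only), sorted.
#' @export
melt_analytic <- function(wide) {
  qcols <- setdiff(colnames(wide), c("respondent_id", "round"))
  long <- do.call(rbind, lapply(qcols, function(q)
    data.frame(response_id = paste0("R_", wide$round, "_", wide$respondent_id),
               question_id = q, answer = wide[[q]], stringsAsFactors = FALSE)))
  if (is.null(long)) return(data.frame(response_id = character(),
                                       question_id = character(),
                                       answer = character(), stringsAsFactors = FALSE))
  long <- long[nzchar(long$answer), , drop = FALSE]
  long <- long[order(long$response_id, long$question_id, method = "radix"), , drop = FALSE]
  rownames(long) <- NULL
  long
}

#' Structural consent check over the whole store
#'
#' Asserts the consent gate: no answer row references a non-consenting
#' response.
#'
#' @param db Store handle.
#' @return `TRUE` invisibly; errors if the gate is violated.
#' @export
assert_consent_gate <- function(db) {
  nc <- db$survey$responses$response_id[db$survey$responses$consented != "true"]
  leak <- db$survey$answers$response_id %in% nc
  if (any(leak))
    sf_stop("integrity_error", sprintf(
      "%d answer row(s) reference non-consenting responses", sum(leak)))
  invisible(TRUE)
}
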