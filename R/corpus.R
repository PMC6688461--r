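#' Construct a chat corpus
#'
#' A corpus bundles a message table and a user-attribute table. Messages are
#' individual inbound (user-to-service) or outbound (agent-to-user) texts;
#' users carry the demographics used for stratified analyses. Users that
#' appear in the message table but not in the user table receive placeholder
#' records with all attributes unknown, so stratified summaries can report a
#' "missing" stratum explicitly.
#'
#' @param messages A data frame with columns `message_id`, `user_id`,
#'   `direction` (`"inbound"`/`"outbound"`), `timestamp` (POSIXct, UTC),
#'   and optionally `body`, `language` (`"en"`, `"sw"`, `"und"` or `NA`),
#'   `agent_id` (outbound only).
#' @param users Optional data frame with columns `user_id`, `sex`
#'   (`"female"`, `"male"`, `"unknown"`), `age_years` (numeric, `NA` for
#'   unknown), `language_preference` (`"en"`, `"sw"`, `"unknown"`).
#' @param load_report Optional load report produced by [read_corpus()].
#'
#' @return An object of class `chat_corpus`: a list with elements
#'   `messages`, `users` and `load_report`.
#' @export
corpus <- function(messages, users = NULL, load_report = NULL) {
  messages <- as_tibble(messages)
  required <- c("message_id", "user_id", "direction", "timestamp")
  missing_cols <- setdiff(required, names(messages))
  if (length(missing_cols) > 0) {
    .chatmine_abort(
      paste0("Missing required message column(s): ",
             paste(missing_cols, collapse = ", ")),
      "chatmine_schema_error"
    )
  }
  for (col in c("body", "language", "agent_id")) {
    if (!col %in% names(messages)) messages[[col]] <- NA_character_
  }
  messages <- messages[, c(required, "body", "language", "agent_id")]
  messages$message_id <- as.character(messages$message_id)
  messages$user_id <- as.character(messages$user_id)

  if (anyDuplicated(messages$message_id) > 0) {
    dup <- messages$message_id[duplicated(messages$message_id)][1]
    .chatmine_abort(
      paste0("Duplicate message_id: ", dup),
      "chatmine_integrity_error"
    )
  }
  if (!all(messages$direction %in% c("inbound", "outbound"))) {
    .chatmine_abort("direction must be 'inbound' or 'outbound'",
                    "chatmine_schema_error")
  }
  if (anyNA(messages$timestamp)) {
    .chatmine_abort("timestamps must all be set", "chatmine_schema_error")
  }
  # agent ids are meaningless on user-authored messages
  messages$agent_id[messages$direction == "inbound"] <- NA_character_

  if (is.null(users)) {
    users <- tibble(user_id = character(), sex = character(),
                    age_years = numeric(), language_preference = character())
  }
  users <- as_tibble(users)
  if (!"user_id" %in% names(users)) {
    .chatmine_abort("Missing required user column: user_id",
                    "chatmine_schema_error")
  }
  users$user_id <- as.character(users$user_id)
  if (!"sex" %in% names(users)) users$sex <- "unknown"
  if (!"age_years" %in% names(users)) users$age_years <- NA_real_
  if (!"language_preference" %in% names(users)) {
    users$language_preference <- "unknown"
  }
  users <- users[, c("user_id", "sex", "age_years", "language_preference")]
  users$sex[is.na(users$sex)] <- "unknown"
  users$language_preference[is.na(users$language_preference)] <- "unknown"
  if (anyDuplicated(users$user_id) > 0) {
    .chatmine_abort("Duplicate user_id in user table",
                    "chatmine_integrity_error")
  }
  bad_age <- !is.na(users$age_years) &
    (users$age_years < 10 | users$age_years > 100)
  if (any(bad_age)) {
    .chatmine_abort("age_years outside [10, 100]; use NA for unknown",
                    "chatmine_schema_error")
  }

  orphans <- setdiff(unique(messages$user_id), users$user_id)
  if (length(orphans) > 0) {
    users <- bind_rows(users, tibble(
      user_id = orphans, sex = "unknown", age_years = NA_real_,
      language_preference = "unknown"
    ))
  }

  structure(
    list(messages = messages, users = users, load_report = load_report),
    class = "chat_corpus"
  )
}

#' @export
print.chat_corpus <- function(x, ...) {
  n_in <- sum(x$messages$direction == "inbound")
  n_out <- sum(x$messages$direction == "outbound")
  cat("<chat_corpus>\n")
  cat("  messages:", nrow(x$messages),
      sprintf("(%d inbound, %d outbound)\n", n_in, n_out))
  cat("  users:   ", nrow(x$users), "\n")
  if (!is.null(x$load_report) && x$load_report$n_rejected > 0) {
    cat("  load:    ", x$load_report$n_rejected, "row(s) rejected\n")
  }
  invisible(x)
}

.ts_format <- "%Y-%m-%dT%H:%M:%SZ"

.format_ts <- function(x) format(x, .ts_format, tz = "UTC")

.parse_ts <- function(x) {
  # element-wise: each row may use any accepted dialect, bad rows stay NA
  x <- as.character(x)
  res <- rep(NA_real_, length(x))
  formats <- c("%Y-%m-%dT%H:%M:%SZ", "%Y-%m-%dT%H:%M:%S",
               "%Y-%m-%d %H:%M:%S", "%Y-%m-%d")
  for (f in formats) {
    need <- which(is.na(res) & !is.na(x))
    if (length(need) == 0) break
    p <- as.numeric(strptime(x[need], f, tz = "UTC"))
    res[need] <- ifelse(is.na(p), NA_real_, p)
  }
  as.POSIXct(res, origin = "1970-01-01", tz = "UTC")
}

#' Read a corpus from delimited or JSON-lines files
#'
#' Reads a message file (CSV or JSON-lines, one message object per line) and
#' an optional user-attribute CSV. Rows with an unparseable timestamp or a
#' missing/invalid direction are rejected, counted in the load report, and
#' dropped (or fatal under `strict = TRUE`). A header mapping supports file
#' dialects whose column names differ from the canonical schema.
#'
#' @param messages_path Path to the message file.
#' @param users_path Optional path to the user CSV.
#' @param format `"csv"` or `"jsonl"` for the message file.
#' @param col_map Optional named character vector mapping canonical field
#'   names (e.g. `message_id`) to the column names used in the file.
#' @param strict If `TRUE`, any rejected row is an error.
#'
#' @return A [corpus()] whose `load_report` lists rejected rows by reason.
#' @export
read_corpus <- function(messages_path, users_path = NULL,
                        format = c("csv", "jsonl"), col_map = NULL,
                        strict = FALSE) {
  format <- match.arg(format)
  if (!file.exists(messages_path)) {
    .chatmine_abort(paste0("No such file: ", messages_path),
                    "chatmine_io_error")
  }
  raw <- if (format == "csv") {
    read_csv(messages_path, col_types = cols(.default = col_character()),
             progress = FALSE)
  } else {
    lines <- readLines(messages_path, encoding = "UTF-8")
    lines <- lines[nzchar(trimws(lines))]
    bind_rows(lapply(lines, function(l) {
      as_tibble(lapply(fromJSON(l), as.character))
    }))
  }
  if (!is.null(col_map)) {
    for (canonical in names(col_map)) {
      file_col <- col_map[[canonical]]
      if (file_col %in% names(raw)) {
        names(raw)[names(raw) == file_col] <- canonical
      }
    }
  }
  required <- c("message_id", "user_id", "direction", "timestamp")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    .chatmine_abort(
      paste0("Missing required message column(s): ",
             paste(missing_cols, collapse = ", ")),
      "chatmine_schema_error"
    )
  }
  for (col in c("body", "language", "agent_id")) {
    if (!col %in% names(raw)) raw[[col]] <- NA_character_
  }

  ts <- .parse_ts(raw$timestamp)
  bad_ts <- is.na(ts)
  bad_dir <- is.na(raw$direction) |
    !raw$direction %in% c("inbound", "outbound")
  rejected <- tibble(
    reason = c("unparseable_timestamp", "missing_or_invalid_direction"),
    n = c(sum(bad_ts), sum(bad_dir & !bad_ts))
  )
  keep <- !(bad_ts | bad_dir)
  report <- list(
    n_read = nrow(raw),
    n_rejected = sum(!keep),
    reasons = rejected[rejected$n > 0, ]
  )
  if (strict && report$n_rejected > 0) {
    .chatmine_abort(
      paste0(report$n_rejected, " row(s) rejected under strict loading"),
      "chatmine_load_error"
    )
  }
  msgs <- raw[keep, ]
  msgs$timestamp <- ts[keep]

  users <- NULL
  if (!is.null(users_path)) {
    users <- read_csv(users_path,
                      col_types = cols(.default = col_character()),
                      progress = FALSE)
    if ("age" %in% names(users) && !"age_years" %in% names(users)) {
      names(users)[names(users) == "age"] <- "age_years"
    }
    if ("age_years" %in% names(users)) {
      users$age_years <- suppressWarnings(as.numeric(users$age_years))
    }
  }
  corpus(msgs, users, load_report = report)
}

#' Write a corpus to delimited or JSON-lines files
#'
#' Timestamps are written as ISO-8601 UTC instants; `NA` fields are written
#' as empty (CSV) or omitted (JSON-lines). `write_corpus()` followed by
#' [read_corpus()] round-trips all message and user fields.
#'
#' @param x A [corpus()].
#' @param messages_path,users_path Output paths (`users_path` optional).
#' @param format `"csv"` or `"jsonl"` for the message file.
#' @return `x`, invisibly.
#' @export
write_corpus <- function(x, messages_path, users_path = NULL,
                         format = c("csv", "jsonl")) {
  format <- match.arg(format)
  stopifnot(inherits(x, "chat_corpus"))
  out <- x$messages
  out$timestamp <- .format_ts(out$timestamp)
  if (format == "csv") {
    write_csv(out, messages_path, na = "", progress = FALSE)
  } else {
    lines <- vapply(seq_len(nrow(out)), function(i) {
      row <- as.list(out[i, ])
      row <- row[!vapply(row, is.na, logical(1))]
      toJSON(row, auto_unbox = TRUE)
    }, character(1))
    writeLines(lines, messages_path, useBytes = TRUE)
  }
  if (!is.null(users_path)) {
    write_csv(x$users, users_path, na = "", progress = FALSE)
  }
  invisible(x)
}

#' Summarize a corpus
#'
#' Corpus-level descriptives: message totals by direction, per-user inbound
#' message statistics (users with no inbound messages are excluded), percent
#' female among users with known sex, and age moments among users with known
#' age. `n_users` counts users who sent at least one inbound message.
#'
#' @param x A [corpus()].
#' @return A `corpus_summary` (named list).
#' @export
summarize_corpus <- function(x) {
  stopifnot(inherits(x, "chat_corpus"))
  if (nrow(x$messages) == 0) {
    .chatmine_abort("Cannot summarize an empty corpus",
                    "chatmine_empty_input")
  }
  inb <- x$messages[x$messages$direction == "inbound", ]
  per_user <- as.integer(table(inb$user_id))
  senders <- unique(inb$user_id)
  known_sex <- x$users$sex[x$users$sex %in% c("female", "male")]
  known_age <- x$users$age_years[!is.na(x$users$age_years)]
  structure(list(
    n_users = length(senders),
    n_inbound = nrow(inb),
    n_outbound = sum(x$messages$direction == "outbound"),
    n_total = nrow(x$messages),
    inbound_per_user_mean = if (length(per_user)) mean(per_user) else NA_real_,
    inbound_per_user_median = if (length(per_user)) median(per_user) else NA_real_,
    inbound_per_user_sd = if (length(per_user) > 1) sd(per_user) else NA_real_,
    pct_female = if (length(known_sex))
      100 * mean(known_sex == "female") else NA_real_,
    age_mean = if (length(known_age)) mean(known_age) else NA_real_,
    age_sd = if (length(known_age) > 1) sd(known_age) else NA_real_
  ), class = "corpus_summary")
}

#' @export
print.corpus_summary <- function(x, ...) {
  cat("<corpus_summary>\n")
  cat(sprintf("  %d users sent %d messages; %d replies (total %d)\n",
              x$n_users, x$n_inbound, x$n_outbound, x$n_total))
  cat(sprintf("  inbound per user: median %.1f, mean %.2f (SD %.2f)\n",
              x$inbound_per_user_median, x$inbound_per_user_mean,
              x$inbound_per_user_sd))
  cat(sprintf("  %% female (known sex): %.1f; age %.1f (SD %.1f)\n",
              x$pct_female, x$age_mean, x$age_sd))
  invisible(x)
}

#' Privacy-preserving term-count export
#'
#' Drops rare terms before sharing tokenized counts: a term survives only if
#' its tally reaches `min_count` (default 3, i.e. terms appearing fewer than
#' three times are omitted). Guards against imperfect anonymization leaking
#' through rare tokens. Output is ordered by descending tally, ties broken
#' lexicographically.
#'
#' @param counts A term-count table with columns `term` and `n` (and any
#'   number of stratum columns, which are preserved).
#' @param min_count Minimum tally to retain (default 3).
#' @return The filtered, re-ordered term-count tibble.
#' @export
export_term_counts <- function(counts, min_count = 3) {
  if (!is.numeric(min_count) || length(min_count) != 1 || min_count < 1) {
    .chatmine_abort("min_count must be a single integer >= 1",
                    "chatmine_parameter_error")
  }
  counts <- as_tibble(counts)
  stopifnot(all(c("term", "n") %in% names(counts)))
  if (any(counts$n < 0)) {
    .chatmine_abort("term counts must be non-negative",
                    "chatmine_parameter_error")
  }
  out <- counts[counts$n >= min_count, , drop = FALSE]
  out[order(-out$n, out$term), , drop = FALSE]
}
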