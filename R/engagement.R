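# Per-user engagement patterns (how many messages sent vs replies received)
# and weekly message-volume series.

.pattern_levels <- c("single_in_single_out", "multi_in_single_out",
                     "multi_in_multi_out", "single_in_multi_out", "no_reply")

.engagement_pattern <- function(n_in, n_out) {
  ifelse(n_out == 0, "no_reply",
  ifelse(n_in == 1 & n_out == 1, "single_in_single_out",
  ifelse(n_in > 1 & n_out == 1, "multi_in_single_out",
  ifelse(n_in > 1 & n_out > 1, "multi_in_multi_out",
         "single_in_multi_out"))))
}

#' Classify per-user engagement patterns
#'
#' Every user with at least one inbound message is assigned exactly one of
#' five patterns from their inbound/outbound counts: (1,1) single message
#' and single reply; (>1,1) multiple messages, one reply; (>1,>1) multiple
#' messages and replies; (1,>1) one message, multiple replies; (>=1,0) no
#' reply. The partition is exhaustive, so the population shares always sum
#' to 100%.
#'
#' @param x A [corpus()]; outbound messages are attributed to users via
#'   their `user_id`.
#' @return A list with `records` (tibble `user_id`, `n_inbound`,
#'   `n_outbound`, `pattern`) and `shares` (tibble `pattern`, `n`, `pct`).
#' @export
classify_engagement <- function(x) {
  stopifnot(inherits(x, "chat_corpus"))
  m <- x$messages
  inb <- table(m$user_id[m$direction == "inbound"])
  if (length(inb) == 0) {
    .chatmine_abort("No inbound messages to classify",
                    "chatmine_empty_input")
  }
  out <- table(m$user_id[m$direction == "outbound"])
  users <- names(inb)
  n_in <- as.integer(inb)
  n_out <- as.integer(out[users])
  n_out[is.na(n_out)] <- 0L
  records <- tibble(
    user_id = users,
    n_inbound = n_in,
    n_outbound = n_out,
    pattern = .engagement_pattern(n_in, n_out)
  )
  tab <- table(factor(records$pattern, levels = .pattern_levels))
  shares <- tibble(pattern = names(tab), n = as.integer(tab),
                   pct = 100 * as.integer(tab) / sum(tab))
  list(records = records, shares = shares)
}

#' Male/female single-message rate ratio
#'
#' Ratio of the probability that a male user falls in the
#' single-in/single-out pattern to the same probability for a female user,
#' computed over users with known sex.
#'
#' @param records Engagement records from [classify_engagement()].
#' @param users A user table with `user_id` and `sex`.
#' @return A list: `ratio`, per-sex shares and denominators, and `defined`
#'   (`FALSE` when a denominator share is zero).
#' @export
single_message_rate_ratio <- function(records, users) {
  rec <- as_tibble(records)
  u <- as_tibble(users)
  sex <- u$sex[match(rec$user_id, u$user_id)]
  known <- sex %in% c("female", "male")
  if (!any(sex == "female", na.rm = TRUE) ||
      !any(sex == "male", na.rm = TRUE)) {
    .chatmine_abort("Need users of both known sexes",
                    "chatmine_empty_input")
  }
  single <- rec$pattern == "single_in_single_out"
  p_m <- mean(single[known & sex == "male"])
  p_f <- mean(single[known & sex == "female"])
  list(
    ratio = if (p_f > 0) p_m / p_f else NA_real_,
    male_share = p_m, female_share = p_f,
    n_male = sum(known & sex == "male"),
    n_female = sum(known & sex == "female"),
    defined = p_f > 0
  )
}

#' Weekly message volume
#'
#' Counts inbound and outbound messages per ISO-8601 calendar week
#' (iso_year, iso_week), zero-filled so that the weeks are contiguous over
#' the corpus span. ISO weeks are unambiguous across year boundaries (a late
#' December day can fall in week 1 of the following ISO year).
#'
#' @param x A [corpus()].
#' @return A tibble `iso_year`, `iso_week`, `n_inbound`, `n_outbound`.
#' @export
weekly_volume <- function(x) {
  stopifnot(inherits(x, "chat_corpus"))
  m <- x$messages
  if (nrow(m) == 0) {
    return(tibble(iso_year = integer(), iso_week = integer(),
                  n_inbound = integer(), n_outbound = integer()))
  }
  wk_start <- floor_date(as.Date(m$timestamp, tz = "UTC"), "week",
                         week_start = 1)
  span <- seq(min(wk_start), max(wk_start), by = "7 days")
  counts <- tibble(wk = wk_start, direction = m$direction) |>
    count(.data$wk, .data$direction) |>
    pivot_wider(names_from = "direction", values_from = "n",
                values_fill = 0L)
  for (col in c("inbound", "outbound")) {
    if (!col %in% names(counts)) counts[[col]] <- 0L
  }
  full <- tibble(wk = span) |>
    left_join(counts, by = "wk") |>
    mutate(
      inbound = replace_na(.data$inbound, 0L),
      outbound = replace_na(.data$outbound, 0L)
    )
  tibble(
    iso_year = isoyear(full$wk),
    iso_week = isoweek(full$wk),
    n_inbound = as.integer(full$inbound),
    n_outbound = as.integer(full$outbound)
  )
}
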