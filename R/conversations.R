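# Conversation segmentation (inactivity-gap rule) and coded-conversation
# analytics: conversation descriptives by demographic stratum, the
# distribution of user question/request categories, and topic co-occurrence
# in multiple-topic conversations.

#' Segment user-agent message streams into conversations
#'
#' A reproducible proxy for manual conversation delimitation: within each
#' user's time-ordered stream (both directions), a new conversation starts
#' whenever the gap between consecutive messages exceeds `gap_hours`
#' (default 24). Every message belongs to exactly one conversation, so
#' message counts are conserved, and shrinking the gap threshold can only
#' split conversations, never merge them.
#'
#' @param x A [corpus()].
#' @param gap_hours Inactivity gap (hours) that opens a new conversation;
#'   `Inf` yields one conversation per user.
#' @return A list with `conversations` (tibble `conversation_id`,
#'   `user_id`, `n_user_messages`, `n_agent_messages`, `n_messages`,
#'   `start`, `end`) and `assignments` (tibble `message_id`,
#'   `conversation_id`).
#' @export
segment_conversations <- function(x, gap_hours = 24) {
  stopifnot(inherits(x, "chat_corpus"), gap_hours > 0)
  m <- x$messages |> arrange(.data$user_id, .data$timestamp, .data$message_id)
  if (nrow(m) == 0) {
    return(list(conversations = tibble(), assignments = tibble()))
  }
  gap_secs <- gap_hours * 3600
  new_user <- c(TRUE, m$user_id[-1] != m$user_id[-nrow(m)])
  dt <- c(0, as.numeric(difftime(m$timestamp[-1], m$timestamp[-nrow(m)],
                                 units = "secs")))
  breaks <- new_user | (is.finite(gap_secs) & dt > gap_secs)
  conv_seq <- ave(as.integer(breaks), m$user_id, FUN = cumsum)
  conv_id <- sprintf("%s/c%03d", m$user_id, conv_seq)
  convs <- tibble(conversation_id = conv_id,
                  user_id = m$user_id,
                  direction = m$direction,
                  timestamp = m$timestamp) |>
    group_by(.data$conversation_id, .data$user_id) |>
    summarise(
      n_user_messages = sum(.data$direction == "inbound"),
      n_agent_messages = sum(.data$direction == "outbound"),
      n_messages = n(),
      start = min(.data$timestamp),
      end = max(.data$timestamp),
      .groups = "drop"
    )
  list(
    conversations = convs,
    assignments = tibble(message_id = m$message_id,
                         conversation_id = conv_id)
  )
}

#' Sample high-engagement users
#'
#' Reusable sampler for the coded-conversation exercise: users who sent at
#' least `min_messages` inbound messages in a given language within a single
#' ISO calendar week, sampled `per_sex` per sex.
#'
#' @param x A [corpus()] with labeled inbound messages.
#' @param min_messages Weekly inbound threshold (default 7).
#' @param per_sex Users sampled per sex (default 50).
#' @param language Language filter (default `"en"`).
#' @param seed Sampling seed.
#' @return Character vector of sampled user ids.
#' @export
sample_high_engagement <- function(x, min_messages = 7, per_sex = 50,
                                   language = "en", seed = 1) {
  stopifnot(inherits(x, "chat_corpus"))
  m <- x$messages
  keep <- m$direction == "inbound" & !is.na(m$language) &
    m$language == language
  if (!any(keep)) return(character(0))
  wk <- .iso_week_key(m$timestamp[keep])
  weekly <- tibble(user = m$user_id[keep], wk = wk) |>
    count(.data$user, .data$wk)
  eligible <- unique(weekly$user[weekly$n >= min_messages])
  sex <- x$users$sex[match(eligible, x$users$user_id)]
  .with_local_seed(seed, {
    unlist(lapply(c("female", "male"), function(s) {
      pool <- eligible[sex == s]
      sample(pool, min(per_sex, length(pool)))
    }), use.names = FALSE)
  })
}

#' Conversation descriptives by stratum
#'
#' The coded-conversation summary table: per stratum (all users, each sex,
#' and sex-by-age-band), the number of users, messages and conversations,
#' and the mean (SD) of conversations per person, messages per conversation
#' and topics per conversation.
#'
#' @param conversations Conversation table from [segment_conversations()]
#'   (or an externally coded table with the same columns).
#' @param users User table with `user_id`, `sex`, `age_years`.
#' @param topics Optional coded-topic tibble `conversation_id`, `topic`.
#' @param bands Age bands, see [default_age_bands()].
#' @return A tibble with one row per stratum.
#' @export
conversation_stats <- function(conversations, users, topics = NULL,
                               bands = default_age_bands()) {
  convs <- as_tibble(conversations)
  u <- as_tibble(users)
  sex <- u$sex[match(convs$user_id, u$user_id)]
  sex <- ifelse(sex %in% c("female", "male"), sex, "missing")
  band <- age_band(u$age_years[match(convs$user_id, u$user_id)], bands)
  if (!is.null(topics)) {
    topics <- as_tibble(topics)
    n_topics <- topics |> count(.data$conversation_id)
    convs$n_topics <- n_topics$n[match(convs$conversation_id,
                                       n_topics$conversation_id)]
    convs$n_topics[is.na(convs$n_topics)] <- 0L
  } else {
    convs$n_topics <- NA_integer_
  }

  one_group <- function(sel, label) {
    cc <- convs[sel, ]
    if (nrow(cc) == 0) return(NULL)
    per_person <- as.integer(table(cc$user_id))
    tibble(
      group = label,
      n_users = length(unique(cc$user_id)),
      n_messages = sum(cc$n_messages),
      n_conversations = nrow(cc),
      convos_per_person_mean = mean(per_person),
      convos_per_person_sd = if (length(per_person) > 1) sd(per_person)
        else NA_real_,
      messages_per_convo_mean = mean(cc$n_messages),
      messages_per_convo_sd = if (nrow(cc) > 1) sd(cc$n_messages)
        else NA_real_,
      topics_per_convo_mean = mean(cc$n_topics),
      topics_per_convo_sd = if (nrow(cc) > 1) sd(cc$n_topics) else NA_real_
    )
  }

  rows <- list(one_group(rep(TRUE, nrow(convs)), "All"))
  for (s in c("male", "female")) {
    lab <- if (s == "male") "Men" else "Women"
    rows <- c(rows, list(one_group(sex == s, lab)))
    for (b in bands$labels) {
      rows <- c(rows, list(one_group(sex == s & band == b,
                                     paste0(lab, ", ", b))))
    }
  }
  bind_rows(rows)
}

#' Distribution of user question/request categories
#'
#' Shares over the six question categories (1 factual-causes, 2
#' factual-concepts, 3 advice, 4 access, 5 symptoms/diagnosis, 6 other)
#' among messages coded as questions/requests; shares sum to 100%. The myth
#' share is computed among information requests (categories 1-2 combined).
#'
#' @param message_codes Tibble with columns `code` (`question_request`,
#'   `response`, `greeting`, `other`), `category` (1-6, only for
#'   questions), `myth_flag` (logical).
#' @return A list: `categories` (tibble `category`, `n`, `pct`),
#'   `pct_question_messages` (questions among all coded messages),
#'   `n_information_requests` and `pct_myth` (among categories 1-2).
#' @export
question_distribution <- function(message_codes) {
  codes <- as_tibble(message_codes)
  stopifnot("code" %in% names(codes))
  q <- codes[codes$code == "question_request", ]
  if (nrow(q) == 0) {
    .chatmine_abort("No coded question/request messages",
                    "chatmine_empty_input")
  }
  if (anyNA(q$category)) {
    .chatmine_abort("Questions must carry a category 1-6",
                    "chatmine_schema_error")
  }
  tab <- table(factor(q$category, levels = 1:6))
  info <- q$category %in% 1:2
  myth <- if (!"myth_flag" %in% names(q)) rep(FALSE, nrow(q)) else
    replace_na(q$myth_flag, FALSE)
  list(
    categories = tibble(category = as.integer(names(tab)),
                        n = as.integer(tab),
                        pct = 100 * as.integer(tab) / sum(tab)),
    pct_question_messages = 100 * nrow(q) / nrow(codes),
    n_information_requests = sum(info),
    pct_myth = if (any(info)) 100 * sum(myth & info) / sum(info)
      else NA_real_
  )
}

#' Topic co-occurrence in multiple-topic conversations
#'
#' For each conversation coded with two or more topics, every unordered
#' topic pair is incremented once; single-topic conversations are excluded.
#' The total count therefore equals the sum of C(k, 2) over multi-topic
#' conversations with k topics.
#'
#' @param topics Tibble `conversation_id`, `topic`.
#' @return A tibble `topic_a`, `topic_b` (`topic_a < topic_b`), `n`.
#' @export
topic_cooccurrence <- function(topics) {
  topics <- as_tibble(topics) |>
    distinct(.data$conversation_id, .data$topic)
  per_conv <- split(topics$topic, topics$conversation_id)
  per_conv <- per_conv[lengths(per_conv) >= 2]
  if (length(per_conv) == 0) {
    return(tibble(topic_a = character(), topic_b = character(),
                  n = integer()))
  }
  pairs <- do.call(rbind, lapply(per_conv, function(tp) {
    t(combn(sort(tp), 2))
  }))
  key <- paste(pairs[, 1], pairs[, 2], sep = "\x1f")
  tab <- table(key)
  parts <- str_split(names(tab), "\x1f", n = 2, simplify = TRUE)
  out <- tibble(topic_a = parts[, 1], topic_b = parts[, 2],
                n = as.integer(tab))
  out[order(-out$n, out$topic_a, out$topic_b), ]
}
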