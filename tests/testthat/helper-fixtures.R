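# Shared fixture builders and independent oracles used across the suite.

ts_utc <- function(x) as.POSIXct(x, tz = "UTC")

make_messages <- function(user_id, direction, timestamp, body = NA,
                          language = NA, agent_id = NA) {
  n <- max(length(user_id), length(direction), length(timestamp))
  tibble::tibble(
    message_id = sprintf("m%03d", seq_len(n)),
    user_id = rep_len(user_id, n),
    direction = rep_len(direction, n),
    timestamp = rep_len(ts_utc(timestamp), n),
    body = rep_len(as.character(body), n),
    language = rep_len(as.character(language), n),
    agent_id = rep_len(as.character(agent_id), n)
  )
}

make_users <- function(user_id, sex = "unknown", age_years = NA,
                       language_preference = "unknown") {
  tibble::tibble(
    user_id = user_id,
    sex = rep_len(sex, length(user_id)),
    age_years = rep_len(as.numeric(age_years), length(user_id)),
    language_preference = rep_len(language_preference, length(user_id))
  )
}

# tiny two-language model over disjoint alphabets
tiny_model <- function() {
  train_language_model(
    c("abab baba abba baab ab ba abab", "cdcd dcdc cddc dccd cd dc cdcd"),
    c("en", "sw")
  )
}

# Independent oracle for the greedy preemption scan: enumerate every tiling
# of the stream into key-bigram pairs and singles, then pick the tiling
# whose segment-length choice vector is lexicographically maximal (a bigram
# taken at the leftmost opportunity beats any tiling that declines it).
enumerate_tilings <- function(tokens, keys) {
  if (length(tokens) == 0) return(list(list(emit = character(0),
                                            segs = integer(0))))
  out <- list()
  if (length(tokens) >= 2 &&
      paste(tokens[1], tokens[2]) %in% keys) {
    for (rest in enumerate_tilings(tokens[-(1:2)], keys)) {
      out <- c(out, list(list(
        emit = c(paste(tokens[1], tokens[2]), rest$emit),
        segs = c(2L, rest$segs))))
    }
  }
  for (rest in enumerate_tilings(tokens[-1], keys)) {
    out <- c(out, list(list(emit = c(tokens[1], rest$emit),
                            segs = c(1L, rest$segs))))
  }
  out
}

oracle_preempt <- function(tokens, keys) {
  tilings <- enumerate_tilings(tokens, keys)
  best <- tilings[[1]]
  for (t in tilings[-1]) {
    a <- t$segs
    b <- best$segs
    len <- min(length(a), length(b))
    cmp <- which(a[seq_len(len)] != b[seq_len(len)])
    if (length(cmp) > 0 && a[cmp[1]] > b[cmp[1]]) best <- t
  }
  best$emit
}

# Independent oracle for double agreement: for each prefix length, check
# whether any label has two distinct raters; the final label is the label of
# the event completing the earliest such prefix.
oracle_double_agreement <- function(rater, label, idx) {
  ord <- order(idx)
  rater <- rater[ord]; label <- label[ord]; idx <- idx[ord]
  for (t in seq_along(label)) {
    pre <- seq_len(t)
    n_raters <- tapply(rater[pre], label[pre],
                       function(r) length(unique(r)))
    if (any(n_raters >= 2)) {
      return(list(final = label[t], n = idx[t], resolved = TRUE))
    }
  }
  list(final = NA_character_, n = idx[length(idx)], resolved = FALSE)
}

random_event_sequence <- function(n_events = 6, n_raters = 3,
                                  n_labels = 3) {
  tibble::tibble(
    question_id = "q1",
    rater_id = sample(sprintf("r%d", seq_len(n_raters)), n_events, TRUE),
    intent_label = sample(LETTERS[seq_len(n_labels)], n_events, TRUE),
    sequence_index = seq_len(n_events)
  )
}
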