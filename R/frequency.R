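# Bigram-preemption tallying: a small set of key bigrams ("family planning",
# "side effects", ...) is counted as single terms, consuming both component
# tokens, while tokens outside a key bigram are counted individually.

#' Default age bands
#'
#' Cohort bands used by the stratified analyses: 15-19, 20-24, 25-35, 36+.
#'
#' @return A band-definition list (breaks and labels).
#' @export
default_age_bands <- function() {
  list(breaks = c(15, 20, 25, 36, Inf),
       labels = c("15-19", "20-24", "25-35", "36+"))
}

#' Assign ages to bands
#'
#' @param age Numeric ages (`NA` = unknown).
#' @param bands A band definition, see [default_age_bands()].
#' @return Character band labels; `"missing"` for unknown or out-of-range.
#' @export
age_band <- function(age, bands = default_age_bands()) {
  lab <- as.character(cut(age, breaks = bands$breaks, labels = bands$labels,
                          right = FALSE, include.lowest = TRUE))
  lab[is.na(lab)] <- "missing"
  lab
}

.bigram_key <- function(a, b) paste(a, b)

#' Packaged default key-bigram set
#'
#' The shipped default set of key bigrams (pairs tallied as single terms),
#' covering the common reproductive-health collocations; the set is
#' configuration, and [discover_key_bigrams()] is the preferred way to
#' derive one from a corpus.
#'
#' @return Character vector of bigrams rendered `"a b"`.
#' @export
default_key_bigrams <- function() {
  tab <- read_csv(system.file("extdata", "key_bigrams.csv",
                              package = "chatmine"),
                  col_types = cols(.default = col_character()),
                  progress = FALSE)
  tolower(tab$bigram)
}

#' Count adjacent token pairs
#'
#' Raw within-message adjacency counts of consecutive token pairs, before
#' any preemption; the input feeding both key-bigram discovery and the
#' directed bigram network.
#'
#' @param streams A list of token vectors (one per message).
#' @return A tibble `term` (pair rendered `"a b"`), `n`, ordered by
#'   descending count then term.
#' @export
adjacent_pair_counts <- function(streams) {
  pairs <- unlist(lapply(streams, function(s) {
    if (length(s) < 2) return(character(0))
    .bigram_key(s[-length(s)], s[-1])
  }), use.names = FALSE)
  if (length(pairs) == 0) return(tibble(term = character(), n = integer()))
  tab <- table(pairs)
  out <- tibble(term = names(tab), n = as.integer(tab))
  out[order(-out$n, out$term), ]
}

#' Discover the most common key bigrams
#'
#' The `top_k` most frequent adjacent pairs with count at least `min_count`,
#' excluding any pair containing a stop word. Ordering (and the cut at rank
#' `top_k` under ties) is deterministic: count descending, then
#' lexicographic.
#'
#' @param streams Normalized (pre-stop-filter) per-message token streams.
#' @param top_k Number of pairs to keep.
#' @param min_count Minimum adjacency count.
#' @param stoplists Stop lists (see [filter_stopwords()]).
#' @return Character vector of key bigrams rendered `"a b"`.
#' @export
discover_key_bigrams <- function(streams, top_k = 25, min_count = 2,
                                 stoplists = NULL) {
  counts <- adjacent_pair_counts(streams)
  if (nrow(counts) == 0) return(character(0))
  stops <- .stop_words(stoplists)
  if (length(stops) > 0) {
    parts <- str_split(counts$term, " ", n = 2, simplify = TRUE)
    counts <- counts[!(parts[, 1] %in% stops | parts[, 2] %in% stops), ]
  }
  counts <- counts[counts$n >= min_count, ]
  head(counts$term, top_k)
}

# Greedy left-to-right preemption scan of one stream: when the pair at the
# cursor is a key bigram, emit the bigram term and advance two positions,
# else emit the single token and advance one. Non-overlapping by
# construction.
.preempt_scan <- function(tokens, key_set) {
  n <- length(tokens)
  if (n == 0) return(character(0))
  out <- character(n)
  k <- 0L
  i <- 1L
  while (i <= n) {
    if (i < n && .bigram_key(tokens[i], tokens[i + 1]) %in% key_set) {
      k <- k + 1L
      out[k] <- .bigram_key(tokens[i], tokens[i + 1])
      i <- i + 2L
    } else {
      k <- k + 1L
      out[k] <- tokens[i]
      i <- i + 1L
    }
  }
  out[seq_len(k)]
}

#' Tally terms with bigram preemption
#'
#' Scans each message greedily left to right: a key-bigram occurrence is
#' tallied as the bigram term and consumes both tokens; every other token is
#' tallied individually. Single tokens (never the key bigrams, which by
#' construction contain no stop words) are then stop-word filtered, and
#' counts are aggregated across messages.
#'
#' @param streams Normalized per-message token streams.
#' @param key_bigrams Character vector of key bigrams (`"a b"`), e.g. from
#'   [discover_key_bigrams()].
#' @param stoplists Stop lists applied to single tokens.
#' @return A tibble `term`, `n` ordered by descending count then term.
#' @export
tally_with_preemption <- function(streams, key_bigrams = character(0),
                                  stoplists = NULL) {
  emitted <- lapply(streams, .preempt_scan, key_set = key_bigrams)
  stops <- .stop_words(stoplists)
  flat <- unlist(emitted, use.names = FALSE)
  if (length(flat) == 0) return(tibble(term = character(), n = integer()))
  is_bigram <- flat %in% key_bigrams
  keep <- is_bigram | !flat %in% stops
  flat <- flat[keep]
  if (length(flat) == 0) return(tibble(term = character(), n = integer()))
  tab <- table(flat)
  out <- tibble(term = names(tab), n = as.integer(tab))
  out[order(-out$n, out$term), ]
}

#' Stratified term counts
#'
#' Runs the preemption tally separately by demographic stratum. Streams must
#' be named by `message_id` (as produced when normalizing a corpus's inbound
#' messages); strata are resolved through the corpus's user table. Users
#' with an unknown stratum value are collected under `"missing"` strata so
#' the stratified counts always marginalize exactly to the pooled counts.
#'
#' @param x A [corpus()].
#' @param streams Named list (by `message_id`) of normalized token streams.
#' @param strata One of `"none"`, `"sex"`, `"sex_age"`, `"language"`.
#' @param key_bigrams,stoplists Passed to [tally_with_preemption()].
#' @param bands Age bands for `"sex_age"`, see [default_age_bands()].
#' @return A tibble `stratum`, `term`, `n`.
#' @export
stratified_counts <- function(x, streams, strata = "none",
                              key_bigrams = character(0), stoplists = NULL,
                              bands = default_age_bands()) {
  stopifnot(inherits(x, "chat_corpus"))
  if (!strata %in% c("none", "sex", "sex_age", "language")) {
    .chatmine_abort("strata must be one of none/sex/sex_age/language",
                    "chatmine_parameter_error")
  }
  ids <- names(streams)
  if (is.null(ids)) {
    .chatmine_abort("streams must be named by message_id",
                    "chatmine_parameter_error")
  }
  m <- x$messages[match(ids, x$messages$message_id), ]
  u <- x$users[match(m$user_id, x$users$user_id), ]
  stratum <- switch(strata,
    none = rep("all", length(streams)),
    sex = ifelse(u$sex %in% c("female", "male"), u$sex, "missing"),
    sex_age = paste(
      ifelse(u$sex %in% c("female", "male"), u$sex, "missing"),
      age_band(u$age_years, bands)
    ),
    language = ifelse(is.na(m$language), "und", m$language)
  )
  out <- lapply(split(streams, stratum), tally_with_preemption,
                key_bigrams = key_bigrams, stoplists = stoplists)
  bind_rows(imap(out, function(tab, s) {
    if (nrow(tab) == 0) return(tibble(stratum = character(),
                                      term = character(), n = integer()))
    tibble(stratum = s, term = tab$term, n = tab$n)
  }))
}

#' Forced ranking of terms within strata
#'
#' Ranks terms 1..N within each stratum by descending count with
#' lexicographic tie-breaking, so no ties are awarded: each rank in a
#' stratum is used exactly once.
#'
#' @param counts_by_stratum A tibble `stratum`, `term`, `n` (a plain
#'   `term`/`n` table is treated as one stratum `"all"`).
#' @param top_n Optional cut: keep only ranks `<= top_n`.
#' @return A tibble `stratum`, `term`, `n`, `rank`.
#' @export
forced_rank <- function(counts_by_stratum, top_n = NULL) {
  counts <- as_tibble(counts_by_stratum)
  if (!"stratum" %in% names(counts)) counts$stratum <- "all"
  stopifnot(all(c("term", "n") %in% names(counts)))
  out <- counts |>
    group_by(.data$stratum) |>
    arrange(desc(.data$n), .data$term, .by_group = TRUE) |>
    mutate(rank = row_number()) |>
    ungroup()
  if (!is.null(top_n)) out <- out[out$rank <= top_n, ]
  out[, c("stratum", "term", "n", "rank")]
}
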