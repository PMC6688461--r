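# Word-association statistics: the directed bigram network (edges between
# temporally ordered adjacent words) and pairwise phi correlations between
# word-presence indicators across sections (by default, one section per
# user's pooled inbound messages).

#' Directed bigram network edges
#'
#' Filters raw adjacency counts into an edge list: the edge `from -> to`
#' records how often `from` immediately preceded `to`. Pairs containing a
#' stop word are excluded; the filter never increases a count. Ordering is
#' deterministic (count descending, then from/to).
#'
#' @param pair_counts A tibble `term` (pair rendered `"a b"`), `n` from
#'   [adjacent_pair_counts()].
#' @param min_count Minimum adjacency count to keep.
#' @param stoplists Stop lists; pairs containing a stop word are dropped.
#' @return A tibble `from`, `to`, `n`.
#' @export
bigram_edges <- function(pair_counts, min_count = 3, stoplists = NULL) {
  counts <- as_tibble(pair_counts)
  stopifnot(all(c("term", "n") %in% names(counts)))
  if (nrow(counts) == 0) {
    return(tibble(from = character(), to = character(), n = integer()))
  }
  parts <- str_split(counts$term, " ", n = 2, simplify = TRUE)
  out <- tibble(from = parts[, 1], to = parts[, 2], n = counts$n)
  stops <- .stop_words(stoplists)
  if (length(stops) > 0) {
    out <- out[!(out$from %in% stops | out$to %in% stops), ]
  }
  out <- out[out$n >= min_count, ]
  out[order(-out$n, out$from, out$to), ]
}

#' Pairwise phi correlations between terms across sections
#'
#' For every retained pair of terms, builds the 2x2 presence table over
#' sections (n11 both present, n10 only the first, n01 only the second, n00
#' neither) and computes
#' \deqn{\phi = \frac{n_{11} n_{00} - n_{10} n_{01}}{
#'   \sqrt{(n_{11}+n_{10})(n_{01}+n_{00})(n_{11}+n_{01})(n_{10}+n_{00})}}}
#' which equals the Pearson correlation of the two binary presence
#' indicators. Terms occurring in fewer than `min_section_occurrences`
#' sections are excluded (rare terms give unstable phi); pairs with a zero
#' denominator (a term present in all or in no sections) are omitted.
#'
#' @param section_terms A tibble `section`, `term` (one row per distinct
#'   term occurrence in a section), or a named list of per-section term
#'   vectors.
#' @param min_section_occurrences Minimum number of sections a term must
#'   appear in (default 20).
#' @param sections Optional full universe of section ids; sections with no
#'   (retained) terms still count as joint absences. Defaults to the
#'   sections observed in `section_terms`.
#' @return A tibble `term_a`, `term_b` (`term_a < term_b`), `phi`,
#'   `n_sections`, ordered by descending phi.
#' @export
pairwise_phi <- function(section_terms, min_section_occurrences = 20,
                         sections = NULL) {
  if (is.list(section_terms) && !is.data.frame(section_terms)) {
    section_terms <- tibble(
      section = rep(names(section_terms), lengths(section_terms)),
      term = unlist(section_terms, use.names = FALSE)
    )
  }
  section_terms <- as_tibble(section_terms)
  stopifnot(all(c("section", "term") %in% names(section_terms)))
  section_terms <- distinct(section_terms, .data$section, .data$term)
  if (is.null(sections)) {
    sections <- unique(section_terms$section)
  } else {
    sections <- unique(as.character(sections))
    if (!all(section_terms$section %in% sections)) {
      .chatmine_abort("sections must cover every observed section",
                      "chatmine_parameter_error")
    }
  }
  n <- length(sections)
  if (n < 2) {
    .chatmine_abort("pairwise_phi needs at least 2 sections",
                    "chatmine_empty_input")
  }
  occ <- table(section_terms$term)
  terms <- sort(names(occ)[occ >= min_section_occurrences])
  if (length(terms) < 2) {
    return(tibble(term_a = character(), term_b = character(),
                  phi = numeric(), n_sections = integer()))
  }
  kept <- section_terms[section_terms$term %in% terms, ]
  M <- matrix(0L, nrow = n, ncol = length(terms),
              dimnames = list(sections, terms))
  M[cbind(match(kept$section, sections), match(kept$term, terms))] <- 1L

  n11 <- crossprod(M)                       # both present
  present <- colSums(M)
  n10 <- outer(present, rep(1, length(terms))) - n11  # a only
  n01 <- t(n10)                             # b only
  n00 <- n - n11 - n10 - n01                # neither
  denom <- sqrt((n11 + n10) * (n01 + n00) * (n11 + n01) * (n10 + n00))
  phi <- (n11 * n00 - n10 * n01) / denom

  ut <- which(upper.tri(phi), arr.ind = TRUE)
  out <- tibble(
    term_a = terms[ut[, 1]],
    term_b = terms[ut[, 2]],
    phi = phi[ut],
    n_sections = n
  )
  out <- out[is.finite(out$phi), ]
  out[order(-out$phi, out$term_a, out$term_b), ]
}

#' Section/term presence from a corpus
#'
#' Builds the `section`, `term` table consumed by [pairwise_phi()], with one
#' section per user: all of a user's inbound messages (optionally restricted
#' to one language) pooled, since co-occurrence is assessed within a user's
#' conversation regardless of message boundaries.
#'
#' @param x A [corpus()].
#' @param streams Named list (by `message_id`) of normalized token streams.
#' @param language Optional language filter (e.g. `"en"`).
#' @param stoplists Stop lists removed from the streams first.
#' @return A tibble `section` (user id), `term`.
#' @export
user_term_sections <- function(x, streams, language = NULL,
                               stoplists = NULL) {
  stopifnot(inherits(x, "chat_corpus"))
  ids <- names(streams)
  m <- x$messages[match(ids, x$messages$message_id), ]
  keep <- m$direction == "inbound"
  if (!is.null(language)) keep <- keep & !is.na(m$language) &
      m$language == language
  streams <- filter_stopwords(streams[keep], stoplists)
  tibble(
    section = rep(m$user_id[keep], lengths(streams)),
    term = unlist(streams, use.names = FALSE)
  ) |> distinct()
}
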