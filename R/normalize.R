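# Token normalization: tokenize -> spell-correct -> lemmatize -> collapse
# synonyms -> (bigram preemption, frequency module) -> stop-word filter.
# Each stage is a pure, idempotent-where-stated transformation on token
# streams, so counts are reproducible and order is preserved.

#' Tokenize message bodies
#'
#' Lowercases, removes apostrophes joining the halves (`"don't"` ->
#' `"dont"`), strips punctuation and returns maximal runs of letters
#' (Unicode-aware). Digits are dropped in the default `"letters"` mode; the
#' `"alnum"` mode keeps alphanumeric tokens that contain at least one letter
#' (so brand/price tokens like `"p2"` or `"100ksh"` survive), while
#' standalone numbers are dropped in both modes.
#'
#' @param texts Character vector of message bodies.
#' @param mode `"letters"` (default) or `"alnum"`.
#' @return A list of character vectors (one ordered token stream per input;
#'   empty for empty or non-alphabetic input).
#' @export
tokenize <- function(texts, mode = c("letters", "alnum")) {
  mode <- match.arg(mode)
  x <- tolower(ifelse(is.na(texts), "", texts))
  x <- str_remove_all(x, "['’]")
  pattern <- if (mode == "letters") "\\p{L}+" else
    "[\\p{L}\\p{N}]*\\p{L}[\\p{L}\\p{N}]*"
  str_extract_all(x, pattern)
}

#' Read a stop-word list
#'
#' CSV with columns `word`, `language` and optionally `source`. Entries are
#' lowercased; internal whitespace is an error.
#'
#' @param path File path.
#' @return A tibble of class `stoplist`.
#' @export
read_stoplist <- function(path) {
  sl <- read_csv(path, col_types = cols(.default = col_character()),
                 progress = FALSE)
  stopifnot(all(c("word", "language") %in% names(sl)))
  if (!"source" %in% names(sl)) sl$source <- "custom"
  sl$word <- tolower(sl$word)
  if (any(grepl("\\s", sl$word))) {
    .chatmine_abort("Stop words must not contain whitespace",
                    "chatmine_config_error")
  }
  class(sl) <- c("stoplist", class(sl))
  sl
}

.stop_words <- function(stoplists) {
  if (is.null(stoplists)) return(character(0))
  if (is.character(stoplists)) return(unique(tolower(stoplists)))
  if (is.data.frame(stoplists)) return(unique(tolower(stoplists$word)))
  unique(tolower(unlist(lapply(stoplists, .stop_words), use.names = FALSE)))
}

#' Filter stop words from token streams
#'
#' Removes tokens present in any supplied stop list; the order of the
#' surviving tokens is preserved.
#'
#' @param streams A list of token vectors (or a single character vector).
#' @param stoplists A character vector, a [read_stoplist()] table, or a list
#'   of either.
#' @return Streams with stop words removed (same container shape as input).
#' @export
filter_stopwords <- function(streams, stoplists) {
  words <- .stop_words(stoplists)
  if (is.character(streams)) return(streams[!streams %in% words])
  lapply(streams, function(s) s[!s %in% words])
}

#' Spell-correction policy
#'
#' Suggestions are accepted only for tokens that appear fewer than
#' `max_count_exclusive` times in the corpus (default 4: counts 1-3 are
#' eligible, count 4 is not) and only for the enabled languages (default
#' English only; Swahili suggestions are never accepted).
#'
#' @param max_count_exclusive Corpus count at and above which a token is
#'   never corrected.
#' @param languages_enabled Languages whose tokens may be corrected.
#' @return A `spell_policy`.
#' @export
spell_policy <- function(max_count_exclusive = 4, languages_enabled = "en") {
  if (max_count_exclusive < 1) {
    .chatmine_abort("max_count_exclusive must be >= 1",
                    "chatmine_parameter_error")
  }
  structure(list(max_count_exclusive = max_count_exclusive,
                 languages_enabled = languages_enabled),
            class = "spell_policy")
}

#' Offline edit-distance suggestion source
#'
#' Returns a suggester function: for a token absent from the word list it
#' proposes the lexicographically first in-list word at edit distance 1 (no
#' suggestion otherwise); in-list tokens get no suggestion. A stand-in for
#' an external spell engine with identical plug-in shape (token ->
#' character vector of suggestions).
#'
#' @param wordlist Character vector of known-good words; defaults to the
#'   packaged English word list.
#' @return A function `token -> character vector` (possibly empty).
#' @export
edit_distance_suggester <- function(wordlist = NULL) {
  if (is.null(wordlist)) {
    wordlist <- readLines(
      system.file("extdata", "wordlist_en.txt", package = "chatmine"),
      encoding = "UTF-8", warn = FALSE)
  }
  wordlist <- sort(unique(tolower(wordlist[nzchar(wordlist)])))
  function(token) {
    token <- tolower(token)
    if (token %in% wordlist) return(character(0))
    # cheap length pre-filter before the edit-distance pass
    cand <- wordlist[abs(nchar(wordlist) - nchar(token)) <= 1]
    if (length(cand) == 0) return(character(0))
    d <- adist(token, cand)[1, ]
    cand[d == 1]
  }
}

#' Build a corpus-level spell-correction map
#'
#' Applies the frequency-thresholded policy: a token maps to its first
#' suggestion iff its corpus count is below `policy$max_count_exclusive`,
#' the token's language is enabled, and the suggester returns at least one
#' suggestion; every other token maps to itself. The counts must be computed
#' over the full corpus before any correction.
#'
#' @param corpus_token_counts Tibble with columns `term`, `n`.
#' @param suggester A function `token -> character vector of suggestions`,
#'   e.g. [edit_distance_suggester()].
#' @param policy A [spell_policy()].
#' @param language Language context of the counts (default `"en"`).
#' @return A named character vector mapping token -> replacement.
#' @export
build_correction_map <- function(corpus_token_counts, suggester,
                                 policy = spell_policy(), language = "en") {
  stopifnot(inherits(policy, "spell_policy"))
  counts <- as_tibble(corpus_token_counts)
  stopifnot(all(c("term", "n") %in% names(counts)))
  map <- setNames(counts$term, counts$term)
  if (!language %in% policy$languages_enabled) return(map)
  eligible <- counts$term[counts$n < policy$max_count_exclusive]
  for (tok in eligible) {
    sugg <- suggester(tok)
    if (length(sugg) > 0) map[[tok]] <- sugg[[1]]
  }
  map
}

#' Apply a token substitution map
#'
#' Pure substitution: tokens present in the map are replaced, all others
#' pass through; stream lengths are conserved.
#'
#' @param streams A list of token vectors (or a single character vector).
#' @param map Named character vector (token -> replacement).
#' @return Substituted streams.
#' @export
apply_token_map <- function(streams, map) {
  sub_one <- function(s) {
    hit <- s %in% names(map)
    s[hit] <- unname(map[s[hit]])
    s
  }
  if (is.character(streams)) return(sub_one(streams))
  lapply(streams, sub_one)
}

#' Read a lemma table
#'
#' Two-column CSV `inflected, lemma`. The table is validated to be
#' idempotent: the lemma of a lemma must be itself.
#'
#' @param path File path.
#' @return A named character vector (inflected -> lemma).
#' @export
read_lemma_table <- function(path) {
  tab <- read_csv(path, col_types = cols(.default = col_character()),
                  progress = FALSE)
  stopifnot(all(c("inflected", "lemma") %in% names(tab)))
  map <- setNames(tolower(tab$lemma), tolower(tab$inflected))
  chained <- names(map)[map %in% names(map) & unname(map[map]) != unname(map)]
  if (length(chained) > 0) {
    .chatmine_abort(
      paste0("Lemma table is not idempotent at: ",
             paste(head(chained, 5), collapse = ", ")),
      "chatmine_config_error"
    )
  }
  map
}

#' Lemmatize English token streams by table lookup
#'
#' Tokens found in the table are replaced by their lemma; unknown tokens
#' pass through unchanged. Length-preserving and idempotent.
#'
#' @param streams A list of token vectors (or a single character vector).
#' @param table A named vector from [read_lemma_table()].
#' @return Lemmatized streams.
#' @export
lemmatize <- function(streams, table) {
  apply_token_map(streams, table)
}

#' Read a synonym map
#'
#' CSV with columns `variant`, `canonical`. Chains and cycles (a canonical
#' label that is itself mapped elsewhere) are a configuration error, which
#' guarantees idempotent application.
#'
#' @param path File path.
#' @return A named character vector (variant -> canonical).
#' @export
read_synonym_map <- function(path) {
  tab <- read_csv(path, col_types = cols(.default = col_character()),
                  progress = FALSE)
  stopifnot(all(c("variant", "canonical") %in% names(tab)))
  map <- setNames(tolower(tab$canonical), tolower(tab$variant))
  bad <- names(map)[map %in% names(map) & unname(map[map]) != unname(map)]
  if (length(bad) > 0) {
    .chatmine_abort(
      paste0("Synonym map contains chains or cycles at: ",
             paste(head(bad, 5), collapse = ", ")),
      "chatmine_config_error"
    )
  }
  map
}

#' Collapse synonym variants onto canonical labels
#'
#' Each token mapped in the synonym map is replaced by its canonical label
#' (e.g. `"menses"` -> `"period"`); stream lengths are preserved and the
#' operation is idempotent.
#'
#' @param streams A list of token vectors (or a single character vector).
#' @param map A named vector from [read_synonym_map()].
#' @return Streams with variants collapsed.
#' @export
collapse_synonyms <- function(streams, map) {
  apply_token_map(streams, map)
}

#' Count tokens across streams
#'
#' @param streams A list of token vectors.
#' @return A tibble `term`, `n` ordered by descending count then term.
#' @export
count_tokens <- function(streams) {
  toks <- unlist(streams, use.names = FALSE)
  if (length(toks) == 0) return(tibble(term = character(), n = integer()))
  tab <- table(toks)
  out <- tibble(term = names(tab), n = as.integer(tab))
  out[order(-out$n, out$term), ]
}

#' Run the full normalization pipeline on message bodies
#'
#' tokenize -> spell-correct (corpus-frequency policy) -> lemmatize ->
#' collapse synonyms. Stop-word filtering is deliberately left to the
#' tallying stage so key bigrams are detected on the intact adjacency
#' structure.
#'
#' @param texts Character vector of message bodies.
#' @param suggester Optional suggestion source (e.g.
#'   [edit_distance_suggester()]); `NULL` disables spell correction.
#' @param policy A [spell_policy()].
#' @param lemma_table Optional named vector (inflected -> lemma).
#' @param synonym_map Optional named vector (variant -> canonical).
#' @param mode Tokenization mode, see [tokenize()].
#' @return A list of normalized token streams, one per input text.
#' @export
normalize_messages <- function(texts, suggester = NULL,
                               policy = spell_policy(),
                               lemma_table = NULL, synonym_map = NULL,
                               mode = "letters") {
  streams <- tokenize(texts, mode = mode)
  if (!is.null(suggester)) {
    counts <- count_tokens(streams)
    cmap <- build_correction_map(counts, suggester, policy)
    streams <- apply_token_map(streams, cmap)
  }
  if (!is.null(lemma_table)) streams <- lemmatize(streams, lemma_table)
  if (!is.null(synonym_map)) streams <- collapse_synonyms(streams, synonym_map)
  streams
}
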