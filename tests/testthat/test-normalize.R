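test_that("tokenization lowercases, strips punctuation and joins apostrophes", {
  expect_equal(tokenize("What is family planning?")[[1]],
               c("what", "is", "family", "planning"))
  expect_equal(tokenize("")[[1]], character(0))
  expect_equal(tokenize("123 !!")[[1]], character(0))
  expect_equal(tokenize("Don't worry")[[1]], c("dont", "worry"))
  expect_equal(tokenize("p2 100ksh!!")[[1]], c("p", "ksh"))
  expect_equal(tokenize("p2 100ksh!!", mode = "alnum")[[1]],
               c("p2", "100ksh"))
  expect_equal(tokenize("42 100", mode = "alnum")[[1]], character(0))
})

test_that("spell policy corrects only below the frequency boundary", {
  counts <- tibble::tibble(term = c("pregnnt", "pregnat", "family"),
                           n = c(3L, 4L, 50L))
  suggester <- function(token) {
    if (startsWith(token, "pregn")) "pregnant" else character(0)
  }
  map <- build_correction_map(counts, suggester, spell_policy())
  expect_equal(unname(map["pregnnt"]), "pregnant")   # count 3 < 4: corrected
  expect_equal(unname(map["pregnat"]), "pregnat")    # count 4: untouched
  expect_equal(unname(map["family"]), "family")

  # Swahili context: no suggestion is ever accepted
  sw_counts <- tibble::tibble(term = "mimbaa", n = 1L)
  sw_map <- build_correction_map(sw_counts, function(t) "mimba",
                                 spell_policy(), language = "sw")
  expect_equal(unname(sw_map["mimbaa"]), "mimbaa")
})

test_that("the offline suggester proposes only edit-distance-1 dictionary words", {
  sugg <- edit_distance_suggester(c("pregnant", "period", "planning"))
  expect_equal(sugg("pregnent"), "pregnant")
  expect_equal(sugg("period"), character(0))      # in-list: no suggestion
  expect_equal(sugg("xyzzy"), character(0))
  expect_equal(sugg("perod"), "period")           # deletion typo
})

test_that("lemmatization is a pure idempotent lookup", {
  tab <- read_lemma_table(system.file("extdata", "lemma_en.csv",
                                      package = "chatmine"))
  expect_equal(lemmatize(list(c("periods", "pain")), tab)[[1]],
               c("period", "pain"))
  expect_equal(lemmatize("zzz-unknown", tab), "zzz-unknown")
  set.seed(8)
  for (i in 1:10) {
    stream <- sample(c(names(tab), unname(tab), letters), 30, TRUE)
    once <- lemmatize(stream, tab)
    expect_equal(lemmatize(once, tab), once)
    expect_length(once, length(stream))
  }
})

test_that("synonym collapsing maps variants to canonical labels idempotently", {
  map <- read_synonym_map(system.file("extdata", "synonyms_en.csv",
                                      package = "chatmine"))
  expect_equal(collapse_synonyms(list("menses"), map)[[1]], "period")
  expect_equal(collapse_synonyms(list(c("a", "b")), setNames(
    character(0), character(0)))[[1]], c("a", "b"))
  stream <- c("menses", "period", "contraceptive", "other")
  once <- collapse_synonyms(stream, map)
  expect_equal(collapse_synonyms(once, map), once)

  cyclic <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("variant,canonical", "a,b", "b,a"), cyclic)
  expect_error(read_synonym_map(cyclic), class = "chatmine_config_error")
})

test_that("stop-word filtering removes listed tokens and preserves order", {
  expect_equal(
    filter_stopwords(c("what", "is", "family", "planning"),
                     c("what", "is")),
    c("family", "planning"))
  expect_equal(filter_stopwords(c("a", "b"), character(0)), c("a", "b"))
  expect_equal(filter_stopwords(c("a", "b"), c("a", "b")), character(0))
  sl <- default_stoplists()
  expect_true(all(c("the", "and") %in% chatmine:::.stop_words(sl)))
  expect_true(all(c("ya", "na") %in% chatmine:::.stop_words(sl)))
})

test_that("normalization conserves token counts before stop filtering", {
  texts <- c("My periods are late", "menses pain, menses pain!",
             "Don't worry about the injecton")
  streams <- normalize_messages(
    texts,
    suggester = edit_distance_suggester(),
    lemma_table = read_lemma_table(system.file("extdata", "lemma_en.csv",
                                               package = "chatmine")),
    synonym_map = read_synonym_map(system.file("extdata", "synonyms_en.csv",
                                               package = "chatmine")))
  expect_equal(lengths(streams), lengths(tokenize(texts)))
  expect_true("period" %in% streams[[2]])   # menses collapsed
  expect_true("injection" %in% streams[[3]]) # corrected then lemmatized
})
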