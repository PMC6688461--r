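test_that("disjoint-alphabet training texts classify as their own label", {
  m <- tiny_model()
  out <- detect_language(m, c("abab baba abba", "cdcd dcdc cddc"))
  expect_equal(out$label, c("en", "sw"))
  expect_true(all(out$score > m$threshold))
})

test_that("scores agree with an independently computed naive Bayes log-likelihood", {
  texts <- c("aabb abab", "ccdd cdcd")
  labels <- c("en", "sw")
  m <- train_language_model(texts, labels, ngram_range = c(2, 2),
                            smoothing = 0.5, threshold = 0.01)
  # brute-force oracle: count 2-grams of " text " per language, smooth, score
  grams_of <- function(x) {
    x <- paste0(" ", x, " ")
    substring(x, 1:(nchar(x) - 1), 2:nchar(x))
  }
  cnt <- lapply(texts, function(t) table(grams_of(t)))
  vocab <- sort(unique(c(names(cnt[[1]]), names(cnt[[2]]))))
  ll_oracle <- function(text, k) {
    tc <- cnt[[k]]
    denom <- sum(tc) + 0.5 * (length(vocab) + 1)
    sum(vapply(grams_of(text), function(g) {
      c0 <- if (g %in% names(tc)) tc[[g]] else 0
      log((c0 + 0.5) / denom)
    }, numeric(1))) + log(0.5)
  }
  probe <- "abcd"
  sc <- chatmine:::.lm_score(m, probe)
  o <- c(ll_oracle(probe, 1), ll_oracle(probe, 2))
  expect_equal(sc$margin, abs(o[1] - o[2]) / length(grams_of(probe)),
               tolerance = 1e-12)
  expect_equal(sc$label, c("en", "sw")[which.max(o)])
})

test_that("identical training corpora for both languages yield und everywhere", {
  m <- train_language_model(c("abab abba", "abab abba"), c("en", "sw"))
  out <- detect_language(m, c("abab", "abba baab"))
  expect_equal(out$label, c("und", "und"))
})

test_that("detection is total: empty, digit-only and unseen input get und", {
  m <- tiny_model()
  out <- detect_language(m, c("", "0712345678", NA, "!!??"))
  expect_equal(out$label, rep("und", 4))
  expect_equal(out$score, rep(0, 4))
})

test_that("model serialization round-trips classifications exactly", {
  m <- train_default_model()
  path <- withr::local_tempfile(fileext = ".json")
  write_language_model(m, path)
  m2 <- read_language_model(path)
  probes <- c("what are the side effects of the pill",
              "nataka kujua kuhusu uzazi wa mpango",
              "abc xyz", "0722000000", "")
  expect_equal(detect_language(m2, probes), detect_language(m, probes))
})

test_that("weekly imputation relabels und to the weekly dominant language", {
  # one user, ten messages in one ISO week: six en, two sw, two und
  labs <- c(rep("en", 6), rep("sw", 2), rep("und", 2))
  x <- corpus(make_messages("u1", "inbound",
    sprintf("2018-03-%02d 10:00:00", 12:17)[c(1:6, 1:2, 3:4)],
    language = labs))
  y <- impute_weekly_language(x)
  expect_equal(sum(y$messages$language == "en"), 8)
  expect_equal(sum(y$messages$language == "sw"), 2)
  expect_equal(y$messages$language[labs == "und"], c("en", "en"))
})

test_that("imputation falls back to the overall dominant language, then stays und", {
  # week A: 2 en / 2 sw tie + 1 und; week B: 3 en -> overall dominant en
  x <- corpus(make_messages("u1", "inbound",
    c(sprintf("2018-03-%02d 10:00:00", c(12, 13, 14, 15, 16)),
      sprintf("2018-04-%02d 10:00:00", 2:4)),
    language = c("en", "en", "sw", "sw", "und", "en", "en", "en")))
  y <- impute_weekly_language(x)
  expect_equal(y$messages$language[5], "en")

  # isolated all-und week with no other evidence stays und
  z <- corpus(make_messages("u2", "inbound",
    sprintf("2018-03-%02d 10:00:00", 12:13), language = "und"))
  expect_equal(impute_weekly_language(z)$messages$language, c("und", "und"))

  # global tie: weekly tie and overall tie -> und
  w <- corpus(make_messages("u3", "inbound",
    sprintf("2018-03-%02d 10:00:00", 12:16),
    language = c("en", "en", "sw", "sw", "und")))
  expect_equal(impute_weekly_language(w)$messages$language[5], "und")
})

test_that("imputation is idempotent and never touches labels it should not", {
  g <- generate_corpus(generator_config(n_users = 150, seed = 3))
  x <- detect_corpus_language(g$corpus, train_default_model())
  y1 <- impute_weekly_language(x)
  y2 <- impute_weekly_language(y1)
  expect_equal(y2$messages, y1$messages)
  pre <- x$messages$language
  post <- y1$messages$language
  changed <- which(!is.na(pre) & pre != post)
  expect_true(all(pre[changed] == "und"))
  out_rows <- x$messages$direction == "outbound"
  expect_equal(post[out_rows], pre[out_rows])
  expect_true(all(post[x$messages$direction == "inbound"] %in%
                    c("en", "sw", "und")))
})

test_that("language mix shares are percentages that sum to 100", {
  x <- corpus(make_messages("u1", "inbound",
    sprintf("2018-03-%02d 10:00:00", 12:15),
    language = c("en", "en", "sw", "und")))
  mix <- language_mix(x)
  expect_equal(mix$pct, c(50, 25, 25))
  expect_equal(sum(mix$pct), 100)
  all_en <- corpus(make_messages("u1", "inbound",
    sprintf("2018-03-%02d 10:00:00", 12:14), language = "en"))
  expect_equal(language_mix(all_en)$pct, c(100, 0, 0))
  no_in <- corpus(make_messages("u1", "outbound", "2018-03-12 10:00:00"))
  expect_error(language_mix(no_in), class = "chatmine_empty_input")
})

test_that("discordance compares final labels with stated preferences", {
  x <- corpus(make_messages("u1", "inbound",
    c("2018-03-12 10:00:00", "2018-03-13 10:00:00"),
    language = c("en", "sw")),
    make_users("u1", language_preference = "en"))
  d <- discordance(x)
  expect_equal(d$pct_messages_discordant, 50)
  expect_equal(d$pct_users_any_discordant, 100)

  y <- corpus(make_messages(c("u1", "u2"), "inbound",
    c("2018-03-12 10:00:00", "2018-03-13 10:00:00"), language = "en"),
    make_users(c("u1", "u2"), language_preference = "en"))
  dy <- discordance(y)
  expect_equal(dy$pct_messages_discordant, 0)
  expect_equal(dy$pct_users_any_discordant, 0)

  z <- corpus(make_messages("u1", "inbound", "2018-03-12 10:00:00",
                            language = "en"),
              make_users("u1", language_preference = "unknown"))
  expect_false(discordance(z)$defined)
})

test_that("end-to-end label accuracy reaches 99% on distinct-vocabulary text", {
  g <- generate_corpus(generator_config(n_users = 400, seed = 21))
  det <- detect_corpus_language(g$corpus, train_default_model())
  inb <- det$messages$direction == "inbound"
  lab <- det$messages$language[inb]
  tru <- g$truth$messages$language
  long <- nchar(det$messages$body[inb]) >= 20 & tru != "und"
  expect_gte(mean(lab[long] == tru[long]), 0.99)
})
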