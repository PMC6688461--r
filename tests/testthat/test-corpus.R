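test_that("well-formed input loads completely and reports zero rejections", {
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(make_messages(
    c("u1", "u1", "u2"), c("inbound", "inbound", "outbound"),
    c("2018-01-01 10:00:00", "2018-01-02 11:00:00", "2018-01-02 11:05:00"),
    body = c("hello", "habari", "welcome")
  ), path, na = "")
  x <- read_corpus(path)
  expect_s3_class(x, "chat_corpus")
  expect_equal(nrow(x$messages), 3)
  expect_equal(x$load_report$n_rejected, 0)
  expect_equal(sum(x$messages$direction == "inbound"), 2)
})

test_that("rows with missing direction or bad timestamps are rejected and counted", {
  path <- withr::local_tempfile(fileext = ".csv")
  df <- make_messages(
    c("u1", "u1", "u2"), c("inbound", NA, "outbound"),
    c("2018-01-01 10:00:00", "2018-01-02 11:00:00", "2018-01-03 09:00:00")
  )
  df$timestamp <- as.character(df$timestamp)
  df$timestamp[3] <- "not-a-time"
  readr::write_csv(df, path, na = "")
  x <- read_corpus(path)
  expect_equal(nrow(x$messages), 1)
  expect_equal(x$load_report$n_rejected, 2)
  expect_setequal(x$load_report$reasons$reason,
                  c("unparseable_timestamp", "missing_or_invalid_direction"))
  expect_error(read_corpus(path, strict = TRUE), class = "chatmine_load_error")
})

test_that("schema and integrity violations are fatal with informative classes", {
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(user_id = "u1", direction = "inbound",
                                  timestamp = "2018-01-01"), path)
  expect_error(read_corpus(path), regexp = "message_id",
               class = "chatmine_schema_error")
  dup <- make_messages(c("u1", "u1"), "inbound",
                       c("2018-01-01 10:00:00", "2018-01-01 11:00:00"))
  dup$message_id <- c("m1", "m1")
  expect_error(corpus(dup), class = "chatmine_integrity_error")
})

test_that("write/read round-trips preserve every field in both formats", {
  g <- generate_corpus(generator_config(n_users = 20, seed = 11))
  x <- g$corpus
  x$messages$language[x$messages$direction == "inbound"] <-
    g$truth$messages$language
  for (fmt in c("csv", "jsonl")) {
    mp <- withr::local_tempfile(fileext = paste0(".", fmt))
    up <- withr::local_tempfile(fileext = ".csv")
    write_corpus(x, mp, up, format = fmt)
    y <- read_corpus(mp, up, format = fmt)
    expect_equal(y$messages, x$messages, ignore_attr = TRUE)
    expect_equal(y$users[order(y$users$user_id), ],
                 x$users[order(x$users$user_id), ], ignore_attr = TRUE)
  }
})

test_that("unknown message senders get placeholder user records", {
  x <- corpus(make_messages(c("u1", "u9"), "inbound",
                            c("2018-01-01 10:00:00", "2018-01-01 11:00:00")),
              make_users("u1", sex = "female"))
  expect_setequal(x$users$user_id, c("u1", "u9"))
  expect_equal(x$users$sex[x$users$user_id == "u9"], "unknown")
})

test_that("corpus summaries compute per-user inbound statistics", {
  # users with inbound counts {1, 2, 3}
  x <- corpus(make_messages(
    c("u1", "u2", "u2", "u3", "u3", "u3"), "inbound",
    sprintf("2018-01-0%d 10:00:00", 1:6)))
  s <- summarize_corpus(x)
  expect_equal(s$inbound_per_user_median, 2)
  expect_equal(s$inbound_per_user_mean, 2)
  expect_equal(s$n_total, s$n_inbound + s$n_outbound)

  y <- corpus(make_messages("u1", c("inbound", "outbound"),
                            c("2018-01-01 10:00:00", "2018-01-01 10:05:00")))
  sy <- summarize_corpus(y)
  expect_equal(sy$n_total, 2)
  expect_equal(sy$inbound_per_user_mean, 1)
  expect_error(summarize_corpus(corpus(make_messages(
    character(0), character(0), character(0)))),
    class = "chatmine_empty_input")
})

test_that("privacy export keeps exactly the terms at or above the threshold", {
  counts <- tibble::tibble(term = c("a", "b", "c"), n = c(5L, 3L, 2L))
  out <- export_term_counts(counts, min_count = 3)
  expect_equal(out$term, c("a", "b"))
  expect_equal(export_term_counts(counts, min_count = 1), counts)
  empty <- tibble::tibble(term = character(), n = integer())
  expect_equal(nrow(export_term_counts(empty)), 0)
  expect_error(export_term_counts(counts, min_count = 0),
               class = "chatmine_parameter_error")

  # property: never emits a tally below min_count; retained mass shrinks
  set.seed(4)
  for (i in 1:20) {
    tc <- tibble::tibble(term = sprintf("t%02d", 1:30),
                         n = rpois(30, 3))
    mc <- sample(1:6, 1)
    out <- export_term_counts(tc, mc)
    expect_true(all(out$n >= mc))
    expect_lte(sum(out$n), sum(tc$n))
  }
})
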