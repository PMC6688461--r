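test_that("the inactivity-gap rule segments streams as specified", {
  x <- corpus(make_messages("u1", "inbound",
    c("2018-06-01 08:00:00", "2018-06-01 09:00:00", "2018-06-02 14:00:00")))
  seg <- segment_conversations(x, gap_hours = 24)
  expect_equal(nrow(seg$conversations), 2)
  expect_equal(sort(seg$conversations$n_messages), c(1L, 2L))

  one <- corpus(make_messages("u1", "inbound", "2018-06-01 08:00:00"))
  expect_equal(nrow(segment_conversations(one)$conversations), 1)

  seg_inf <- segment_conversations(x, gap_hours = Inf)
  expect_equal(nrow(seg_inf$conversations), 1)
})

test_that("segmentation partitions messages and is monotone in the threshold", {
  g <- generate_corpus(generator_config(n_users = 60, seed = 31))
  prev <- Inf
  for (gap in c(240, 48, 24, 6, 1)) {
    seg <- segment_conversations(g$corpus, gap_hours = gap)
    expect_equal(nrow(seg$assignments), nrow(g$corpus$messages))
    expect_equal(sum(seg$conversations$n_messages),
                 nrow(g$corpus$messages))
    expect_equal(sum(seg$conversations$n_user_messages) +
                   sum(seg$conversations$n_agent_messages),
                 nrow(g$corpus$messages))
    n <- nrow(seg$conversations)
    if (is.finite(prev)) expect_gte(n, prev)
    prev <- n
  }
})

test_that("conversation descriptives aggregate the coded table", {
  convs <- tibble::tibble(
    conversation_id = c("c1", "c2", "c3"),
    user_id = c("u1", "u1", "u2"),
    n_user_messages = c(6L, 5L, 9L),
    n_agent_messages = c(4L, 5L, 7L),
    n_messages = c(10L, 10L, 16L))
  users <- make_users(c("u1", "u2"), sex = c("female", "male"),
                      age_years = c(22, 17))
  stats <- conversation_stats(convs, users)
  all_row <- stats[stats$group == "All", ]
  expect_equal(all_row$messages_per_convo_mean, 12)
  expect_equal(all_row$n_users, 2)
  expect_equal(all_row$n_conversations, 3)
  expect_equal(all_row$n_messages, 36)
  expect_true(all(c("Women, 20-24", "Men, 15-19") %in% stats$group))

  topics <- tibble::tibble(conversation_id = c("c1", "c1"),
                           topic = c("contraception", "fertility"))
  with_topics <- conversation_stats(convs[1, ], users, topics = topics)
  expect_equal(with_topics$topics_per_convo_mean[
    with_topics$group == "All"], 2)
})

test_that("question categories distribute over the six-way scheme", {
  codes <- tibble::tibble(
    code = c(rep("question_request", 10), rep("greeting", 2)),
    category = c(rep(1L, 5), rep(3L, 3), rep(5L, 2), NA, NA),
    myth_flag = FALSE)
  qd <- question_distribution(codes)
  expect_equal(qd$categories$pct, c(50, 0, 30, 0, 20, 0))
  expect_equal(sum(qd$categories$pct), 100)
  expect_equal(qd$pct_question_messages, 100 * 10 / 12)

  all2 <- question_distribution(tibble::tibble(
    code = "question_request", category = rep(2L, 4), myth_flag = FALSE))
  expect_equal(all2$categories$pct, c(0, 100, 0, 0, 0, 0))
})

test_that("the myth share is computed among information requests", {
  n_info <- 516
  codes <- tibble::tibble(
    code = "question_request",
    category = c(rep(1L, n_info), rep(3L, 100)),
    myth_flag = c(rep(TRUE, 24), rep(FALSE, n_info - 24 + 100)))
  qd <- question_distribution(codes)
  expect_equal(qd$n_information_requests, 516)
  expect_equal(qd$pct_myth, 100 * 24 / 516, tolerance = 1e-12)
  expect_equal(round(qd$pct_myth, 1), 4.7)
})

test_that("topic co-occurrence counts unordered pairs in multi-topic conversations", {
  two <- tibble::tibble(conversation_id = "c1",
                        topic = c("contraception", "fertility"))
  out <- topic_cooccurrence(two)
  expect_equal(out$n, 1L)
  expect_equal(out$topic_a, "contraception")

  three <- tibble::tibble(conversation_id = "c1", topic = c("a", "b", "c"))
  expect_equal(nrow(topic_cooccurrence(three)), 3)

  singles <- tibble::tibble(conversation_id = c("c1", "c2"),
                            topic = c("a", "b"))
  expect_equal(nrow(topic_cooccurrence(singles)), 0)

  set.seed(2)
  many <- tibble::tibble(
    conversation_id = rep(sprintf("c%02d", 1:12),
                          times = rep(c(1, 2, 3, 4), 3)),
    topic = unlist(lapply(rep(c(1, 2, 3, 4), 3),
                          function(k) sample(letters[1:6], k))))
  k <- table(many$conversation_id)
  expected_total <- sum(choose(k[k >= 2], 2))
  expect_equal(sum(topic_cooccurrence(many)$n), expected_total)
})

test_that("high-engagement sampling honors the weekly threshold and sex quota", {
  g <- generate_corpus(generator_config(n_users = 250, seed = 17))
  x <- detect_corpus_language(g$corpus, train_default_model())
  x <- impute_weekly_language(x)
  x$users <- g$truth$users[, c("user_id", "sex", "age_years",
                               "language_preference")]
  picked <- sample_high_engagement(x, min_messages = 3, per_sex = 5,
                                  seed = 9)
  expect_lte(length(picked), 10)
  sex <- x$users$sex[match(picked, x$users$user_id)]
  expect_true(all(table(sex) <= 5))
  # every sampled user has >= 3 English inbound messages in some ISO week
  m <- x$messages
  for (u in picked) {
    keep <- m$user_id == u & m$direction == "inbound" &
      !is.na(m$language) & m$language == "en"
    wk <- format(m$timestamp[keep], "%G-%V")
    expect_gte(max(table(wk)), 3)
  }
  same <- sample_high_engagement(x, min_messages = 3, per_sex = 5, seed = 9)
  expect_equal(picked, same)
})
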