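test_that("generation is deterministic given the seed", {
  cfg <- generator_config(n_users = 80, seed = 123)
  g1 <- generate_corpus(cfg)
  g2 <- generate_corpus(cfg)
  expect_identical(g1$corpus$messages, g2$corpus$messages)
  expect_identical(g1$corpus$users, g2$corpus$users)
  expect_identical(g1$truth$users, g2$truth$users)
  g3 <- generate_corpus(generator_config(n_users = 80, seed = 124))
  expect_false(identical(g1$corpus$messages$body,
                         g3$corpus$messages$body))
})

test_that("invalid configurations are rejected with the violations named", {
  expect_error(generator_config(female_share = 1.4),
               class = "chatmine_parameter_error")
  expect_error(generator_config(pattern_shares = c(
    single_in_single_out = 0.5, multi_in_single_out = 0.5,
    multi_in_multi_out = 0.2, single_in_multi_out = 0,
    no_reply = 0)), regexp = "sum to 1",
    class = "chatmine_parameter_error")
  expect_error(generator_config(messages_mean = 0.5),
               class = "chatmine_parameter_error")
})

test_that("realized demographics match the configured distributions", {
  cfg <- generator_config(n_users = 5000, seed = 2)
  g <- generate_corpus(cfg)
  tu <- g$truth$users
  ci <- chatmine:::.ci_prop(cfg$female_share, nrow(tu))
  expect_gt(mean(tu$sex == "female"), ci[1])
  expect_lt(mean(tu$sex == "female"), ci[2])
  expect_true(all(tu$age_years >= 15 & tu$age_years <= 65))
  expect_equal(mean(tu$age_years), cfg$age_mean, tolerance = 0.02)
  expect_equal(sd(tu$age_years), cfg$age_sd, tolerance = 0.05)
  # recorded table masks but never distorts the attributes
  rec <- g$corpus$users
  known <- rec$sex != "unknown"
  expect_equal(rec$sex[known], tu$sex[known])
})

test_that("per-user inbound counts hit the configured heavy-tailed moments", {
  g <- generate_corpus(generator_config(n_users = 10000, seed = 8))
  n_in <- g$truth$users$n_inbound
  expect_equal(median(n_in), 2)
  expect_equal(mean(n_in), 3.1, tolerance = 0.1 / 3.1)
  expect_gt(sd(n_in), mean(n_in))  # overdispersed
  counted <- table(g$corpus$messages$user_id[
    g$corpus$messages$direction == "inbound"])
  expect_equal(sort(as.integer(counted)), sort(n_in[n_in > 0]))
})

test_that("truth tables are row-consistent with the emitted corpus", {
  g <- generate_corpus(generator_config(n_users = 200, seed = 4))
  m <- g$corpus$messages
  expect_setequal(g$truth$messages$message_id,
                  m$message_id[m$direction == "inbound"])
  und <- g$truth$messages$language == "und"
  bodies <- m$body[match(g$truth$messages$message_id, m$message_id)]
  expect_true(all(!grepl("[a-z]{3}", bodies[und])))
  agents <- m$agent_id[m$direction == "outbound"]
  expect_false(anyNA(agents))
  expect_true(all(is.na(m$agent_id[m$direction == "inbound"])))
})

test_that("label-event generation honors the disagreement limits", {
  zero <- generate_label_events(n_questions = 50, disagreement_rate = 0,
                                seed = 5)
  res0 <- resolve_double_agreement(zero$events)
  expect_true(all(res0$resolved))
  expect_true(all(res0$n_presentations == 2))
  expect_equal(res0$final_label,
               zero$truth$intent_label[match(res0$question_id,
                                             zero$truth$question_id)])

  all_wrong <- generate_label_events(n_questions = 30,
                                     disagreement_rate = 1, seed = 5)
  res1 <- resolve_double_agreement(all_wrong$events)
  expect_false(any(res1$resolved))

  mixed <- generate_label_events(n_questions = 400,
                                 disagreement_rate = 0.3, seed = 5)
  resm <- resolve_double_agreement(mixed$events)
  ok <- resm$resolved
  expect_gt(mean(ok), 0.5)
  expect_equal(
    resm$final_label[ok],
    mixed$truth$intent_label[match(resm$question_id[ok],
                                   mixed$truth$question_id)])
})

test_that("generated conversation codes follow the configured scheme", {
  g <- generate_corpus(generator_config(n_users = 100, seed = 19))
  seg <- segment_conversations(g$corpus)
  codes <- generate_conversation_codes(seg$conversations, seed = 3)
  expect_equal(nrow(codes$message_codes),
               sum(seg$conversations$n_user_messages))
  qd <- question_distribution(codes$message_codes)
  expect_equal(sum(qd$categories$pct), 100)
  expect_gt(qd$pct_question_messages, 60)
  expect_lt(qd$pct_question_messages, 85)
  n_t <- table(codes$topics$conversation_id)
  expect_true(all(n_t >= 1))
  co <- topic_cooccurrence(codes$topics)
  k <- n_t[n_t >= 2]
  expect_equal(sum(co$n), sum(choose(k, 2)))
})
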