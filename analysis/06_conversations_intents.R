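#!/usr/bin/env Rscript
# Conversation-level analytics on the high-engagement subsample (segmented
# by the 24-hour inactivity rule and coded with the synthetic coding
# scheme) and intent-label adjudication under the double-agreement
# protocol.

source("analysis/00_common.R")

lab <- analysis_labeled_corpus()
x <- lab$corpus

sampled <- sample_high_engagement(x, min_messages = 7, per_sex = 50,
                                  seed = ANALYSIS_SEED + 1L)
sub <- x
sub$messages <- sub$messages[sub$messages$user_id %in% sampled, ]
sub$users <- sub$users[sub$users$user_id %in% sampled, ]

seg <- segment_conversations(sub, gap_hours = 24)
codes <- generate_conversation_codes(seg$conversations,
                                     seed = ANALYSIS_SEED + 2L)

stats <- conversation_stats(seg$conversations, sub$users,
                            topics = codes$topics)
readr::write_csv(stats, "results/conversation_stats.csv")

qd <- question_distribution(codes$message_codes)
readr::write_csv(qd$categories, "results/question_categories.csv")
co <- topic_cooccurrence(codes$topics)
readr::write_csv(co, "results/topic_pairs.csv")

all_row <- stats[stats$group == "All", ]
cat(sprintf(
  "%d sampled users held %d conversations (%.1f per person; %.1f messages and %.1f topics per conversation).\n",
  all_row$n_users, all_row$n_conversations,
  all_row$convos_per_person_mean, all_row$messages_per_convo_mean,
  all_row$topics_per_convo_mean))
cat(sprintf(
  "%.1f%% of coded user messages were questions/requests; %.1f%% of information requests asked about myths.\n",
  qd$pct_question_messages, qd$pct_myth))

events <- generate_label_events(n_questions = 2000,
                                disagreement_rate = 0.3,
                                seed = ANALYSIS_SEED + 3L)
res <- resolve_double_agreement(events$events)
dist <- intent_distribution(res)
readr::write_csv(dist$overall, "results/intent_shares.csv")
readr::write_csv(res, "scratch/intent_resolutions.csv")
cat(sprintf(
  "Double agreement resolved %.1f%% of %d questions (mean %.2f presentations); top intent: %s (%.1f%%).\n",
  100 * mean(res$resolved), nrow(res),
  mean(res$n_presentations[res$resolved]),
  dist$overall$intent_label[1], dist$overall$pct[1]))
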