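#!/usr/bin/env Rscript
# Detect message language with the packaged character n-gram classifier,
# impute undetected labels from weekly usage, and quantify
# preference/detection discordance.

source("analysis/00_common.R")

lab <- analysis_labeled_corpus()
x <- lab$corpus

write_language_model(lab$model, "scratch/language_model.json")

pre <- detect_corpus_language(analysis_corpus()$corpus, lab$model)
pre_mix <- language_mix(pre)
post_mix <- language_mix(x)
mix <- dplyr::bind_rows(
  dplyr::mutate(pre_mix, stage = "detected"),
  dplyr::mutate(post_mix, stage = "after_imputation"))
readr::write_csv(mix, "results/language_mix.csv")

d <- discordance(x)
readr::write_csv(tibble::tibble(
  quantity = c("pct_messages_discordant", "pct_users_any_discordant"),
  value = c(d$pct_messages_discordant, d$pct_users_any_discordant),
  n = c(d$n_messages, d$n_users)), "results/discordance.csv")

acc <- mean(
  x$messages$language[x$messages$direction == "inbound"] ==
    lab$truth$messages$language |
    lab$truth$messages$language == "und")
cat("Language mix after imputation:\n")
print(as.data.frame(post_mix))
cat(sprintf(
  "Discordant: %.1f%% of inbound messages; %.1f%% of users had at least one.\n",
  d$pct_messages_discordant, d$pct_users_any_discordant))
cat(sprintf("Final labels agree with ground truth on %.2f%% of en/sw messages.\n",
            100 * acc))
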