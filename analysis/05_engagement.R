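#!/usr/bin/env Rscript
# Classify per-user engagement patterns and contrast single-message use by
# sex.

source("analysis/00_common.R")

gen <- analysis_corpus()
x <- gen$corpus

eng <- classify_engagement(x)
readr::write_csv(eng$records, "scratch/engagement_records.csv")
readr::write_csv(eng$shares, "results/engagement_shares.csv")

rr <- single_message_rate_ratio(eng$records, x$users)
readr::write_csv(tibble::tibble(
  quantity = c("ratio", "male_share", "female_share", "n_male", "n_female"),
  value = c(rr$ratio, rr$male_share, rr$female_share, rr$n_male,
            rr$n_female)), "results/single_message_ratio.csv")

sh <- setNames(eng$shares$pct, eng$shares$pattern)
cat(sprintf(
  "Engagement: %.1f%% single-in/single-out, %.1f%% multi-in/single-out, %.1f%% multi-in/multi-out (plus %.1f%% single-in/multi-out, %.1f%% no reply).\n",
  sh[["single_in_single_out"]], sh[["multi_in_single_out"]],
  sh[["multi_in_multi_out"]], sh[["single_in_multi_out"]],
  sh[["no_reply"]]))
cat(sprintf(
  "Men were %.2f times as likely as women to send a single message and get a single reply.\n",
  rr$ratio))
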