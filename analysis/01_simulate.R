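#!/usr/bin/env Rscript
# Generate the synthetic two-way chat corpus and record its descriptives:
# who the users are, how much they write, and how volume moves week to
# week. Writes the full corpus to scratch/ (large) and summary tables to
# results/.

source("analysis/00_common.R")

gen <- analysis_corpus()
x <- gen$corpus

write_corpus(x, "scratch/messages.csv", "scratch/users.csv")

s <- summarize_corpus(x)
summary_tbl <- tibble::tibble(
  quantity = c("n_users", "n_inbound", "n_outbound", "n_total",
               "inbound_per_user_median", "inbound_per_user_mean",
               "inbound_per_user_sd", "pct_female", "age_mean", "age_sd"),
  value = c(s$n_users, s$n_inbound, s$n_outbound, s$n_total,
            s$inbound_per_user_median, s$inbound_per_user_mean,
            s$inbound_per_user_sd, s$pct_female, s$age_mean, s$age_sd))
readr::write_csv(summary_tbl, "results/corpus_summary.csv")

wv <- weekly_volume(x)
readr::write_csv(wv, "results/weekly_volume.csv")

cat(sprintf(
  "%d users sent %d messages and received %d replies (%d total).\n",
  s$n_users, s$n_inbound, s$n_outbound, s$n_total))
cat(sprintf(
  "Median user sent %.1f messages (mean %.2f); %.1f%% of known-sex users female; mean age %.1f (SD %.1f).\n",
  s$inbound_per_user_median, s$inbound_per_user_mean, s$pct_female,
  s$age_mean, s$age_sd))
cat(sprintf("Weekly volume spans %d ISO weeks (peak %d inbound).\n",
            nrow(wv), max(wv$n_inbound)))
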