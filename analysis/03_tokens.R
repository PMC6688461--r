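#!/usr/bin/env Rscript
# Normalize English inbound messages, discover the key bigrams, tally
# terms with bigram preemption (overall and stratified by sex and
# sex-by-age cohort), force-rank them, and write privacy-filtered count
# tables shaped like the archived token files.

source("analysis/00_common.R")

lab <- analysis_labeled_corpus()
x <- lab$corpus
streams <- analysis_streams(x)
stops <- default_stoplists()

keys <- discover_key_bigrams(streams, top_k = 25, min_count = 10,
                             stoplists = stops)
cat("Top key bigrams:", paste(head(keys, 8), collapse = "; "), "...\n")

tok <- tally_with_preemption(streams, keys, stops)
readr::write_csv(export_term_counts(tok, 3), "results/tok_en.csv")

pair_counts <- adjacent_pair_counts(streams)
bi <- bigram_edges(pair_counts, min_count = 3, stoplists = stops)
readr::write_csv(
  tibble::tibble(bigram = paste(bi$from, bi$to), n = bi$n),
  "results/tok_bi_en.csv")

# stratified tallies use the *recorded* attributes, so "missing" strata
# appear exactly as they would on real data
for (spec in c("sex", "sex_age")) {
  strat <- stratified_counts(x, streams, strata = spec,
                             key_bigrams = keys, stoplists = stops)
  out <- export_term_counts(strat, 3)
  readr::write_csv(out, sprintf("results/tok_en_%s.csv",
                                ifelse(spec == "sex", "g", "cohort")))
  ranks <- forced_rank(strat, top_n = 25)
  readr::write_csv(ranks, sprintf("results/rank_%s.csv", spec))
}

top5 <- head(tok, 5)
cat("Top terms overall:",
    paste(sprintf("%s (%d)", top5$term, top5$n), collapse = ", "), "\n")
ranks <- readr::read_csv("results/rank_sex_age.csv",
                         show_col_types = FALSE)
old_men <- ranks[ranks$stratum == "male 36+" & ranks$rank <= 3, ]
cat("Oldest-men top 3:", paste(old_men$term, collapse = ", "), "\n")
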