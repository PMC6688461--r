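#!/usr/bin/env Rscript
# Word-association structure of the English corpus: the directed bigram
# network (edge list) and pairwise phi correlations between words across
# users' pooled message sets.

source("analysis/00_common.R")

lab <- analysis_labeled_corpus()
x <- lab$corpus
streams <- analysis_streams(x)
stops <- default_stoplists()

edges <- bigram_edges(adjacent_pair_counts(streams), min_count = 10,
                      stoplists = stops)
readr::write_csv(edges, "results/bigram_edges.csv")
cat(sprintf("Bigram network: %d edges with count >= 10; strongest %s -> %s (%d).\n",
            nrow(edges), edges$from[1], edges$to[1], edges$n[1]))

sections <- user_term_sections(x, streams, stoplists = stops)
phi <- pairwise_phi(sections, min_section_occurrences = 20,
                    sections = unique(x$messages$user_id[
                      x$messages$direction == "inbound"]))
readr::write_csv(head(phi, 500), "results/phi_pairs.csv")
cat(sprintf("Phi table: %d pairs over %d user-sections; top pair %s / %s (phi %.3f).\n",
            nrow(phi), phi$n_sections[1], phi$term_a[1], phi$term_b[1],
            phi$phi[1]))
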