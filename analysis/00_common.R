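# Shared setup for the numbered analysis drivers. Each driver regenerates
# the same seeded corpus (cheap and fully deterministic), so every script
# can be run on its own; large intermediates go to scratch/, small result
# tables to results/.

suppressMessages(library(chatmine))

ANALYSIS_SEED <- 20190529L %% 10000L  # small fixed seed for the workflow
N_USERS <- 10000L

dir.create("results", showWarnings = FALSE)
dir.create("scratch", showWarnings = FALSE)

analysis_corpus <- function() {
  generate_corpus(generator_config(n_users = N_USERS, seed = ANALYSIS_SEED))
}

analysis_labeled_corpus <- function() {
  gen <- analysis_corpus()
  model <- train_default_model()
  x <- detect_corpus_language(gen$corpus, model)
  list(corpus = impute_weekly_language(x), truth = gen$truth,
       model = model)
}

# inbound English token streams, fully normalized, named by message id
analysis_streams <- function(x) {
  inb <- x$messages$direction == "inbound" &
    !is.na(x$messages$language) & x$messages$language == "en"
  streams <- normalize_messages(
    x$messages$body[inb],
    suggester = edit_distance_suggester(),
    lemma_table = read_lemma_table(system.file("extdata", "lemma_en.csv",
                                               package = "chatmine")),
    synonym_map = read_synonym_map(system.file("extdata", "synonyms_en.csv",
                                               package = "chatmine")))
  names(streams) <- x$messages$message_id[inb]
  streams
}
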