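# Character n-gram naive Bayes language identification for short bilingual
# messages, with a reliability margin that returns "und" (undetermined) on
# texts the model cannot attribute confidently.

.lm_clean <- function(x) {
  x <- tolower(ifelse(is.na(x), "", x))
  x <- str_replace_all(x, "[^\\p{L}]+", " ")
  x <- str_squish(x)
  ifelse(nzchar(x), paste0(" ", x, " "), "")
}

.char_ngrams <- function(x, nmin, nmax) {
  n <- nchar(x)
  if (n < nmin) return(character(0))
  out <- vector("list", nmax - nmin + 1)
  for (k in nmin:nmax) {
    if (n >= k) out[[k - nmin + 1]] <- substring(x, 1:(n - k + 1), k:n)
  }
  unlist(out, use.names = FALSE)
}

# Deterministic local RNG: runs `expr` under a fixed seed and restores the
# caller's RNG state, so training is reproducible without disturbing
# simulations that call it.
.with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Train a character n-gram naive Bayes language identifier
#'
#' Fits per-language multinomial models over character n-grams (default
#' 2- to 4-grams) of the lowercased, letters-and-spaces-only text, with
#' additive smoothing. Classification compares per-language log-likelihoods
#' plus log-priors; a text whose per-character log-likelihood margin between
#' the best and second-best language falls below the reliability threshold
#' is labeled `"und"` rather than guessed.
#'
#' The default threshold is calibrated at training time: margins are
#' measured on deterministic pseudo-random letter strings (which carry no
#' language signal) and the threshold is set at their 99th absolute
#' percentile, so near-random text returns `"und"`.
#'
#' @param texts Character vector of training texts.
#' @param labels Language label per text (e.g. `"en"`, `"sw"`).
#' @param ngram_range Inclusive `(min, max)` character n-gram lengths.
#' @param smoothing Additive smoothing constant (> 0), default 0.5.
#' @param threshold Optional fixed reliability threshold; if `NULL`,
#'   calibrated as described above.
#' @return A `language_model`.
#' @export
train_language_model <- function(texts, labels, ngram_range = c(2, 4),
                                 smoothing = 0.5, threshold = NULL) {
  stopifnot(length(texts) == length(labels), length(ngram_range) == 2,
            ngram_range[1] >= 1, ngram_range[2] >= ngram_range[1],
            smoothing > 0)
  languages <- sort(unique(as.character(labels)))
  if (length(languages) < 2) {
    .chatmine_abort("Need at least two languages to train",
                    "chatmine_training_error")
  }
  cleaned <- .lm_clean(texts)
  by_lang <- split(cleaned, as.character(labels))
  empty <- names(by_lang)[!vapply(by_lang, function(v) any(nzchar(v)),
                                  logical(1))]
  if (length(empty) > 0) {
    .chatmine_abort(
      paste0("No training text for language(s): ",
             paste(empty, collapse = ", ")),
      "chatmine_training_error"
    )
  }
  gram_counts <- lapply(by_lang, function(v) {
    grams <- unlist(lapply(v, .char_ngrams, ngram_range[1], ngram_range[2]),
                    use.names = FALSE)
    table(grams)
  })
  vocab <- sort(unique(unlist(lapply(gram_counts, names), use.names = FALSE)))
  V <- length(vocab)
  log_probs <- list()
  unseen <- numeric(0)
  for (lang in languages) {
    cnt <- rep(0, V)
    names(cnt) <- vocab
    tc <- gram_counts[[lang]]
    cnt[names(tc)] <- as.numeric(tc)
    denom <- sum(cnt) + smoothing * (V + 1)
    log_probs[[lang]] <- log((cnt + smoothing) / denom)
    unseen[lang] <- log(smoothing / denom)
  }
  priors <- log(table(factor(as.character(labels), levels = languages)) /
                  length(labels))
  priors <- setNames(as.numeric(priors), languages)

  model <- structure(list(
    languages = languages,
    ngram_range = as.integer(ngram_range),
    smoothing = smoothing,
    log_probs = log_probs,
    unseen = unseen,
    priors = priors,
    threshold = 0,
    version = 1L
  ), class = "language_model")

  if (is.null(threshold)) {
    alphabet <- sort(unique(unlist(strsplit(
      gsub(" ", "", cleaned[nzchar(cleaned)]), ""), use.names = FALSE)))
    margins <- .with_local_seed(20170938L, {
      noise <- vapply(1:400, function(i) {
        paste(sample(alphabet, sample(10:60, 1), replace = TRUE),
              collapse = "")
      }, character(1))
      abs(.lm_score(model, noise)$margin)
    })
    threshold <- max(quantile(margins, 0.99, names = FALSE), 1e-8)
  }
  model$threshold <- threshold
  model
}

#' @export
print.language_model <- function(x, ...) {
  cat("<language_model>", paste(x$languages, collapse = "/"),
      sprintf("char %d-%d-grams, smoothing %.2f, threshold %.4g\n",
              x$ngram_range[1], x$ngram_range[2], x$smoothing, x$threshold))
  invisible(x)
}

# Vectorized scoring: per text, per-character mean log-likelihood margin
# between the best and second-best language (0 when no modeled n-grams).
.lm_score <- function(model, texts) {
  cleaned <- .lm_clean(texts)
  gram_list <- lapply(cleaned, .char_ngrams,
                      model$ngram_range[1], model$ngram_range[2])
  lens <- lengths(gram_list)
  idx <- rep.int(seq_along(gram_list), lens)
  grams <- unlist(gram_list, use.names = FALSE)
  n_texts <- length(texts)
  ll <- matrix(rep(model$priors, each = n_texts), nrow = n_texts,
               dimnames = list(NULL, model$languages))
  if (length(grams) > 0) {
    for (lang in model$languages) {
      lp <- unname(model$log_probs[[lang]][grams])
      lp[is.na(lp)] <- model$unseen[[lang]]
      sums <- rowsum(lp, idx)
      ll[as.integer(rownames(sums)), lang] <-
        ll[as.integer(rownames(sums)), lang] + sums[, 1]
    }
  }
  # margin normalized per modeled character position
  ord <- t(apply(ll, 1, sort, decreasing = TRUE))
  denom <- pmax(lens, 1)
  margin <- unname((ord[, 1, drop = TRUE] - ord[, 2, drop = TRUE]) / denom)
  best <- model$languages[max.col(ll, ties.method = "first")]
  tie <- abs(ll - ll[cbind(seq_len(n_texts),
                           max.col(ll, ties.method = "first"))]) < 1e-12
  n_best <- rowSums(tie)
  margin[lens == 0] <- 0
  tibble(label = best, margin = margin, n_grams = lens, n_best = n_best)
}

#' Detect the language of texts
#'
#' Total and deterministic: every input receives a label in the model's
#' language set or `"und"`. `"und"` is returned for empty text, text with no
#' modeled n-grams (e.g. digits-only), or a per-character log-likelihood
#' margin below the model's reliability threshold.
#'
#' @param model A [train_language_model()] fit.
#' @param texts Character vector.
#' @return A tibble with columns `label` and `score` (the margin).
#' @export
detect_language <- function(model, texts) {
  stopifnot(inherits(model, "language_model"))
  if (length(texts) == 0) return(tibble(label = character(), score = numeric()))
  sc <- .lm_score(model, texts)
  und <- sc$n_grams == 0 | sc$margin < model$threshold | sc$n_best > 1
  tibble(label = ifelse(und, "und", sc$label),
         score = ifelse(sc$n_grams == 0, 0, sc$margin))
}

#' Label message languages in a corpus
#'
#' Applies [detect_language()] to message bodies and writes the result into
#' the `language` column. By default only inbound (user-authored) messages
#' are labeled, matching the downstream analyses.
#'
#' @param x A [corpus()].
#' @param model A `language_model`.
#' @param which `"inbound"`, `"outbound"` or `"both"`.
#' @return The corpus with `language` filled in.
#' @export
detect_corpus_language <- function(x, model, which = "inbound") {
  stopifnot(inherits(x, "chat_corpus"))
  sel <- switch(which,
    inbound = x$messages$direction == "inbound",
    outbound = x$messages$direction == "outbound",
    both = rep(TRUE, nrow(x$messages)),
    .chatmine_abort("which must be inbound/outbound/both",
                    "chatmine_parameter_error")
  )
  if (any(sel)) {
    x$messages$language[sel] <- detect_language(model,
                                                x$messages$body[sel])$label
  }
  x
}

.iso_week_key <- function(ts) {
  sprintf("%d-W%02d", isoyear(ts), isoweek(ts))
}

.modal_label <- function(labels) {
  # unique modal non-und label, or NA on tie/absence
  labels <- labels[labels %in% c("en", "sw")]
  if (length(labels) == 0) return(NA_character_)
  tab <- table(labels)
  top <- names(tab)[tab == max(tab)]
  if (length(top) == 1) top else NA_character_
}

#' Impute undetected message languages from weekly usage
#'
#' Inbound messages labeled `"und"` are relabeled to the dominant (modal)
#' detected language among the same user's inbound messages in the same ISO
#' calendar week. A user who sent ten messages in a week — six English, two
#' Swahili, two undetected — has the two undetected messages set to English.
#' When the week has no detected-language message, or the weekly mode is
#' tied, the user's overall dominant detected language across the corpus is
#' used; if that is also tied or absent, the label stays `"und"`. Non-`und`
#' labels and outbound messages are never touched, so the operation is
#' idempotent.
#'
#' @param x A [corpus()] whose inbound messages carry detected labels.
#' @return The corpus with imputed labels.
#' @export
impute_weekly_language <- function(x) {
  stopifnot(inherits(x, "chat_corpus"))
  m <- x$messages
  inb <- m$direction == "inbound"
  if (!any(inb)) return(x)
  lang <- m$language
  lang[inb & is.na(lang)] <- "und"
  week <- .iso_week_key(m$timestamp)

  target <- which(inb & lang == "und")
  if (length(target) == 0) {
    x$messages$language <- lang
    return(x)
  }
  inb_idx <- which(inb)
  df <- tibble(user = m$user_id[inb_idx], week = week[inb_idx],
               lab = lang[inb_idx])
  weekly <- df |>
    group_by(.data$user, .data$week) |>
    summarise(modal = .modal_label(.data$lab), .groups = "drop")
  overall <- df |>
    group_by(.data$user) |>
    summarise(modal = .modal_label(.data$lab), .groups = "drop")

  key <- paste(m$user_id[target], week[target])
  wk_mode <- weekly$modal[match(key, paste(weekly$user, weekly$week))]
  ov_mode <- overall$modal[match(m$user_id[target], overall$user)]
  imputed <- ifelse(!is.na(wk_mode), wk_mode,
                    ifelse(!is.na(ov_mode), ov_mode, "und"))
  lang[target] <- imputed
  x$messages$language <- lang
  x
}

#' Inbound language mix
#'
#' Percent shares of inbound messages by final language label.
#'
#' @param x A [corpus()] with labeled inbound messages.
#' @return A tibble with columns `language`, `n`, `pct` (shares sum to 100).
#' @export
language_mix <- function(x) {
  stopifnot(inherits(x, "chat_corpus"))
  inb <- x$messages[x$messages$direction == "inbound", ]
  if (nrow(inb) == 0) {
    .chatmine_abort("No inbound messages", "chatmine_empty_input")
  }
  lab <- ifelse(is.na(inb$language), "und", inb$language)
  tab <- table(factor(lab, levels = c("en", "sw", "und")))
  tibble(language = names(tab), n = as.integer(tab),
         pct = 100 * as.integer(tab) / sum(tab))
}

#' Preference/detection discordance
#'
#' A message is discordant when its final language differs from its sender's
#' stated language preference, both being known (labels `"und"` and unknown
#' preferences are excluded from the denominators). Reported at the message
#' level (percent of inbound messages discordant) and the user level
#' (percent of users with at least one discordant message).
#'
#' @param x A [corpus()] with labeled inbound messages.
#' @return A list: `pct_messages_discordant`, `pct_users_any_discordant`,
#'   `n_messages`, `n_users`, and `defined` (`FALSE` when the denominators
#'   are empty, e.g. no user has a known preference).
#' @export
discordance <- function(x) {
  stopifnot(inherits(x, "chat_corpus"))
  inb <- x$messages[x$messages$direction == "inbound", ]
  pref <- setNames(x$users$language_preference, x$users$user_id)
  p <- unname(pref[inb$user_id])
  known <- !is.na(inb$language) & inb$language %in% c("en", "sw") &
    p %in% c("en", "sw")
  if (!any(known)) {
    return(list(pct_messages_discordant = NA_real_,
                pct_users_any_discordant = NA_real_,
                n_messages = 0L, n_users = 0L, defined = FALSE))
  }
  disc <- inb$language[known] != p[known]
  by_user <- tapply(disc, inb$user_id[known], any)
  list(
    pct_messages_discordant = 100 * mean(disc),
    pct_users_any_discordant = 100 * mean(by_user),
    n_messages = sum(known),
    n_users = length(by_user),
    defined = TRUE
  )
}

#' Write / read a language model as portable JSON
#'
#' @param model A `language_model`.
#' @param path File path.
#' @return `read_language_model()` returns the model; classifications are
#'   identical before and after a round trip.
#' @export
write_language_model <- function(model, path) {
  stopifnot(inherits(model, "language_model"))
  payload <- list(
    format_version = model$version,
    languages = model$languages,
    ngram_range = model$ngram_range,
    smoothing = model$smoothing,
    threshold = model$threshold,
    priors = as.list(model$priors),
    unseen = as.list(model$unseen),
    log_probs = lapply(model$log_probs, as.list)
  )
  write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(model)
}

#' @rdname write_language_model
#' @export
read_language_model <- function(path) {
  payload <- read_json(path, simplifyVector = FALSE)
  to_named <- function(lst) setNames(vapply(lst, as.numeric, numeric(1)),
                                     names(lst))
  structure(list(
    languages = vapply(payload$languages, as.character, character(1)),
    ngram_range = vapply(payload$ngram_range, as.integer, integer(1)),
    smoothing = as.numeric(payload$smoothing),
    log_probs = lapply(payload$log_probs, to_named),
    unseen = to_named(payload$unseen),
    priors = to_named(payload$priors),
    threshold = as.numeric(payload$threshold),
    version = as.integer(payload$format_version)
  ), class = "language_model")
}

#' Train the packaged default English/Swahili model
#'
#' Convenience wrapper that trains on the packaged English and Swahili seed
#' corpora shipped under `inst/extdata/` (one sentence per line).
#'
#' @param ... Passed to [train_language_model()].
#' @return A `language_model`.
#' @export
train_default_model <- function(...) {
  en <- readLines(system.file("extdata", "seed_en.txt", package = "chatmine"),
                  encoding = "UTF-8", warn = FALSE)
  sw <- readLines(system.file("extdata", "seed_sw.txt", package = "chatmine"),
                  encoding = "UTF-8", warn = FALSE)
  en <- en[nzchar(trimws(en))]
  sw <- sw[nzchar(trimws(sw))]
  train_language_model(c(en, sw), c(rep("en", length(en)),
                                    rep("sw", length(sw))), ...)
}
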