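# Intent-label adjudication: each user question is presented to raters
# until two *different* raters have given the same label; that label, at the
# earliest presentation where the second assignment occurs, is final.

.resolve_events_one <- function(rater_id, intent_label, sequence_index) {
  ord <- order(sequence_index)
  rater <- rater_id[ord]
  label <- intent_label[ord]
  idx <- sequence_index[ord]
  if (anyDuplicated(idx) > 0) {
    .chatmine_abort("Duplicate sequence_index within a question",
                    "chatmine_integrity_error")
  }
  raters_by_label <- list()
  for (i in seq_along(label)) {
    seen <- raters_by_label[[label[i]]]
    if (!is.null(seen) && any(seen != rater[i])) {
      first_rater <- seen[seen != rater[i]][1]
      return(list(final_label = label[i], n_presentations = idx[i],
                  rater_a = first_rater, rater_b = rater[i],
                  resolved = TRUE))
    }
    raters_by_label[[label[i]]] <- unique(c(seen, rater[i]))
  }
  list(final_label = NA_character_, n_presentations = idx[length(idx)],
       rater_a = NA_character_, rater_b = NA_character_, resolved = FALSE)
}

#' Resolve intent labels by double agreement
#'
#' For each question, scans the label events in presentation order and
#' fixes the final label as the first label to have been assigned by two
#' distinct raters, resolved at the earliest presentation where that second
#' assignment occurs. The same rater repeating a label does not count.
#' Questions whose event sequence never reaches agreement are unresolved.
#' Resolution is deterministic, and events after the resolving presentation
#' can never change the final label.
#'
#' @param events Tibble with columns `question_id`, `rater_id`,
#'   `intent_label`, `sequence_index` (unique per question, starting at 1).
#' @return A tibble `question_id`, `final_label` (`NA` if unresolved),
#'   `n_presentations`, `rater_a`, `rater_b`, `resolved`.
#' @export
resolve_double_agreement <- function(events) {
  events <- as_tibble(events)
  needed <- c("question_id", "rater_id", "intent_label", "sequence_index")
  stopifnot(all(needed %in% names(events)))
  if (any(!nzchar(events$rater_id) | is.na(events$rater_id))) {
    .chatmine_abort("rater_id must be non-empty",
                    "chatmine_integrity_error")
  }
  events |>
    group_by(.data$question_id) |>
    summarise(
      res = list(.resolve_events_one(.data$rater_id, .data$intent_label,
                                     .data$sequence_index)),
      .groups = "drop"
    ) |>
    mutate(
      final_label = map_chr(.data$res, "final_label"),
      n_presentations = map_int(.data$res, function(r)
        as.integer(r$n_presentations)),
      rater_a = map_chr(.data$res, "rater_a"),
      rater_b = map_chr(.data$res, "rater_b"),
      resolved = map_lgl(.data$res, "resolved")
    ) |>
    select(-"res")
}

#' Intent distributions by margin
#'
#' Percent shares of resolved intents, overall and optionally by user sex
#' and by marketing status of the intent. Unresolved questions are excluded
#' from every denominator and reported as a count; shares sum to 100% on
#' each margin.
#'
#' @param resolutions Output of [resolve_double_agreement()].
#' @param questions Optional tibble `question_id`, `user_id` linking
#'   questions to users (needed for the by-sex margin).
#' @param users Optional user table with `user_id`, `sex`.
#' @param marketed Optional tibble `intent_label`, `marketed` (logical) or
#'   a named logical vector.
#' @return A list: `overall`, optionally `by_sex` and `by_marketed`
#'   (tibbles of shares), plus `n_resolved` and `n_unresolved`.
#' @export
intent_distribution <- function(resolutions, questions = NULL, users = NULL,
                                marketed = NULL) {
  res <- as_tibble(resolutions)
  resolved <- res[res$resolved, ]
  if (nrow(resolved) == 0) {
    .chatmine_abort("No resolved questions", "chatmine_empty_input")
  }
  share_tab <- function(labels, extra = NULL) {
    tab <- table(labels)
    out <- tibble(intent_label = names(tab), n = as.integer(tab),
                  pct = 100 * as.integer(tab) / sum(tab))
    if (!is.null(extra)) out <- bind_cols(extra[rep(1, nrow(out)), ], out)
    out[order(-out$n, out$intent_label), ]
  }
  out <- list(
    overall = share_tab(resolved$final_label),
    n_resolved = nrow(resolved),
    n_unresolved = sum(!res$resolved)
  )
  if (!is.null(questions) && !is.null(users)) {
    q <- as_tibble(questions)
    u <- as_tibble(users)
    uid <- q$user_id[match(resolved$question_id, q$question_id)]
    sex <- u$sex[match(uid, u$user_id)]
    sex <- ifelse(sex %in% c("female", "male"), sex, "missing")
    out$by_sex <- bind_rows(lapply(unique(sex), function(s) {
      share_tab(resolved$final_label[sex == s], tibble(sex = s))
    }))
  }
  if (!is.null(marketed)) {
    if (is.data.frame(marketed)) {
      mk <- setNames(marketed$marketed, marketed$intent_label)
    } else {
      mk <- marketed
    }
    flag <- unname(mk[resolved$final_label])
    flag <- ifelse(is.na(flag), FALSE, flag)
    out$by_marketed <- bind_rows(
      share_tab(resolved$final_label[flag], tibble(marketed = TRUE)),
      share_tab(resolved$final_label[!flag], tibble(marketed = FALSE))
    )
  }
  out
}
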