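# Synthetic two-way chat corpus generator. Emulates the statistical
# structure the analyses assume -- demographics, heavy-tailed per-user
# message counts, bilingual code-switching with occasional undetectable
# messages, engagement patterns, cohort-specific vocabularies, agent
# replies -- and returns row-for-row ground truth so every pipeline stage
# can be checked by parameter recovery.

# Parent (mu, sigma) of a normal truncated to [lo, hi] whose *realized*
# truncated distribution has the requested mean and sd.
.solve_truncnorm <- function(mean_target, sd_target, lo, hi) {
  moments <- function(mu, sigma) {
    a <- (lo - mu) / sigma
    b <- (hi - mu) / sigma
    Z <- pnorm(b) - pnorm(a)
    m <- mu + sigma * (dnorm(a) - dnorm(b)) / Z
    v <- sigma^2 * (1 + (a * dnorm(a) - b * dnorm(b)) / Z -
                      ((dnorm(a) - dnorm(b)) / Z)^2)
    c(m, sqrt(v))
  }
  # nested root search keeps the parent parameters in the unimodal regime
  mu_for <- function(sigma) {
    stats::uniroot(function(mu) moments(mu, sigma)[1] - mean_target,
                   lower = lo - 3 * sigma, upper = hi,
                   tol = 1e-10)$root
  }
  sigma <- stats::uniroot(function(s) moments(mu_for(s), s)[2] - sd_target,
                          lower = sd_target / 3, upper = 3 * sd_target,
                          tol = 1e-10)$root
  list(mu = mu_for(sigma), sigma = sigma)
}

.rtruncnorm <- function(n, mu, sigma, lo, hi) {
  p_lo <- pnorm(lo, mu, sigma)
  p_hi <- pnorm(hi, mu, sigma)
  qnorm(runif(n, p_lo, p_hi), mu, sigma)
}

# Zero-truncated negative binomial with E[X | X > 0] = mean_target and
# P(X = 1 | X > 0) = p_one_target (two constraints, two parameters).
.solve_ztnb <- function(mean_target, p_one_target) {
  tmean <- function(mu, size) {
    mu / (1 - dnbinom(0, size = size, mu = mu))
  }
  tp1 <- function(mu, size) {
    dnbinom(1, size = size, mu = mu) /
      (1 - dnbinom(0, size = size, mu = mu))
  }
  # the truncated mean is increasing in mu at fixed size
  mu_for <- function(size) {
    stats::uniroot(function(mu) tmean(mu, size) - mean_target,
                   lower = 1e-6, upper = mean_target * 3,
                   tol = 1e-10)$root
  }
  size <- stats::uniroot(function(s) tp1(mu_for(s), s) - p_one_target,
                         lower = 0.02, upper = 50, tol = 1e-10)$root
  list(mu = mu_for(size), size = size)
}

.rztnb_ge2 <- function(n, mu, size) {
  # ztNB conditioned on X >= 2, by rejection
  out <- integer(0)
  while (length(out) < n) {
    draw <- rnbinom(max(2 * (n - length(out)), 16), size = size, mu = mu)
    out <- c(out, draw[draw >= 2])
  }
  out[seq_len(n)]
}

.typo <- function(words) {
  # drop one interior letter of one eligible word per body (edit distance 1)
  vapply(words, function(body) {
    toks <- strsplit(body, " ", fixed = TRUE)[[1]]
    ok <- which(nchar(toks) >= 5)
    if (length(ok) == 0) return(body)
    j <- ok[sample.int(length(ok), 1)]
    w <- strsplit(toks[j], "")[[1]]
    k <- 1 + sample.int(length(w) - 2, 1)
    toks[j] <- paste(w[-k], collapse = "")
    paste(toks, collapse = " ")
  }, character(1), USE.NAMES = FALSE)
}

#' Generator configuration
#'
#' Defaults mirror the study conditions the analyses assume: 63.2% female
#' users; ages truncated-normal on \[15, 65\] with realized mean 22.5 and SD
#' 6.4; 46.7% stated English preference; heavy-tailed per-user inbound
#' counts (zero-truncated negative binomial, median 2, mean 3.1);
#' engagement-pattern shares 40/9/46 for the three dominant patterns plus a
#' 2/3 split of the residual; a 1.7 male/female single-message rate ratio;
#' per-preference language mixes with 2% undetectable messages; Table-1-like
#' missingness of recorded sex (44.7%), age (49.2%) and preference (1.1%).
#'
#' @param n_users Number of users.
#' @param female_share,english_pref_share True attribute probabilities.
#' @param age_mean,age_sd,age_range Realized age moments and truncation.
#' @param messages_mean Target mean inbound messages per user.
#' @param pattern_shares Named shares for the five engagement patterns
#'   (must sum to 1).
#' @param single_message_sex_ratio Male/female ratio of the
#'   single-in/single-out probability.
#' @param language_mix List with per-preference `(en, sw, und)` message
#'   probabilities: elements `en` and `sw`.
#' @param switcher_share Share of users who ever code-switch; deviations
#'   from the stated preference are concentrated in this subset with the
#'   per-message rate scaled to preserve the marginal `language_mix`.
#' @param misspell_prob Probability an English body carries one typo.
#' @param missing_sex,missing_age,missing_pref Recording missingness.
#' @param period_start,period_end Corpus span (Dates).
#' @param n_agents Number of reply agents.
#' @param topic_lexicons Cohort phrase pools, see
#'   [default_topic_lexicons()].
#' @param seed Integer seed; generation is fully reproducible given it.
#' @return A validated `generator_config`.
#' @export
generator_config <- function(
    n_users = 1000,
    female_share = 0.632,
    age_mean = 22.5, age_sd = 6.4, age_range = c(15, 65),
    english_pref_share = 0.467,
    messages_mean = 3.1,
    pattern_shares = c(single_in_single_out = 0.40,
                       multi_in_single_out = 0.09,
                       multi_in_multi_out = 0.46,
                       single_in_multi_out = 0.02,
                       no_reply = 0.03),
    single_message_sex_ratio = 1.7,
    language_mix = list(en = c(en = 0.93, sw = 0.05, und = 0.02),
                        sw = c(en = 0.25, sw = 0.73, und = 0.02)),
    switcher_share = 0.3,
    misspell_prob = 0.05,
    missing_sex = 0.447, missing_age = 0.492, missing_pref = 0.011,
    period_start = as.Date("2017-09-18"),
    period_end = as.Date("2019-01-28"),
    n_agents = 18,
    topic_lexicons = default_topic_lexicons(),
    seed = 1) {
  cfg <- as.list(environment())
  probs <- c(female_share, english_pref_share, misspell_prob,
             missing_sex, missing_age, missing_pref,
             pattern_shares, unlist(language_mix))
  bad <- character(0)
  if (any(probs < 0 | probs > 1)) bad <- c(bad, "probabilities in [0, 1]")
  if (abs(sum(pattern_shares) - 1) > 1e-8) {
    bad <- c(bad, "pattern_shares must sum to 1")
  }
  if (!setequal(names(pattern_shares), .pattern_levels)) {
    bad <- c(bad, "pattern_shares must name the five patterns")
  }
  for (p in c("en", "sw")) {
    if (abs(sum(language_mix[[p]]) - 1) > 1e-8) {
      bad <- c(bad, paste0("language_mix$", p, " must sum to 1"))
    }
  }
  if (n_users < 1) bad <- c(bad, "n_users >= 1")
  if (messages_mean <= 1) bad <- c(bad, "messages_mean > 1")
  if (single_message_sex_ratio <= 0) {
    bad <- c(bad, "single_message_sex_ratio > 0")
  }
  if (length(bad) > 0) {
    .chatmine_abort(paste0("Invalid generator config: ",
                           paste(bad, collapse = "; ")),
                    "chatmine_parameter_error")
  }
  structure(cfg, class = "generator_config")
}

#' Generate a synthetic corpus with ground truth
#'
#' Draws users, per-user inbound message counts, engagement-pattern reply
#' counts, per-message true languages and phrase-bag bodies from the
#' configured cohort lexicons (undetectable messages get digit/emoticon
#' bodies, so the language detector genuinely fails on them rather than
#' being told to), plus agent replies. Deterministic given `config$seed`.
#'
#' @param config A [generator_config()].
#' @return A list: `corpus` (a [corpus()] whose user table carries the
#'   *recorded*, partially missing attributes) and `truth` (realized
#'   attributes, per-message true language, true engagement pattern).
#' @export
generate_corpus <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  n <- config$n_users
  shares <- config$pattern_shares

  # --- users ------------------------------------------------------------
  user_id <- sprintf("u%06d", seq_len(n))
  sex <- ifelse(runif(n) < config$female_share, "female", "male")
  age_par <- .solve_truncnorm(config$age_mean, config$age_sd,
                              config$age_range[1], config$age_range[2])
  age <- .rtruncnorm(n, age_par$mu, age_par$sigma,
                     config$age_range[1], config$age_range[2])
  pref <- ifelse(runif(n) < config$english_pref_share, "en", "sw")

  # --- inbound counts & engagement patterns -----------------------------
  # The single-sender mass is the single-inbound pattern mass (no-reply
  # users are realized as multi-senders); the count model is a
  # zero-truncated negative binomial pinned to the configured mean with
  # P(N = 1) equal to that mass, so engagement shares and the count
  # distribution stay mutually consistent. The per-sex single-sender
  # probability realizes the configured male/female rate ratio while
  # preserving the overall mass.
  p_single <- shares[["single_in_single_out"]] +
    shares[["single_in_multi_out"]]
  r <- config$single_message_sex_ratio
  w_f <- config$female_share
  q_f <- p_single / (w_f + r * (1 - w_f))
  q_m <- min(r * q_f, 1)
  single <- runif(n) < ifelse(sex == "female", q_f, q_m)

  nb <- tryCatch(.solve_ztnb(config$messages_mean, p_single),
                 error = function(e) .chatmine_abort(
                   paste0("No zero-truncated negative binomial has mean ",
                          config$messages_mean, " with P(N=1) = ", p_single,
                          "; adjust messages_mean or pattern_shares"),
                   "chatmine_parameter_error"))
  n_in <- integer(n)
  n_in[single] <- 1L
  n_in[!single] <- .rztnb_ge2(sum(!single), nb$mu, nb$size)

  cond_single <- c(
    single_in_single_out = shares[["single_in_single_out"]],
    single_in_multi_out = shares[["single_in_multi_out"]]
  ) / p_single
  cond_multi <- c(
    multi_in_single_out = shares[["multi_in_single_out"]],
    multi_in_multi_out = shares[["multi_in_multi_out"]],
    no_reply = shares[["no_reply"]]
  ) / (1 - p_single)
  pattern <- character(n)
  pattern[single] <- sample(names(cond_single), sum(single), TRUE,
                            prob = cond_single)
  pattern[!single] <- sample(names(cond_multi), sum(!single), TRUE,
                             prob = cond_multi)

  n_out <- integer(n)
  n_out[pattern %in% c("single_in_single_out", "multi_in_single_out")] <- 1L
  multi_out <- pattern %in% c("multi_in_multi_out", "single_in_multi_out")
  n_out[multi_out] <- pmax(2L, n_in[multi_out] - 1L +
                             rpois(sum(multi_out), 1))

  # --- inbound messages -------------------------------------------------
  uidx <- rep.int(seq_len(n), n_in)
  m_total <- length(uidx)
  # Code-switching is user-clustered: only a `switcher_share` subset of
  # users ever deviates from their preference, with a per-message deviation
  # probability scaled so the marginal per-preference language mix equals
  # the configured one.
  mix <- rbind(en = config$language_mix$en, sw = config$language_mix$sw)
  u_mix <- mix[pref[uidx], , drop = FALSE]
  other <- ifelse(pref == "en", "sw", "en")
  dev_marginal <- mix[cbind(pref, other)] / (1 - mix[pref, "und"])
  dev_cond <- dev_marginal / config$switcher_share
  if (any(dev_cond > 1 + 1e-9)) {
    .chatmine_abort(
      "switcher_share too small for the configured language_mix",
      "chatmine_parameter_error")
  }
  switcher <- runif(n) < config$switcher_share
  p_und <- u_mix[, "und"]
  p_dev <- ifelse(switcher[uidx], pmin(1, dev_cond[uidx]), 0)
  draw <- runif(m_total)
  dev_draw <- runif(m_total)
  lang <- ifelse(draw < p_und, "und",
                 ifelse(dev_draw < p_dev, other[uidx], pref[uidx]))

  cohort <- paste(sex, age_band(age))
  lex <- config$topic_lexicons
  body <- character(m_total)
  for (lg in c("en", "sw")) {
    for (ch in unique(cohort)) {
      sel <- which(lang == lg & cohort[uidx] == ch)
      if (length(sel) == 0) next
      pool <- lex[[lg]][[ch]]
      if (is.null(pool)) pool <- unlist(lex[[lg]], use.names = FALSE)
      body[sel] <- paste(sample(pool, length(sel), TRUE),
                         sample(pool, length(sel), TRUE))
    }
  }
  und_sel <- which(lang == "und")
  if (length(und_sel) > 0) {
    kind <- runif(length(und_sel))
    body[und_sel] <- ifelse(
      kind < 0.7, sprintf("07%08d", floor(runif(length(und_sel)) * 1e8)),
      sample(c(":-)", "??", "...", "!!", "... ?"), length(und_sel), TRUE))
  }
  ms <- which(lang == "en" & runif(m_total) < config$misspell_prob)
  if (length(ms) > 0) body[ms] <- .typo(body[ms])

  start <- as.POSIXct(paste(config$period_start, "00:00:00"), tz = "UTC")
  span_secs <- as.numeric(difftime(
    as.POSIXct(paste(config$period_end, "00:00:00"), tz = "UTC"), start,
    units = "secs"))
  user_t0 <- start + runif(n, 0, span_secs * 0.95)
  gap_h <- rexp(m_total, 1 / 5) +
    ifelse(runif(m_total) < 0.12, runif(m_total, 48, 400), 0)
  offset_h <- ave(gap_h, uidx, FUN = cumsum)
  ts_in <- user_t0[uidx] + offset_h * 3600

  inbound <- tibble(
    message_id = sprintf("m%07d", seq_len(m_total)),
    user_id = user_id[uidx],
    direction = "inbound",
    timestamp = ts_in,
    body = body,
    language = NA_character_,
    agent_id = NA_character_
  )

  # --- agent replies ----------------------------------------------------
  oidx <- rep.int(seq_len(n), n_out)
  o_total <- length(oidx)
  out_ts <- vector("list", n)
  first_in <- split(seq_len(m_total), uidx)
  reply_anchor <- unlist(lapply(seq_len(n), function(i) {
    if (n_out[i] == 0) return(numeric(0))
    idxs <- first_in[[as.character(i)]]
    anchors <- idxs[sample.int(length(idxs), n_out[i], replace = TRUE)]
    as.numeric(ts_in[anchors]) + runif(n_out[i], 300, 7200)
  }), use.names = FALSE)
  outbound <- tibble(
    message_id = sprintf("r%07d", seq_len(o_total)),
    user_id = user_id[oidx],
    direction = "outbound",
    timestamp = as.POSIXct(reply_anchor, origin = "1970-01-01", tz = "UTC"),
    body = sample(lex$agents, o_total, TRUE),
    language = NA_character_,
    agent_id = sprintf("a%02d", sample.int(config$n_agents, o_total, TRUE))
  )

  # --- recorded (partially missing) user table --------------------------
  users_obs <- tibble(
    user_id = user_id,
    sex = ifelse(runif(n) < config$missing_sex, "unknown", sex),
    age_years = ifelse(runif(n) < config$missing_age, NA_real_, age),
    language_preference = ifelse(runif(n) < config$missing_pref,
                                 "unknown", pref)
  )

  truth <- list(
    users = tibble(user_id = user_id, sex = sex, age_years = age,
                   language_preference = pref, pattern = pattern,
                   n_inbound = n_in, n_outbound = n_out),
    messages = tibble(message_id = inbound$message_id, language = lang),
    nb_params = nb,
    age_params = age_par
  )
  list(
    corpus = corpus(bind_rows(inbound, outbound), users_obs),
    truth = truth
  )
}

#' Generate intent label events with known truth
#'
#' Emulates the double-agreement labeling protocol: each question is
#' presented to a stream of raters; a rater labels the true intent with
#' probability `1 - disagreement_rate`, otherwise a rater-specific wrong
#' label. Because every wrong label is unique to its rater, two distinct
#' raters can only ever agree on the truth, so resolution recovers the true
#' intent for every resolved question by construction.
#'
#' @param n_questions Number of questions.
#' @param intents Pool of intent labels for the truths.
#' @param disagreement_rate Probability a presentation yields a wrong label.
#' @param n_raters Number of raters.
#' @param max_presentations Presentations before a question is abandoned
#'   (unresolved).
#' @param seed Integer seed.
#' @return A list: `events` (label-event tibble) and `truth` (tibble
#'   `question_id`, `intent_label`).
#' @export
generate_label_events <- function(n_questions = 100,
                                  intents = c("find contraception method",
                                              "side effects", "sti",
                                              "pregnancy", "relationships",
                                              "symptoms"),
                                  disagreement_rate = 0.3,
                                  n_raters = 8,
                                  max_presentations = 12,
                                  seed = 1) {
  stopifnot(disagreement_rate >= 0, disagreement_rate <= 1, n_raters >= 2)
  set.seed(seed)
  qid <- sprintf("q%05d", seq_len(n_questions))
  truth <- sample(intents, n_questions, TRUE)
  rows <- vector("list", n_questions)
  for (i in seq_len(n_questions)) {
    raters <- character(0)
    labels <- character(0)
    label_raters <- list()
    for (k in seq_len(max_presentations)) {
      pool <- sprintf("agent%02d", seq_len(n_raters))
      if (k > 1) pool <- setdiff(pool, raters[k - 1])  # no immediate repeat
      rt <- sample(pool, 1)
      lb <- if (runif(1) < disagreement_rate) paste0("wrong-", rt) else
        truth[i]
      raters[k] <- rt
      labels[k] <- lb
      prev <- label_raters[[lb]]
      done <- !is.null(prev) && any(prev != rt)
      label_raters[[lb]] <- unique(c(prev, rt))
      if (done) break
    }
    rows[[i]] <- tibble(question_id = qid[i], rater_id = raters,
                        intent_label = labels,
                        sequence_index = seq_along(raters))
  }
  list(events = bind_rows(rows),
       truth = tibble(question_id = qid, intent_label = truth))
}

#' Generate coded-conversation tables
#'
#' Emulates a manual coding exercise over segmented conversations: each
#' user message is coded as a question/request (default share 72%) or a
#' residual code; questions receive a category from the six-way scheme
#' (factual-causes, factual-concepts, advice, access, symptoms, other;
#' default shares 48.9/11.2/26.0/1.5/10.6/1.9) and information requests
#' (categories 1-2) carry a myth flag at the configured rate. Each
#' conversation is coded with `1 + Poisson(topics_rate)` topics.
#'
#' @param conversations Conversation table from [segment_conversations()].
#' @param question_share Share of user messages that are questions.
#' @param category_shares Shares over the six question categories.
#' @param myth_rate Myth-flag rate among information requests.
#' @param topics_rate Poisson rate for extra topics per conversation.
#' @param topic_pool Topic labels to draw from.
#' @param seed Integer seed.
#' @return A list: `topics` (tibble `conversation_id`, `topic`) and
#'   `message_codes` (tibble `conversation_id`, `code`, `category`,
#'   `myth_flag`, one row per user message).
#' @export
generate_conversation_codes <- function(
    conversations,
    question_share = 0.72,
    category_shares = c(0.489, 0.112, 0.260, 0.015, 0.106, 0.019),
    myth_rate = 0.047,
    topics_rate = 1.6,
    topic_pool = c("contraception", "fertility", "sti", "relationships",
                   "sex pains", "unsafe days", "menstruation",
                   "emergency contraception", "hiv", "pregnancy",
                   "cancer", "hygiene", "nutrition", "referral"),
    seed = 1) {
  convs <- as_tibble(conversations)
  # printed percentage tables can sum to 100.1 after rounding; renormalize
  stopifnot(abs(sum(category_shares) - 1) < 0.02)
  category_shares <- category_shares / sum(category_shares)
  set.seed(seed)
  n_msg <- convs$n_user_messages
  cid <- rep(convs$conversation_id, n_msg)
  total <- length(cid)
  is_q <- runif(total) < question_share
  code <- ifelse(is_q, "question_request",
                 sample(c("response", "greeting", "other"), total, TRUE,
                        prob = c(0.5, 0.35, 0.15)))
  category <- rep(NA_integer_, total)
  category[is_q] <- sample.int(6, sum(is_q), TRUE, prob = category_shares)
  myth <- rep(FALSE, total)
  info <- !is.na(category) & category %in% 1:2
  myth[info] <- runif(sum(info)) < myth_rate
  n_topics <- pmin(1 + rpois(nrow(convs), topics_rate), length(topic_pool))
  topics <- tibble(
    conversation_id = rep(convs$conversation_id, n_topics),
    topic = unlist(lapply(n_topics, function(k) sample(topic_pool, k)),
                   use.names = FALSE)
  )
  list(
    topics = topics,
    message_codes = tibble(conversation_id = cid, code = code,
                           category = category, myth_flag = myth)
  )
}

.ci_prop <- function(p, n, level = 0.99) {
  z <- qnorm(1 - (1 - level) / 2)
  half <- z * sqrt(p * (1 - p) / n)
  c(p - half, p + half)
}

#' Parameter-recovery report
#'
#' Runs the pipeline stages on a generated corpus and compares the
#' recovered quantities with their configured values: sex share, realized
#' age mean/SD, English-preference share, per-message language mix (on the
#' detected, pre-imputation labels -- imputation deliberately reassigns
#' `und` labels), the five engagement-pattern shares, the male/female
#' single-message rate ratio, and the planted cohort-specific top-ranked
#' term. Interval checks use normal-approximation confidence bounds at
#' `level` around the configured value.
#'
#' @param config The [generator_config()] used.
#' @param generated Output of [generate_corpus()] under `config`.
#' @param model Optional `language_model`; defaults to the packaged
#'   English/Swahili model ([train_default_model()]).
#' @param level Confidence level for the interval checks (default 0.99).
#' @return A tibble `quantity`, `configured`, `recovered`, `lo`, `hi`,
#'   `pass`.
#' @export
recovery_report <- function(config, generated, model = NULL, level = 0.99) {
  stopifnot(inherits(config, "generator_config"))
  x <- generated$corpus
  z <- qnorm(1 - (1 - level) / 2)
  rows <- list()
  add <- function(quantity, configured, recovered, lo, hi) {
    rows[[length(rows) + 1]] <<- tibble(
      quantity = quantity, configured = configured, recovered = recovered,
      lo = lo, hi = hi, pass = recovered >= lo & recovered <= hi)
  }

  known_sex <- x$users$sex[x$users$sex %in% c("female", "male")]
  ci <- .ci_prop(config$female_share, length(known_sex), level)
  add("female_share", config$female_share, mean(known_sex == "female"),
      ci[1], ci[2])

  ages <- x$users$age_years[!is.na(x$users$age_years)]
  half <- z * config$age_sd / sqrt(length(ages))
  add("age_mean", config$age_mean, mean(ages),
      config$age_mean - half, config$age_mean + half)
  half_sd <- z * config$age_sd / sqrt(2 * length(ages))
  add("age_sd", config$age_sd, sd(ages),
      config$age_sd - half_sd, config$age_sd + half_sd)

  known_pref <- x$users$language_preference[
    x$users$language_preference %in% c("en", "sw")]
  ci <- .ci_prop(config$english_pref_share, length(known_pref), level)
  add("english_pref_share", config$english_pref_share,
      mean(known_pref == "en"), ci[1], ci[2])

  # language mix: detected labels vs the preference-weighted configured mix
  if (is.null(model)) model <- train_default_model()
  det <- detect_corpus_language(x, model)
  mix <- language_mix(det)
  p_en_pref <- config$english_pref_share
  expected <- p_en_pref * config$language_mix$en +
    (1 - p_en_pref) * config$language_mix$sw
  n_inb <- sum(mix$n)
  for (lg in c("en", "sw", "und")) {
    ci <- .ci_prop(expected[[lg]], n_inb, level)
    # widen by a 1% detector-error allowance on each side
    add(paste0("language_mix_", lg), expected[[lg]],
        mix$pct[mix$language == lg] / 100,
        ci[1] - 0.01, ci[2] + 0.01)
  }

  eng <- classify_engagement(x)
  n_users <- nrow(eng$records)
  for (p in .pattern_levels) {
    ci <- .ci_prop(config$pattern_shares[[p]], n_users, level)
    add(paste0("share_", p), config$pattern_shares[[p]],
        eng$shares$pct[eng$shares$pattern == p] / 100, ci[1], ci[2])
  }

  rr <- single_message_rate_ratio(eng$records, x$users)
  se_log <- sqrt((1 - rr$male_share) / (rr$n_male * rr$male_share) +
                   (1 - rr$female_share) / (rr$n_female * rr$female_share))
  add("single_message_rate_ratio", config$single_message_sex_ratio,
      rr$ratio,
      config$single_message_sex_ratio * exp(-z * se_log),
      config$single_message_sex_ratio * exp(z * se_log))

  # planted cohort signal: "prostate" tops the oldest-male English ranks
  imp <- impute_weekly_language(det)
  inb <- imp$messages$direction == "inbound" &
    !is.na(imp$messages$language) & imp$messages$language == "en"
  streams <- tokenize(imp$messages$body[inb])
  names(streams) <- imp$messages$message_id[inb]
  stops <- .default_stoplists()
  truth_users <- generated$truth$users
  cohort_corpus <- x
  cohort_corpus$users <- truth_users[, c("user_id", "sex", "age_years",
                                         "language_preference")]
  strat <- stratified_counts(cohort_corpus, streams, strata = "sex_age",
                             stoplists = stops)
  ranks <- forced_rank(strat)
  planted <- ranks[ranks$term == "prostate", ]
  top_in_cohort <- any(planted$stratum == "male 36+" & planted$rank == 1)
  only_there <- all(planted$stratum == "male 36+")
  add("planted_term_top_rank", 1,
      as.numeric(top_in_cohort && only_there), 1, 1)

  bind_rows(rows)
}

#' Packaged default stop lists
#'
#' The shipped English and Swahili stop lists. Counts of stop words are
#' lexicon-version configuration, not constants of the method.
#'
#' @return A list of two [read_stoplist()] tables.
#' @export
default_stoplists <- function() .default_stoplists()

.default_stoplists <- function() {
  list(
    read_stoplist(system.file("extdata", "stop_en.csv",
                              package = "chatmine")),
    read_stoplist(system.file("extdata", "stop_sw.csv",
                              package = "chatmine"))
  )
}
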