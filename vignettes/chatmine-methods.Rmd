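---
title: "Mining two-way health-chat transcripts: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining two-way health-chat transcripts: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chatmine)
```

chatmine analyses transcripts of two-way SMS-style health-information
services: free-form inbound messages from users (here, young Kenyan men and
women asking about reproductive health) answered by live agents. The
pipeline covers language identification for short bilingual messages, token
normalization, frequency and association mining, engagement and
conversation analytics, intent-label adjudication, and privacy-preserving
export. Because raw transcripts of such services cannot be shared, the
package pairs every stage with a synthetic corpus generator that emits
ground truth, so the whole pipeline is validated by parameter recovery
rather than by a frozen fixture.

This vignette documents the models, the tunable parameters and their
defaults, and the design decisions taken where the problem was genuinely
open. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## Language identification

Short chat messages code-switch between English and Swahili, and some
(phone numbers, emoticons) carry no language signal at all. The classifier
is a multinomial naive Bayes over character n-grams:

* the text is lowercased and reduced to letters and spaces, padded with a
  leading/trailing space;
* character 2- to 4-grams are counted per language with additive smoothing
  (default 0.5), giving per-language log-likelihoods plus log-priors;
* the decision margin is the difference between the best and second-best
  log-likelihood, divided by the number of scored n-grams (a per-character
  scale, so long and short messages are comparable).

A message is labeled `und` (undetermined) when it is empty, contains no
modeled n-grams (digits-only bodies), or its margin falls below the
model's *reliability threshold*. The threshold is calibrated during
training: margins are measured on deterministic pseudo-random letter
strings drawn from the training alphabet — strings with no language signal
— and the threshold is their 99th absolute percentile. Near-random text is
therefore labeled `und` rather than guessed, and two identical training
corpora yield a degenerate model that labels everything `und`, which is the
correct limiting behavior. Character 2–4-grams with this threshold are
sufficient for the two study languages; the model file is portable JSON,
and an external detector can be plugged in wherever a `language_model` is
accepted.

**Weekly imputation.** Messages labeled `und` are relabeled to the modal
detected language among the same user's inbound messages in the same
ISO-8601 calendar week (a user who sent six English, two Swahili and two
undetected messages in a week ends the week with eight English labels).
ISO weeks are used because "calendar week" is ambiguous across year
boundaries. Two rules are underdetermined by that description and fixed
here: a tied weekly mode falls back to the user's overall dominant detected
language (the most similar available evidence, with no arbitrary
ordering), and if that is also tied or absent the label stays `und`.
Imputation never touches non-`und` labels or outbound messages, so it is
idempotent.

## Token normalization

The normalization pipeline is `tokenize -> spell-correct -> lemmatize ->
collapse synonyms -> (bigram preemption) -> stop-word filter`. Published
descriptions of such pipelines rarely pin the exact order, and order
changes counts; the order here is fixed, exposed in code, and chosen so
that bigram detection sees the intact adjacency structure (stop words are
removed only from single tokens at tally time, never from inside a
candidate bigram).

* **Tokenization** keeps maximal runs of Unicode letters, lowercased, with
  apostrophes removed and their halves joined (`don't` → `dont`). Digits
  are dropped by default; an `alnum` mode keeps letter-bearing
  alphanumerics (`p2`, `100ksh` — contraceptive brands and prices matter in
  this domain) while still dropping standalone numbers.
* **Spell correction** is deliberately conservative: a suggestion is
  accepted only for tokens appearing fewer than four times in the corpus
  (rare tokens are where typos live; frequent tokens are likelier genuine
  vocabulary), and only for English — Swahili suggestions are never
  accepted because suggestion quality there is too poor to trust. The
  suggestion source is pluggable; the shipped default proposes the
  lexicographically first dictionary word at edit distance 1 from a
  packaged English word list, so tests need no external spell engine.
* **Lemmatization** is table lookup (`periods` → `period`), never suffix
  stripping, to avoid manufacturing non-words; unknown tokens pass
  through. **Synonym collapsing** maps variants to one canonical label
  (`menses` → `period`). Both tables are validated at load to be
  chain-free, which makes application idempotent.
* **Stop lists** ship as data files (an English list of common function
  words plus custom additions, and a Swahili list). Stop-word counts are
  lexicon-version artifacts, so the lists are configuration, not
  constants.

## Frequency tallies with bigram preemption

Key collocations ("family planning", "side effects") should count as one
term, not two. Given a configurable key-bigram set — discoverable from the
corpus as the most frequent adjacent pairs containing no stop word — each
message is scanned greedily left to right: if the token pair at the cursor
is a key bigram, the bigram term is emitted and both tokens are consumed;
otherwise the single token is emitted. Greedy non-overlapping pairing is a
deliberate choice where prose descriptions are silent about overlap: it is
deterministic, and on `[a, a, a]` with key `a a` yields one bigram plus one
single. The scan conserves tokens (singles + 2·bigrams = stream length),
which the tests assert against an independent tiling-enumeration oracle.

Counts can be stratified by sex, sex-by-age cohort (default bands 15–19,
20–24, 25–35, 36+, configurable) or message language; users with unknown
attributes form an explicit `missing` stratum so stratified counts always
marginalize exactly to the pooled counts. Rank charts use *forced ranking*:
ties break lexicographically so each rank is used exactly once.
Privacy-preserving export drops terms with corpus count below 3, the
standard guard against imperfect anonymization leaking through rare
tokens.

## Word associations

Two complementary views: the **directed bigram network** (edges `from →
to` for adjacent pairs above a count floor, stop-word pairs excluded), and
**pairwise phi** between word-presence indicators across *sections*. A
section defaults to one user's pooled inbound messages, because
co-occurrence is meant to capture conversation-level association
regardless of message boundaries. For each pair the 2×2 presence table
over sections gives

$$\phi = \frac{n_{11}n_{00} - n_{10}n_{01}}
{\sqrt{(n_{11}+n_{10})(n_{01}+n_{00})(n_{11}+n_{01})(n_{10}+n_{00})}},$$

identical to the Pearson correlation of the two binary indicators (the
tests verify the equivalence on random configurations). Terms present in
fewer than 20 sections are excluded by default — phi on rare terms is
unstable — and pairs with a zero denominator (a term present in all or no
sections) are omitted rather than forced to zero. Both thresholds are
arguments.

## Engagement, conversations, intents

**Engagement** classifies every user with at least one inbound message by
their inbound/outbound counts into five patterns: (1,1), (>1,1), (>1,>1),
(1,>1) and no-reply. Analyses of such services often report only the first
three; the two residual classes are kept so the classification is an
exhaustive partition whose shares must sum to 100% — a testable
conservation law. The male/female single-message rate ratio is the ratio
of the two conditional (1,1)-shares among known-sex users.

**Conversations** in the source data were delimited by a human coder with
no stated rule. The reproducible proxy here is an inactivity gap: a new
conversation starts when more than `gap_hours` (default 24) elapse between
a user's consecutive messages. Decreasing the gap can only split
conversations, never merge them, and segmentation is a partition — both
properties are tested. Coding itself (topics, six question categories,
myth flags) is input data, mirroring a manually coded archive; the module
defines the schema, the stratified descriptive table, the question-category
distribution (myth share computed among information requests, categories
1–2), and topic co-occurrence over conversations with two or more topics.

**Intent labels** are resolved by double agreement: scanning label events
in presentation order, the final label is the first to have been assigned
by two *distinct* raters, at the earliest presentation where the second
assignment occurs; the same rater repeating a label never counts, and
questions that never reach agreement stay unresolved. Events arriving
after resolution cannot change the outcome. A hypothetical tie — two labels
completing agreement at the same presentation — is impossible because
presentation indices are unique per question, which the loader enforces.

## The synthetic corpus generator

The generator emits the statistical structure the analyses assume, with
defaults fixed at the study conditions: 63.2% female users; ages from a
truncated normal on [15, 65]; 46.7% stated English preference; heavy-tailed
per-user inbound counts with median 2 and mean 3.1; engagement-pattern
shares 40/9/46 (single/single, multi/single, multi/multi) plus a 2/3 split
of the residual into single/multi and no-reply; a 1.7 male/female
single-message rate ratio; per-preference language mixes with 2%
genuinely undetectable messages; and recorded-attribute missingness of
44.7% (sex), 49.2% (age) and 1.1% (preference). Message bodies are bags of
phrases from sex-by-age-cohort lexicons — no grammar, which is sufficient
for every statistic the pipeline computes and keeps the generator
inspectable. Undetectable messages get digit/emoticon bodies so the
detector genuinely fails on them rather than being told to. The term
*prostate* appears only in the oldest-male English lexicon, planting a
cohort-specific signal that the stratified rank analysis must recover.

Several numerical points deserve note:

* **Ages.** The study reports *realized* moments (mean 22.5, SD 6.4), so
  the parent parameters of the truncated normal are solved numerically
  (nested root search on the analytic truncated-normal moments) so that
  the truncated distribution itself has those moments; drawing a truncated
  normal naively with parent parameters 22.5/6.4 would inflate the
  realized mean by over a year.
* **Message counts.** Counts are zero-truncated negative binomial, with
  (mean, P(N=1)) solved numerically; P(N=1) is pinned to the configured
  single-sender pattern mass (0.40 + 0.02 by default) so the count
  distribution and the engagement shares are mutually consistent, and
  no-reply users are realized among multi-senders. No zero-truncated
  negative binomial with truncated mean 3.1 can reach the reported SD of
  4.3 (the supremum is about 3.46 as the size parameter tends to zero), so
  the real counts are more overdispersed than this family allows; the
  generator accepts a realized SD near 3.3, and median 2 / mean 3.1 hold.
* **Language mix and code-switching.** The per-preference mixes are the
  primitive (they subsume a code-switch probability). Deviations from the
  stated preference are concentrated in a configurable 30% subset of
  "switcher" users, with the per-message rate scaled to preserve the
  marginal mix — message-level discordance stays near the study's level
  while user-level discordance drops to a realistic clustered value, which
  i.i.d. per-message switching would roughly double. The three published
  marginals (46.7% English preference, 63% English messages, 14% message
  discordance) cannot all hold without a per-preference volume tilt the
  source does not describe; the defaults keep the preference share and the
  discordance level, and accept an English message share in the high 50s.
* **The sex ratio.** The single-sender probability is tilted by sex around
  the configured overall mass, so the 1.7 ratio is exact in expectation
  while the marginal count distribution is preserved.

**What recovery does and does not show.** The parameter-recovery report
re-runs the pipeline on a generated corpus and checks each recovered
quantity against its configured value with 99% normal-approximation
intervals (the language-mix check compares *detected pre-imputation*
labels against the configured per-message mix, since reassigning `und`
labels is precisely what imputation is for, and allows a one-percentage-
point detector-error margin fixed in advance). Passing shows the pipeline
is internally consistent and statistically calibrated at study scale. It
does not show robustness to what the generator omits: real orthographic
chaos (the bag-of-phrases bodies carry only single-character-deletion
typos), intra-message code-switching, topic drift over time, or
human-coder judgment in conversation delimitation.

## Problem sizes and reproducibility

The acceptance script and the recovery checks run at 10,000 users
(~31,000 inbound messages, ~58,000 total), the scale at which the 99%
interval checks are meaningful for every configured share; the analysis
drivers under `analysis/` use the same scale, and module tests use a few
hundred users. All randomness flows from explicit integer seeds — the
generator, the calibration of the reliability threshold (a fixed internal
seed that restores the caller's RNG state), the samplers — so every
number in the test suite, the drivers and the acceptance output is exactly
reproducible.

## Known limitations

Only English and Swahili (plus `und`) are modeled; there is no per-token
code-switch detection, no Swahili lemmatization (mirroring the source
analysis, which corrected and lemmatized English only), no topic modeling
or embeddings, no significance testing of phi, and no automated topic or
question-category classification — coded tables are inputs. Conversation
counts from the gap rule approximate, but cannot exactly reproduce, manual
delimitation on real data.
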