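---
title: "Event-anchored surveillance of health queries: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Event-anchored surveillance of health queries: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(querysignal)
library(data.table)
```

## The question and the design

Celiac disease presents with a famously heterogeneous mix of intestinal
and extraintestinal symptoms, and diagnosis is often delayed by years.
Search-engine query streams offer a way to observe, at the individual
level, what people were worried about *before* the moment they first
showed interest in celiac disease or the gluten-free diet. `querysignal`
implements a before/after, event-anchored design on per-user query logs:

1. **Index event.** A celiac-related query (CRQ) is any query containing a
   word starting with "celiac" or "gluten". Each user's index time `t0` is
   their first CRQ inside an index month.
2. **Cohort filters.** A user enters the cohort only if (a) they have
   observable history — at least one query of any kind on or before a
   history cutoff, (b) they have a CRQ dated in the index period, and
   (c) they have no CRQ in the washout months immediately before it. The
   washout makes `t0` a plausible *first* expression of interest rather
   than a repeat visit.
3. **Interest labels.** Users whose CRQs all fall on one calendar day have
   *passing* interest; CRQs on more than one day mark *sustained*
   interest, which serves as a proxy for having the condition or caring
   for someone who does. Rare first-person queries ("i have celiac")
   and diagnostic work-up phrases ("marsh score", "duodenal biopsy",
   "tissue transglutaminase"/"ttg", ...) are flagged as corroborating
   signals.
4. **The query-ratio statistic.** For each concept (symptom or condition
   defined by a synonym lexicon), pool over cohort members the number of
   matching queries in the 14 days before `t0` and in the 14 days after,
   and form `QR = n_before / n_after`. Ratios above 1 identify concepts
   searched more in the run-up to the first CRQ.
5. **Temporal profiles.** For one concept, queries of all members are
   binned by whole-day offset from `t0` and the concept's per-day share
   of queries is divided by its overall share, giving a curve whose
   excursions above 1 localize *when* interest rises.
6. **Dietary shift.** Recipe queries are detected (dish synonym plus a
   recipe-intent cue, or an unambiguous multi-word dish name), mapped to
   ingredients, and ranked by the smoothed log-ratio
   `log((n_after + 0.5) / (n_before + 0.5))` across the same windows.
7. **Discrimination check.** Each user is represented by pre-`t0` counts
   of every symptom and condition concept, and cross-validated AUC
   measures whether those antecedent counts can distinguish user classes
   at all.

## Window conventions and the ratio's denominator

The before window is the half-open interval `[t0 − w, t0)` and the after
window is `(t0, t0 + w]` with `w = 14` days by default; the index query
itself belongs to neither. Two denominator conventions circulate for
before/after statistics: the after window alone, or the union of both
windows. We adopt the **after window alone** as the default. The decisive
observation is arithmetic: with a union denominator the ratio can never
exceed 1, so any reported ratio above 1 (and the interesting ones all
are) must have been computed against the after window. The union variant
remains available via `denominator = "union"` for sensitivity analyses.

Pooling is at the *count* level (sum of counts over members, before and
after, then one ratio), not a mean of per-user ratios: individual users
contribute mostly zero counts, so per-user ratios are dominated by 0/0.

Members whose after window would extend past the end of the log (or
before window past its start) are excluded from pooled counts by the
default `complete-windows` truncation policy. Without it, members
adopting late in the index month would systematically contribute
truncated after windows and inflate every QR. Cohort *identity* is
deliberately independent of this policy: truncation is applied by each
window statistic, not by the cohort filters.

Ratios with a pooled denominator below `min_support` (default 10) are
flagged undefined and excluded from rankings; otherwise concepts with a
handful of stray counts would top every leaderboard. No smoothing is
applied to QR by default (a +0.5 option exists); the dietary-shift score
uses +0.5 smoothing because zero counts on one side are routine and the
smoothed log-ratio stays finite and exactly antisymmetric under swapping
the windows.

## Text handling

All matching operates on normalized text: lowercased, with every run of
non-alphanumeric characters collapsed to one space. This makes
"Gluten-Free!" and "gluten free" identical, which matters because the
hyphenated and spaced forms are both common. Concept matching is
word-boundary phrase matching — "flu" does not match "fluent",
"diarrhea" does not match "cardiarrhea". CRQ detection is the one
deliberate exception: it is prefix-at-word-start ("glutenfree",
"celiacs" count), because users concatenate and inflect these particular
words freely. When one matched synonym is a word-prefix of a longer
matched synonym of a different concept and occurs only inside it, the
longer phrase wins; a query may still match several concepts, and each
concept is counted at most once per query.

The bundled symptom and condition lexicons are small demonstration
dictionaries (a few dozen concepts with common synonyms), not the
hundreds-of-concepts production lists such analyses use; those are
supplied by the user as two-column TSV files. Duplicate synonyms across
concepts are a load-time error rather than a silent tie.

## Eligibility choices worth making explicit

* "Active since" the history cutoff is read as *has at least one query on
  or before* that date. This is the only reading that guarantees the
  washout is observable: a user first seen in the index month has no
  evidence of a clean washout.
* Distinct CRQ days for the passing/sustained label are counted over the
  whole log span, including days after the index month — the definition
  concerns behaviour, not a reporting horizon.
* Ties between CRQs at identical timestamps are broken by file order via
  a stable sort, so `t0` is deterministic.
* Self-identification requires the asserted phrase with no interrogative
  word ("do", "how", "why", ...) anywhere before it in the query, which
  excludes "do i have celiac" while keeping "i have celiac disease can i
  eat rice". This codifies as a rule what would otherwise be a manual
  review step.

## The classifier harness

The discrimination check deliberately mirrors simple practice:
"linear regression" is ordinary least squares on the 0/1 label, used
only to *rank* held-out users (AUC is invariant to monotone transforms
of the score, so OLS is a legitimate scorer even though it is not a
probability model); the alternative is a random forest with 50 trees.
Folds are stratified within class, assigned on users sorted by id under
a fixed seed, so a run is reproducible end to end. Comparison users have
no CRQ and hence no `t0`; they are anchored at pseudo-index dates drawn
uniformly from the target users' `t0` distribution, which censors both
classes' feature streams identically and avoids a trivial
"more history = more counts" artifact. The comparison pool defaults to
five comparison users per target, capped by availability.

## What the simulator emulates — and what it does not

The generator produces per-user streams with exactly the structure the
estimators assume:

* background queries as a per-user Poisson process (`background_rate`
  queries per user-day, default 0.5) over a ten-month span whose last
  month is the index period, phrased from the same lexicons the matcher
  uses, plus non-medical filler;
* an adopter subpopulation (`adopter_fraction`) with `t0` uniform in the
  index month and a first CRQ emitted exactly at `t0`;
* a passing/sustained mixture with `sustained_fraction = 0.07` by
  default — about one adopter in fourteen keeps querying across multiple
  days, the split reported for real CRQ populations; sustained adopters
  add CRQs on `1 + Geometric` extra days (mean 3 CRQ days in total);
* planted pre-window multipliers: inside `[t0 − w, t0)` a concept's
  per-query probability is multiplied by `r`, with query volume
  unchanged, so the estimand of QR for that concept is exactly `r`;
* a post-`t0` shift toward gluten-free recipe queries. Because any
  gluten-free dish query *is* a CRQ, this shift is restricted to
  sustained adopters: giving passing adopters later gluten-free queries
  would silently turn them into multi-day (sustained) users and detach
  the planted labels from what the cohort filters compute. For the same
  reason background users never emit gluten-free dish queries, and the
  generator validates at configuration time that no background phrase is
  celiac-related;
* rare self-identification queries, emitted on the day of `t0` so they
  cannot change a passing label;
* a sustained adopter whose `t0` lands on the last day of the span has no
  room for a second CRQ day and is relabelled passing in the ground
  truth, keeping truth and log consistent.

Timestamps are uniform within the day (no diurnal rhythm — irrelevant to
day-level statistics), queries carry one concept each apart from
deliberate multi-concept templates, and the text is template-generated,
not natural language. Passing the parameter-recovery suite therefore
shows that the estimators are correct *under the assumed structure*; it
does not certify behaviour under bursty sessions, bot traffic,
misspellings, or concept co-occurrence, none of which the generator
produces. Duplicate identical queries are kept throughout (a user may
genuinely repeat a query, and the statistics count queries, not users).

## Validation sizes and numerical choices

The test suite validates each estimator against an independent
brute-force oracle (positional-scan matcher, literal per-user cohort
scan, double-loop window counter) on dozens of small random logs, and
runs parameter recovery at sizes chosen so the Monte-Carlo standard
errors are informative: planted multipliers `r ∈ {1.5, 2, 3}` are
recovered within `3·SE` with pooled after-window counts above 10³
(about 3,000 simulated users); null calibration uses 20 concepts with
≥500 pooled counts each; classifier calibration uses about 2,000 users
(shuffled labels must stay at chance, a planted 5× pre-window elevation
on three concepts must be detected); the dietary-shift check uses 20
seeded runs of 400 all-adopter users. The delta-method standard error
`QR·sqrt(1/n_before + 1/n_after)` is used for ratio comparisons.

Degenerate inputs are contracts, not errors: an empty log yields an
empty cohort and empty outputs; a concept never queried yields an empty
temporal profile (its baseline share is zero, so no ratio is defined);
undefined ratios are reported but excluded from rankings; a classifier
class that is absent is a fatal error, a class that is merely small
skips the stage with a reason in its output. Rankings break ties by
support and then lexicographically, so output order never depends on
hash order or input order.

## Limitations

Sustained interest is a behavioural proxy, not a diagnosis; nothing here
distinguishes celiac disease from non-celiac gluten sensitivity or from
caregiving. Query ratios are descriptive — the package deliberately
reports raw ratios without confidence intervals or multiple-testing
machinery, because the design's strength is ranking and temporal
alignment, not hypothesis testing. Zip codes are carried through
ingestion but never analysed. The log is processed in memory; spans of
hundreds of millions of queries would need chunked processing that this
package does not promise.
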