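#' Is a query celiac-related (a CRQ)?
#'
#' A celiac-related query (CRQ) is any query containing a word that begins
#' with "celiac" or "gluten". Prefix matching at word starts means
#' "celiacs", "gluten" and "glutenfree" all qualify while "eggluten" does
#' not.
#'
#' @param norm_text Character vector of normalized query text.
#' @return Logical vector.
#' @examples
#' is_crq(c("celiac disease symptoms", "gluten free pancakes",
#'          "best pizza near me"))
#' @export
is_crq <- function(norm_text) {
  grepl("(^| )(celiac|gluten)", norm_text)
}

# Query phrases strongly suggestive of celiac diagnosis or work-up.
INDICATOR_PHRASES <- c(
  "marsh score", "duodenal biopsy", "intestinal biopsy", "beyond celiac",
  "celiac disease foundation", "tissue transglutaminase", "ttg",
  "gliadin antibody", "celiac clinical trials", "celiac trials",
  "gluten trials"
)

#' Does a query contain a celiac indicator phrase?
#'
#' Indicator phrases are terms strongly suggestive of a celiac diagnosis or
#' diagnostic work-up: marsh score, duodenal biopsy, intestinal biopsy,
#' beyond celiac, celiac disease foundation, tissue transglutaminase (or its
#' acronym TTG as a standalone word), gliadin antibody, celiac clinical
#' trials, celiac trials, gluten trials. Matching is at word boundaries.
#'
#' @inheritParams is_crq
#' @return Logical vector.
#' @examples
#' is_indicator(c("marsh score 3b meaning", "ttg iga normal range",
#'                "celiac recipes"))
#' @export
is_indicator <- function(norm_text) {
  pad <- pad_words(norm_text)
  out <- rep(FALSE, length(norm_text))
  for (p in INDICATOR_PHRASES) {
    out <- out | grepl(pad_words(p), pad, fixed = TRUE)
  }
  out
}

SELF_ID_PHRASES <- c("i have celiac", "i was diagnosed with celiac")
INTERROGATIVE_WORDS <- c("do", "does", "did", "could", "can", "might",
                         "may", "should", "how", "what", "why", "when")

#' Does a query assert first-person celiac status?
#'
#' True when the query contains "i have celiac" or
#' "i was diagnosed with celiac" and no interrogative trigger word (do,
#' does, did, could, can, might, may, should, how, what, why, when) occurs
#' before the matched phrase — so "do i have celiac" is a question, not a
#' self-identification. When the phrase occurs more than once, one clean
#' occurrence suffices.
#'
#' @inheritParams is_crq
#' @return Logical vector.
#' @examples
#' is_self_identified(c("i have celiac disease can i eat rice",
#'                      "do i have celiac"))
#' @export
is_self_identified <- function(norm_text) {
  pad <- pad_words(norm_text)
  cand <- rep(FALSE, length(norm_text))
  for (p in SELF_ID_PHRASES) {
    cand <- cand | grepl(pad_words(p), pad, fixed = TRUE)
  }
  out <- rep(FALSE, length(norm_text))
  phrase_words <- strsplit(SELF_ID_PHRASES, " ", fixed = TRUE)
  for (i in which(cand)) {
    words <- strsplit(norm_text[i], " ", fixed = TRUE)[[1L]]
    for (pw in phrase_words) {
      L <- length(pw)
      if (length(words) < L) next
      for (s in seq_len(length(words) - L + 1L)) {
        if (!all(words[s:(s + L - 1L)] == pw)) next
        if (s == 1L || !any(words[seq_len(s - 1L)] %in%
                            INTERROGATIVE_WORDS)) {
          out[i] <- TRUE
          break
        }
      }
      if (out[i]) break
    }
  }
  out
}

#' Configuration of the cohort eligibility filters
#'
#' @param index_start,index_end Inclusive date range of the index period —
#'   the month in which a user's first-ever CRQ must occur.
#' @param history_cutoff Users must have at least one query (of any kind) on
#'   or before this date, so that the washout period is observable.
#' @param washout_months Number of months immediately before `index_start`
#'   that must contain zero CRQs.
#' @param window_days Half-window length (days) used by the before/after
#'   statistics downstream.
#' @return A `cohort_config` object.
#' @export
cohort_config <- function(index_start = "2017-10-01",
                          index_end = "2017-10-31",
                          history_cutoff = "2017-09-01",
                          washout_months = 9L,
                          window_days = 14L) {
  cfg <- list(index_start = as.Date(index_start),
              index_end = as.Date(index_end),
              history_cutoff = as.Date(history_cutoff),
              washout_months = as.integer(washout_months),
              window_days = as.integer(window_days))
  if (cfg$index_start > cfg$index_end) stop("index_start after index_end")
  if (cfg$history_cutoff > cfg$index_start) {
    stop("history_cutoff must not be after index_start")
  }
  if (cfg$washout_months < 0L) stop("washout_months must be >= 0")
  if (cfg$window_days < 1L) stop("window_days must be >= 1")
  cfg$washout_start <- months_before(cfg$index_start, cfg$washout_months)
  structure(cfg, class = "cohort_config")
}

#' Apply the eligibility and washout filters and label the cohort
#'
#' A user becomes a cohort member iff they (a) have at least one query of
#' any kind on or before `history_cutoff`, (b) have at least one CRQ dated
#' within the index period, and (c) have zero CRQs in the washout window
#' (the `washout_months` months immediately preceding `index_start`). The
#' index time `t0` is the earliest qualifying CRQ instant; ties at identical
#' timestamps are broken by file order via the stable record sort. The
#' passing/sustained label counts distinct calendar days with at least one
#' CRQ over the entire log: one day is "passing", more than one
#' "sustained" — sustained interest serves as a proxy for having the
#' condition or caring for a patient. Indicator and self-identification
#' flags scan each member's full query stream.
#'
#' @param records Records `data.table` sorted by `(user_id, timestamp)` (as
#'   returned by [read_query_log()] or [generate_logs()]).
#' @param config A [cohort_config()].
#' @return A list of class `cohort`: `members` (a `data.table` with columns
#'   `user_id`, `t0`, `interest` (`"passing"`/`"sustained"`),
#'   `crq_day_count`, `indicator_positive`, `self_identified`) and
#'   `exclusions` (users counted at the first criterion they fail:
#'   `no_history`, `no_index_crq`, `washout_crq`, plus `n_users` and
#'   `n_members`).
#' @export
build_cohort <- function(records, config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  if (!nrow(records)) {
    members <- data.table(user_id = character(),
                          t0 = parse_instant(character()),
                          interest = character(),
                          crq_day_count = integer(),
                          indicator_positive = logical(),
                          self_identified = logical())
    return(structure(list(members = members,
                          exclusions = list(n_users = 0L, no_history = 0L,
                                            no_index_crq = 0L,
                                            washout_crq = 0L,
                                            n_members = 0L)),
                     class = "cohort"))
  }
  d <- data.table(user_id = records$user_id,
                  timestamp = records$timestamp,
                  qdate = instant_date(records$timestamp),
                  crq = is_crq(records$norm_text))
  agg <- d[, .(
    has_history = any(qdate <= config$history_cutoff),
    crq_index = any(crq & qdate >= config$index_start &
                      qdate <= config$index_end),
    crq_washout = any(crq & qdate >= config$washout_start &
                        qdate < config$index_start)
  ), by = user_id]
  agg[, eligible := has_history & crq_index & !crq_washout]

  exclusions <- list(
    n_users = nrow(agg),
    no_history = agg[, sum(!has_history)],
    no_index_crq = agg[, sum(has_history & !crq_index)],
    washout_crq = agg[, sum(has_history & crq_index & crq_washout)],
    n_members = agg[, sum(eligible)]
  )

  member_ids <- agg[eligible == TRUE, user_id]
  if (!length(member_ids)) {
    return(structure(list(members = build_cohort(
      empty_records(), config)$members, exclusions = exclusions),
      class = "cohort"))
  }

  dm <- d[user_id %in% member_ids]
  # earliest CRQ inside the index period; records are sorted stably, so the
  # first row wins timestamp ties by file order
  t0s <- dm[crq & qdate >= config$index_start & qdate <= config$index_end,
            .(t0 = timestamp[1L]), by = user_id]
  days <- dm[crq == TRUE, .(crq_day_count = uniqueN(qdate)), by = user_id]

  rm_idx <- records$user_id %in% member_ids
  flags <- data.table(
    user_id = records$user_id[rm_idx],
    ind = is_indicator(records$norm_text[rm_idx]),
    sid = is_self_identified(records$norm_text[rm_idx])
  )[, .(indicator_positive = any(ind), self_identified = any(sid)),
    by = user_id]

  members <- t0s[days, on = "user_id", nomatch = 0L][
    flags, on = "user_id", nomatch = 0L]
  members[, interest := fifelse(crq_day_count > 1L, "sustained", "passing")]
  setcolorder(members, c("user_id", "t0", "interest", "crq_day_count",
                         "indicator_positive", "self_identified"))
  setorderv(members, "user_id")
  structure(list(members = members, exclusions = exclusions),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  ex <- x$exclusions
  cat(sprintf("<cohort> %d members of %d users\n", ex$n_members,
              ex$n_users))
  cat(sprintf("  excluded: no_history=%d, no_index_crq=%d, washout_crq=%d\n",
              ex$no_history, ex$no_index_crq, ex$washout_crq))
  invisible(x)
}

#' Summarize a cohort the way surveillance studies report it
#'
#' Computes counts and rounded percentages for the passing/sustained
#' interest split (nearest integer percent), and indicator-positive and
#' self-identified rates within each interest class (one decimal at or
#' above 1 percent, two decimals below). Either pass `members` from
#' [build_cohort()], or pass pre-tabulated `counts` — e.g. counts printed in
#' a publication — as a list with elements `total`, `passing`, `sustained`,
#' and optionally `indicator_passing`, `indicator_sustained`,
#' `self_identified_sustained`, `self_identified_total`.
#'
#' @param members A `members` data.table (or a `cohort` object).
#' @param counts Optional list of pre-tabulated counts (overrides
#'   `members`).
#' @return A list of class `cohort_summary` with `counts` and `percent`
#'   components. Percentages are `NA` when the denominator is zero.
#' @examples
#' cohort_summary(counts = list(total = 90142, passing = 83614,
#'                              sustained = 6528))
#' @export
cohort_summary <- function(members = NULL, counts = NULL) {
  if (is.null(counts)) {
    if (inherits(members, "cohort")) members <- members$members
    stopifnot(is.data.frame(members))
    sus <- members$interest == "sustained"
    counts <- list(
      total = nrow(members),
      passing = sum(!sus),
      sustained = sum(sus),
      indicator_passing = sum(members$indicator_positive & !sus),
      indicator_sustained = sum(members$indicator_positive & sus),
      self_identified_sustained = sum(members$self_identified & sus),
      self_identified_total = sum(members$self_identified)
    )
  }
  pct <- function(num, den) {
    if (is.null(num) || is.null(den) || !length(den) || den == 0) {
      return(NA_real_)
    }
    100 * num / den
  }
  percent <- list(
    passing = round(pct(counts$passing, counts$total)),
    sustained = round(pct(counts$sustained, counts$total)),
    indicator_passing = round_rate(pct(counts$indicator_passing,
                                       counts$passing)),
    indicator_sustained = round_rate(pct(counts$indicator_sustained,
                                         counts$sustained)),
    self_identified_sustained = round_rate(
      pct(counts$self_identified_sustained, counts$sustained)),
    self_identified_total = round_rate(pct(counts$self_identified_total,
                                           counts$total))
  )
  structure(list(counts = counts, percent = percent),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  ct <- x$counts; pc <- x$percent
  cat(sprintf("<cohort_summary> %s users with >=1 CRQ\n",
              format(ct$total, big.mark = ",")))
  cat(sprintf("  passing interest:   %s (%s%%)\n",
              format(ct$passing, big.mark = ","), pc$passing))
  cat(sprintf("  sustained interest: %s (%s%%)\n",
              format(ct$sustained, big.mark = ","), pc$sustained))
  if (!is.null(ct$indicator_sustained)) {
    cat(sprintf("  indicator-positive among sustained: %s (%s%%)\n",
                ct$indicator_sustained, pc$indicator_sustained))
  }
  if (!is.null(ct$self_identified_sustained)) {
    cat(sprintf("  self-identified among sustained: %s (%s%%)\n",
                ct$self_identified_sustained, pc$self_identified_sustained))
  }
  if (!is.null(ct$self_identified_total)) {
    cat(sprintf("  self-identified overall: %s (%s%%)\n",
                ct$self_identified_total, pc$self_identified_total))
  }
  invisible(x)
}

utils::globalVariables(c("ind", "sid"))
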