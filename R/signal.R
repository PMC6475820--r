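# --- event-anchored before/after statistics -------------------------------
#
# The before window is the half-open interval [t0 - w days, t0) and the
# after window is (t0, t0 + w days]; the index query at t0 belongs to
# neither. Under the default "complete" truncation policy, members whose
# after window extends past the log end (or before window before the log
# start) are excluded from pooled counts, so late adopters do not deflate
# the after-window counts systematically.

# Admit members by truncation policy and attach window bounds.
member_windows <- function(members, window_days, span,
                           truncation = c("complete", "none")) {
  truncation <- match.arg(truncation)
  w <- window_days * DAY_SECONDS
  m <- copy(members)[, `:=`(before_start = t0 - w, after_end = t0 + w)]
  if (truncation == "complete" && nrow(m)) {
    m <- m[before_start >= span_start_instant(span) &
             after_end <= span_end_instant(span)]
  }
  m
}

# Queries of admitted members falling in their before/after windows.
# Returns the joined records with a `side` column ("before"/"after").
window_queries <- function(members_adm, records, window_days) {
  if (!nrow(members_adm) || !nrow(records)) {
    return(data.table(user_id = character(), norm_text = character(),
                      side = character()))
  }
  x <- records[members_adm[, .(user_id, t0)], on = "user_id", nomatch = 0L]
  w <- window_days * DAY_SECONDS
  delta <- as.numeric(x$timestamp) - as.numeric(x$t0)
  x[, side := fifelse(delta >= -w & delta < 0, "before",
                      fifelse(delta > 0 & delta <= w, "after",
                              NA_character_))]
  x[!is.na(side)]
}

#' Count concept-matching queries of one user inside a time interval
#'
#' Counts the queries in `records` whose timestamp lies in `interval` and
#' whose concept-match set contains `concept_id`. Queries that are
#' themselves CRQs still count when they also match the concept (e.g.
#' "gluten bloating").
#'
#' @param records One user's records `data.table`.
#' @param lexicon A `lexicon`.
#' @param concept_id Concept to count.
#' @param interval Length-2 `POSIXct` giving the interval bounds.
#' @param bounds Interval openness: `"[)"` (the before-window convention),
#'   `"(]"` (the after-window convention), `"[]"`, or `"()"`.
#' @return Integer count.
#' @export
count_in_window <- function(records, lexicon, concept_id, interval,
                            bounds = c("[)", "(]", "[]", "()")) {
  bounds <- match.arg(bounds)
  stopifnot(length(interval) == 2L)
  if (!concept_id %in% lexicon_concepts(lexicon)) {
    stop("unknown concept_id: ", concept_id)
  }
  lo_ok <- if (substr(bounds, 1L, 1L) == "[") {
    records$timestamp >= interval[1L]
  } else records$timestamp > interval[1L]
  hi_ok <- if (substr(bounds, 2L, 2L) == "]") {
    records$timestamp <= interval[2L]
  } else records$timestamp < interval[2L]
  sel <- records[lo_ok & hi_ok]
  if (!nrow(sel)) return(0L)
  mm <- match_concepts_bulk(sel$norm_text, lexicon)
  sum(mm$concept_id == concept_id)
}

#' Before/after query-ratio table for every concept of a lexicon
#'
#' For each concept, pools (over admitted cohort members) the number of
#' queries matching the concept in the 14 days (or `window_days`) before
#' each member's first CRQ and in the 14 days after it, and forms the query
#' ratio QR = n_before / n_after. A QR above 1 means the concept was
#' searched more in the run-up to the first CRQ than after it. Ratios are
#' flagged undefined when the denominator count is below `min_support`, so
#' noise ratios cannot top rankings.
#'
#' @param members Cohort members (`data.table` from [build_cohort()], or a
#'   `cohort` object).
#' @param records Records `data.table` covering those members.
#' @param lexicon A `lexicon` (symptoms, conditions, ...).
#' @param window_days Half-window length in days.
#' @param min_support Minimum pooled denominator count for the ratio to be
#'   defined.
#' @param truncation `"complete"` (default) drops members whose windows
#'   extend beyond the log span; `"none"` keeps all members.
#' @param denominator `"after"` (default) uses the after-window count alone;
#'   `"union"` uses the pooled count over both windows.
#' @param smooth If `TRUE`, add 0.5 to numerator and denominator (Laplace
#'   flavor); off by default.
#' @param span A [log_span()]; inferred from the records when `NULL`.
#' @return `data.table` with one row per concept: `concept_id`, `category`,
#'   `n_before`, `n_after`, `qr`, `n_users_contributing`, `defined`. The
#'   number of admitted members is attached as attribute `n_members`.
#' @export
query_ratio_table <- function(members, records, lexicon, window_days = 14L,
                              min_support = 10L,
                              truncation = c("complete", "none"),
                              denominator = c("after", "union"),
                              smooth = FALSE, span = NULL) {
  if (inherits(members, "cohort")) members <- members$members
  denominator <- match.arg(denominator)
  truncation <- match.arg(truncation)
  stopifnot(min_support >= 1L)
  span <- span %||% span_from_records(records)

  adm <- member_windows(members, window_days, span, truncation)
  wq <- window_queries(adm, records, window_days)
  grid <- data.table(concept_id = lexicon_concepts(lexicon))

  if (nrow(wq)) {
    mm <- match_concepts_bulk(wq$norm_text, lexicon)
    mm <- cbind(mm, wq[mm$.idx, .(user_id, side)])
    counts <- dcast(mm, concept_id ~ side, fun.aggregate = length,
                    value.var = ".idx")
    for (cn in c("before", "after")) {
      if (!cn %in% names(counts)) counts[, (cn) := 0L]
    }
    users <- mm[, .(n_users_contributing = uniqueN(user_id)),
                by = concept_id]
    out <- merge(grid, counts[, .(concept_id, n_before = before,
                                  n_after = after)],
                 by = "concept_id", all.x = TRUE)
    out <- merge(out, users, by = "concept_id", all.x = TRUE)
  } else {
    out <- copy(grid)[, `:=`(n_before = 0L, n_after = 0L,
                             n_users_contributing = 0L)]
  }
  for (cn in c("n_before", "n_after", "n_users_contributing")) {
    set(out, which(is.na(out[[cn]])), cn, 0L)
  }
  out[, category := lexicon$category]
  out[, denom := if (denominator == "after") n_after else
    n_before + n_after]
  add <- if (smooth) 0.5 else 0
  out[, qr := (n_before + add) / (denom + add)]
  out[, defined := denom >= min_support]
  out[denom + add == 0, qr := NA_real_]
  out[, denom := NULL]
  setcolorder(out, c("concept_id", "category", "n_before", "n_after", "qr",
                     "n_users_contributing", "defined"))
  setorderv(out, "concept_id")
  setattr(out, "n_members", nrow(adm))
  out[]
}

#' Before/after query ratio for one concept
#'
#' Convenience wrapper around [query_ratio_table()] for a single concept;
#' see that function for the statistic's definition and pooling rules.
#'
#' @inheritParams query_ratio_table
#' @param concept_id Concept to evaluate (must exist in the lexicon).
#' @return A list of class `query_ratio` with fields `concept_id`,
#'   `category`, `n_before`, `n_after`, `qr`, `n_users_contributing`,
#'   `defined`, `n_members`.
#' @export
query_ratio <- function(members, records, lexicon, concept_id,
                        window_days = 14L, min_support = 10L,
                        truncation = c("complete", "none"),
                        denominator = c("after", "union"),
                        smooth = FALSE, span = NULL) {
  if (!concept_id %in% lexicon_concepts(lexicon)) {
    stop("unknown concept_id: ", concept_id)
  }
  cid <- concept_id
  tab <- query_ratio_table(members, records, lexicon, window_days,
                           min_support, truncation, denominator, smooth,
                           span)
  row <- tab[tab$concept_id == cid]
  structure(c(as.list(row), n_members = attr(tab, "n_members")),
            class = "query_ratio")
}

#' @export
print.query_ratio <- function(x, ...) {
  cat(sprintf("<query_ratio> %s (%s): QR=%s (n_before=%d, n_after=%d, %s)\n",
              x$concept_id, x$category,
              ifelse(x$defined, sprintf("%.3f", x$qr), "undefined"),
              x$n_before, x$n_after,
              sprintf("%d contributing users", x$n_users_contributing)))
  invisible(x)
}

#' Rank concepts by query ratio
#'
#' Orders defined query ratios descending (ties broken by larger
#' `n_before`, then lexicographic concept id) and returns the top rows —
#' the "searched more before than after" leaderboard.
#'
#' @param results A table from [query_ratio_table()] (possibly several
#'   categories row-bound).
#' @param category Optional category filter.
#' @param top_k Number of rows to keep (per call).
#' @return Ranked `data.table` with a `rank` column.
#' @export
rank_concepts <- function(results, category = NULL, top_k = 10L) {
  out <- as.data.table(results)
  if (!is.null(category)) {
    keep <- category
    out <- out[category %in% keep]
  }
  out <- out[defined == TRUE & !is.na(qr)]
  if (!nrow(out)) {
    out[, rank := integer()]
    setcolorder(out, "rank")
    return(out[])
  }
  setorderv(out, c("qr", "n_before", "concept_id"),
            order = c(-1L, -1L, 1L))
  out <- head(out, top_k)
  out[, rank := seq_len(.N)]
  setcolorder(out, "rank")
  out[]
}

#' Event-anchored temporal profile of a concept
#'
#' Bins every query of every member by whole-day offset from that member's
#' first CRQ (`floor((t - t0) / 1 day)`, so day 0 covers `[t0, t0 + 1
#' day)`), and at each offset compares the concept's share of queries with
#' its overall share: `ratio = (n_concept_d / n_all_d) / baseline` where
#' `baseline` is the concept share pooled over the whole profile range. A
#' ratio above 1 means the concept is more common at that offset than
#' expected.
#'
#' @inheritParams query_ratio_table
#' @param concept_id Concept to profile.
#' @param range_days Profile half-range D: offsets -D..D are reported.
#' @return `data.table` of class `temporal_profile` with columns `offset`,
#'   `n_concept`, `n_all`, `ratio` (`NA` where no queries fell on a day);
#'   attributes `concept_id` and `baseline`. Zero rows when the concept is
#'   never queried in range (baseline 0).
#' @export
temporal_profile <- function(members, records, lexicon, concept_id,
                             range_days = 30L) {
  if (inherits(members, "cohort")) members <- members$members
  stopifnot(range_days >= 1L)
  if (!concept_id %in% lexicon_concepts(lexicon)) {
    stop("unknown concept_id: ", concept_id)
  }
  grid <- data.table(offset = seq(-range_days, range_days))
  empty <- grid[0L][, `:=`(n_concept = integer(), n_all = integer(),
                           ratio = numeric())]
  if (!nrow(members) || !nrow(records)) {
    return(profile_result(empty, concept_id, 0))
  }
  x <- records[members[, .(user_id, t0)], on = "user_id", nomatch = 0L]
  x[, offset := floor((as.numeric(timestamp) - as.numeric(t0)) /
                        DAY_SECONDS)]
  x <- x[offset >= -range_days & offset <= range_days]
  if (!nrow(x)) return(profile_result(empty, concept_id, 0))

  all_d <- x[, .(n_all = .N), by = offset]
  cid <- concept_id
  mm <- match_concepts_bulk(x$norm_text, lexicon)
  mm <- mm[mm$concept_id == cid]
  conc_d <- if (nrow(mm)) {
    data.table(offset = x$offset[mm$.idx])[, .(n_concept = .N), by = offset]
  } else data.table(offset = integer(), n_concept = integer())

  out <- merge(grid, all_d, by = "offset", all.x = TRUE)
  out <- merge(out, conc_d, by = "offset", all.x = TRUE)
  set(out, which(is.na(out$n_all)), "n_all", 0L)
  set(out, which(is.na(out$n_concept)), "n_concept", 0L)
  baseline <- sum(out$n_concept) / sum(out$n_all)
  if (!is.finite(baseline) || baseline == 0) {
    return(profile_result(empty, concept_id, 0))
  }
  out[, ratio := fifelse(n_all > 0, (n_concept / n_all) / baseline,
                         NA_real_)]
  setcolorder(out, c("offset", "n_concept", "n_all", "ratio"))
  profile_result(out, concept_id, baseline)
}

profile_result <- function(dt, concept_id, baseline) {
  setattr(dt, "concept_id", concept_id)
  setattr(dt, "baseline", baseline)
  setattr(dt, "class", c("temporal_profile", class(dt)))
  dt
}

#' @export
print.temporal_profile <- function(x, ...) {
  cat(sprintf("<temporal_profile> concept=%s, baseline share=%.4g, %d days\n",
              attr(x, "concept_id"), attr(x, "baseline"), nrow(x)))
  if (nrow(x)) {
    NextMethod()
  }
  invisible(x)
}
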