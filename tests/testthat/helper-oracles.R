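# Brute-force reference implementations, written word-by-word rather than
# via string search, used to cross-check the package's vectorized paths.

# O(phrases x positions) scan matcher with the literal longest-phrase-wins
# rule. Returns the sorted set of matched concept ids for one query.
oracle_match <- function(norm_text, lexicon) {
  words <- strsplit(norm_text, " ", fixed = TRUE)[[1L]]
  ph <- lexicon$phrases
  found <- list()
  for (r in seq_len(nrow(ph))) {
    pw <- strsplit(ph$phrase[r], " ", fixed = TRUE)[[1L]]
    L <- length(pw)
    starts <- integer()
    if (length(words) >= L) {
      for (s in seq_len(length(words) - L + 1L)) {
        if (all(words[s:(s + L - 1L)] == pw)) starts <- c(starts, s)
      }
    }
    if (length(starts)) {
      found[[length(found) + 1L]] <- list(phrase = ph$phrase[r],
                                          concept = ph$concept_id[r],
                                          starts = starts, len = L)
    }
  }
  if (!length(found)) return(character())
  keep <- rep(TRUE, length(found))
  for (i in seq_along(found)) {
    for (j in seq_along(found)) {
      if (i == j) next
      fi <- found[[i]]; fj <- found[[j]]
      same_concept <- fi$concept == fj$concept
      longer <- fj$len > fi$len
      prefix <- longer && identical(
        strsplit(fj$phrase, " ", fixed = TRUE)[[1L]][seq_len(fi$len)],
        strsplit(fi$phrase, " ", fixed = TRUE)[[1L]])
      if (!same_concept && prefix && all(fi$starts %in% fj$starts)) {
        keep[i] <- FALSE
      }
    }
  }
  sort(unique(vapply(found[keep], `[[`, "", "concept")))
}

# Word-level CRQ test, independent of the regex used in the package.
oracle_is_crq <- function(norm_text) {
  words <- strsplit(norm_text, " ", fixed = TRUE)[[1L]]
  any(startsWith(words, "celiac") | startsWith(words, "gluten"))
}

# Literal three-criterion per-user scan of the cohort filters.
oracle_cohort <- function(records, config) {
  out <- list()
  for (u in unique(records$user_id)) {
    rs <- records[records$user_id == u, ]
    dates <- as.Date(rs$timestamp, tz = "UTC")
    crq <- vapply(rs$norm_text, oracle_is_crq, logical(1L),
                  USE.NAMES = FALSE)
    has_history <- any(dates <= config$history_cutoff)
    in_index <- crq & dates >= config$index_start &
      dates <= config$index_end
    in_washout <- crq & dates >= config$washout_start &
      dates < config$index_start
    if (has_history && any(in_index) && !any(in_washout)) {
      t0 <- rs$timestamp[which(in_index)[1L]]
      days <- length(unique(dates[crq]))
      out[[length(out) + 1L]] <- data.table(
        user_id = u, t0 = t0,
        interest = if (days > 1L) "sustained" else "passing",
        crq_day_count = days)
    }
  }
  if (!length(out)) {
    return(data.table(user_id = character(),
                      t0 = as.POSIXct(character(), tz = "UTC"),
                      interest = character(), crq_day_count = integer()))
  }
  res <- rbindlist(out)
  setorderv(res, "user_id")
  res[]
}

# Double loop over (member, query): pooled before/after counts for one
# concept, with the complete-windows truncation applied literally.
oracle_query_ratio <- function(members, records, lexicon, concept,
                               window_days, span, min_support = 1L) {
  w <- window_days * 86400
  sp0 <- as.POSIXct(paste(span$start, "00:00:00"), tz = "UTC")
  sp1 <- as.POSIXct(paste(span$end + 1L, "00:00:00"), tz = "UTC")
  nb <- na <- 0L
  users <- character()
  for (i in seq_len(nrow(members))) {
    t0 <- members$t0[i]
    if (t0 - w < sp0 || t0 + w > sp1) next
    rs <- records[records$user_id == members$user_id[i], ]
    cb <- ca <- 0L
    for (j in seq_len(nrow(rs))) {
      if (!concept %in% oracle_match(rs$norm_text[j], lexicon)) next
      d <- as.numeric(rs$timestamp[j]) - as.numeric(t0)
      if (d >= -w && d < 0) cb <- cb + 1L
      if (d > 0 && d <= w) ca <- ca + 1L
    }
    nb <- nb + cb
    na <- na + ca
    if (cb + ca > 0L) users <- c(users, members$user_id[i])
  }
  list(n_before = nb, n_after = na,
       qr = if (na > 0L) nb / na else NA_real_,
       n_users_contributing = length(unique(users)),
       defined = na >= min_support)
}
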