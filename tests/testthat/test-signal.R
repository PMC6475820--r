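span_oct <- log_span("2017-09-01", "2017-11-30")

test_that("window counting respects the half-open window conventions", {
  sym <- shipped_symptoms()
  t0 <- as.POSIXct("2017-10-15 12:00:00", tz = "UTC")
  recs <- make_records(
    user_id = rep("u1", 4),
    timestamp = iso(c(t0 - 3 * 86400, t0 - 10 * 86400, t0,
                      t0 + 2 * 86400)),
    text = c("headache remedy", "bad headache", "headache at t0 exactly",
             "headache after")
  )
  w <- 14 * 86400
  expect_identical(count_in_window(recs, sym, "headache",
                                   c(t0 - w, t0), "[)"), 2L)
  expect_identical(count_in_window(recs, sym, "headache",
                                   c(t0, t0 + w), "(]"), 1L)
  # the index query at t0 belongs to neither window
  expect_identical(count_in_window(recs, sym, "headache",
                                   c(t0 - w, t0), "[)") +
                     count_in_window(recs, sym, "headache",
                                     c(t0, t0 + w), "(]"), 3L)
  expect_identical(count_in_window(recs, sym, "diarrhea",
                                   c(t0 - w, t0), "[)"), 0L)
  expect_error(count_in_window(recs, sym, "not a concept",
                               c(t0 - w, t0)), "unknown concept")
})

test_that("query ratios pool counts and respect min_support", {
  sym <- shipped_symptoms()
  # one member; 3 headache queries before, 2 after; CRQ-containing query
  # that also matches the concept still counts
  t0 <- as.POSIXct("2017-10-15 12:00:00", tz = "UTC")
  recs <- make_records(
    user_id = rep("u1", 7),
    timestamp = iso(c(t0 - 13 * 86400, t0 - 5 * 86400, t0 - 86400, t0,
                      t0 + 86400, t0 + 5 * 86400, t0 + 20 * 86400)),
    text = c("headache", "gluten headache", "headache pills",
             "celiac disease", "headache", "my headache", "headache late")
  )
  members <- data.table::data.table(user_id = "u1", t0 = t0)
  qr <- query_ratio(members, recs, sym, "headache", min_support = 1,
                    span = span_oct)
  expect_identical(qr$n_before, 3L)
  expect_identical(qr$n_after, 2L)
  expect_equal(qr$qr, 1.5)
  expect_true(qr$defined)
  expect_identical(qr$n_users_contributing, 1L)

  strict <- query_ratio(members, recs, sym, "headache", min_support = 10,
                        span = span_oct)
  expect_false(strict$defined)

  # union denominator folds both windows into the denominator
  un <- query_ratio(members, recs, sym, "headache", min_support = 1,
                    denominator = "union", span = span_oct)
  expect_equal(un$qr, 3 / 5)
})

test_that("complete-window truncation drops members near the log edges", {
  sym <- shipped_symptoms()
  t0_ok <- as.POSIXct("2017-10-15 12:00:00", tz = "UTC")
  t0_late <- as.POSIXct("2017-11-25 12:00:00", tz = "UTC")  # after window clips
  recs <- make_records(
    user_id = c("u1", "u2"),
    timestamp = iso(c(t0_ok - 86400, t0_late - 86400)),
    text = c("headache", "headache")
  )
  members <- data.table::data.table(user_id = c("u1", "u2"),
                                    t0 = c(t0_ok, t0_late))
  tab <- query_ratio_table(members, recs, sym, min_support = 1,
                           span = span_oct)
  expect_identical(attr(tab, "n_members"), 1L)
  expect_identical(tab[concept_id == "headache", n_before], 1L)
  all_in <- query_ratio_table(members, recs, sym, min_support = 1,
                              truncation = "none", span = span_oct)
  expect_identical(all_in[concept_id == "headache", n_before], 2L)
})

test_that("rankings order by ratio then support then name", {
  res <- data.table::data.table(
    concept_id = c("a", "b", "c", "d"),
    category = "symptom",
    n_before = c(20L, 5L, 10L, 9L),
    n_after = c(10L, 10L, 10L, 10L),
    qr = c(2.0, 1.5, 1.5, 1.5),
    n_users_contributing = 4L,
    defined = TRUE
  )
  top <- rank_concepts(res, top_k = 3)
  expect_identical(top$concept_id, c("a", "c", "d"))
  expect_identical(top$rank, 1:3)
  expect_identical(nrow(rank_concepts(res[0])), 0L)
  # undefined ratios never enter rankings
  res$defined[1] <- FALSE
  expect_false("a" %in% rank_concepts(res, top_k = 4)$concept_id)
})

test_that("query ratios match the brute-force double loop on random logs", {
  lex <- tiny_lexicon()
  for (seed in 1:8) {
    rl <- random_small_log(seed)
    tab <- query_ratio_table(rl$members, rl$records, lex, window_days = 14,
                             min_support = 1, span = rl$span)
    for (cid in lexicon_concepts(lex)) {
      want <- oracle_query_ratio(rl$members, rl$records, lex, cid, 14,
                                 rl$span)
      got <- tab[concept_id == cid]
      expect_identical(got$n_before, want$n_before)
      expect_identical(got$n_after, want$n_after)
      expect_identical(got$n_users_contributing,
                       want$n_users_contributing)
      if (want$n_after > 0) expect_equal(got$qr, want$qr)
    }
  }
})

test_that("counts and ratios are invariant under a constant time shift", {
  lex <- tiny_lexicon()
  rl <- random_small_log(99)
  base <- query_ratio_table(rl$members, rl$records, lex, min_support = 1,
                            span = rl$span)
  shift <- 5 * 86400 + 12345
  recs2 <- data.table::copy(rl$records)[, timestamp := timestamp + shift]
  mem2 <- data.table::copy(rl$members)[, t0 := t0 + shift]
  span2 <- log_span(rl$span$start + 6, rl$span$end + 6)
  shifted <- query_ratio_table(mem2, recs2, lex, min_support = 1,
                               span = span2)
  expect_equal(as.data.frame(base), as.data.frame(shifted))
})

test_that("temporal profiles flag elevated days and flat nulls", {
  sym <- shipped_symptoms()
  set.seed(303)
  # 60 users, 40 queries each, uniform over +-30 days; headache prob
  # constant 0.2 -> all defined ratios near 1
  n_u <- 60L; n_q <- 40L
  t0 <- as.POSIXct("2017-10-15 00:00:00", tz = "UTC")
  mk <- function(p_head) {
    uid <- rep(sprintf("p%02d", 1:n_u), each = n_q)
    off <- runif(n_u * n_q, -30, 31)
    text <- ifelse(runif(n_u * n_q) < p_head(off), "headache",
                   "weather forecast")
    make_records(uid, iso(t0 + off * 86400), text)
  }
  members <- data.table::data.table(user_id = sprintf("p%02d", 1:n_u),
                                    t0 = t0)
  flat <- temporal_profile(members, mk(function(o) 0.2), sym, "headache",
                           30)
  expect_identical(nrow(flat), 61L)
  expect_lt(abs(mean(flat$ratio, na.rm = TRUE) - 1), 0.15)

  burst <- temporal_profile(members,
                            mk(function(o) ifelse(o >= -5 & o < 0, 0.6,
                                                  0.2)),
                            sym, "headache", 30)
  pre <- burst[offset >= -5 & offset <= -1, mean(ratio, na.rm = TRUE)]
  far <- burst[offset <= -6, mean(ratio, na.rm = TRUE)]
  expect_gt(pre, far)

  # a concept never queried yields an empty profile
  none <- temporal_profile(members, mk(function(o) 0.2), sym, "diarrhea",
                           30)
  expect_identical(nrow(none), 0L)
})
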