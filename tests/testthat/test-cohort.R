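test_that("CRQ detection is prefix-at-word-start", {
  expect_identical(
    is_crq(c("celiac disease symptoms", "gluten free pancakes",
             "best pizza near me", "eggluten snack", "glutenfree bread",
             "celiacs forum")),
    c(TRUE, TRUE, FALSE, FALSE, TRUE, TRUE))
})

test_that("indicator phrases match at word boundaries, including ttg", {
  expect_true(is_indicator("marsh score 3b meaning"))
  expect_true(is_indicator("ttg iga normal range"))
  expect_true(is_indicator("what is tissue transglutaminase"))
  expect_false(is_indicator("celiac recipes"))
  expect_false(is_indicator("attgc sequence"))  # no standalone ttg word
})

test_that("self-identification excludes interrogative phrasings", {
  expect_true(is_self_identified("i have celiac disease can i eat rice"))
  expect_true(is_self_identified("i was diagnosed with celiac now what"))
  expect_false(is_self_identified("do i have celiac"))
  expect_false(is_self_identified("how do i know i have celiac"))
  expect_false(is_self_identified("gluten free bread"))
  # a clean assertion later in the query still counts
  expect_true(is_self_identified("yes i have celiac"))
})

test_that("the eligibility filters admit and label a hand-traced user", {
  recs <- make_records(
    user_id = c("ua", "ua", "ua", "ub", "uc", "uc"),
    timestamp = c("2017-02-03T09:00:00", "2017-10-05T10:00:00",
                  "2017-10-09T11:00:00",
                  "2017-10-02T10:00:00",           # ub: no history
                  "2017-03-01T10:00:00", "2017-10-05T10:00:00"),  # uc: washout CRQ
    text = c("weather", "celiac symptoms", "gluten free bread",
             "celiac", "gluten recipes", "celiac disease")
  )
  ch <- build_cohort(recs, cohort_config())
  expect_identical(ch$members$user_id, "ua")
  expect_identical(ch$members$t0,
                   as.POSIXct("2017-10-05 10:00:00", tz = "UTC"))
  expect_identical(ch$members$crq_day_count, 2L)
  expect_identical(ch$members$interest, "sustained")
  expect_identical(ch$exclusions$no_history, 1L)
  expect_identical(ch$exclusions$washout_crq, 1L)
  expect_identical(ch$exclusions$n_members, 1L)
})

test_that("an empty record set yields an empty cohort, not an error", {
  ch <- build_cohort(make_records(character(), character(), character()),
                     cohort_config())
  expect_identical(nrow(ch$members), 0L)
  expect_identical(ch$exclusions$n_members, 0L)
})

test_that("shrinking the washout can only grow the cohort", {
  # ud has a CRQ in June: inside a 9-month washout, outside a 2-month one
  recs <- make_records(
    user_id = c("ud", "ud", "ud", "ue", "ue"),
    timestamp = c("2017-01-10T08:00:00", "2017-06-15T09:00:00",
                  "2017-10-03T10:00:00",
                  "2017-01-05T08:00:00", "2017-10-04T09:00:00"),
    text = c("news", "gluten free cake", "celiac disease",
             "weather", "celiac test")
  )
  long <- build_cohort(recs, cohort_config(washout_months = 9))
  short <- build_cohort(recs, cohort_config(washout_months = 2))
  expect_identical(sort(long$members$user_id), "ue")
  expect_identical(sort(short$members$user_id), c("ud", "ue"))
  expect_true(all(long$members$user_id %in% short$members$user_id))
})

test_that("cohort construction agrees with the literal per-user scan", {
  cfg <- cohort_config(index_start = "2017-10-01",
                       index_end = "2017-10-31",
                       history_cutoff = "2017-09-01",
                       washout_months = 1)
  for (seed in 1:10) {
    set.seed(seed + 500)
    n <- 40L
    span0 <- as.POSIXct("2017-08-01 00:00:00", tz = "UTC")
    recs <- make_records(
      user_id = sample(sprintf("u%02d", 1:12), n, replace = TRUE),
      timestamp = iso(span0 + runif(n, 0, 110 * 86400)),
      text = sample(c("celiac test", "gluten free bread", "weather",
                      "dry mouth", "glutenous rice", "sports"),
                    n, replace = TRUE)
    )
    got <- build_cohort(recs, cfg)$members
    want <- oracle_cohort(recs, cfg)
    expect_equal(
      as.data.frame(got[, .(user_id, t0, interest, crq_day_count)]),
      as.data.frame(want), label = paste("seed", seed))
    # partition property: every member is exactly one of the two classes
    expect_identical(sum(got$interest == "passing") +
                       sum(got$interest == "sustained"), nrow(got))
  }
})

test_that("cohort summaries round the way surveillance reports print", {
  s <- cohort_summary(counts = list(
    total = 90142, passing = 83614, sustained = 6528,
    indicator_sustained = 104, indicator_passing = 336,
    self_identified_sustained = 8, self_identified_total = 31))
  expect_identical(s$percent$passing, 93)
  expect_identical(s$percent$sustained, 7)
  expect_identical(s$percent$indicator_sustained, 1.6)
  expect_identical(s$percent$self_identified_sustained, 0.12)
  expect_identical(s$percent$self_identified_total, 0.03)

  empty <- cohort_summary(counts = list(total = 0, passing = 0,
                                        sustained = 0))
  expect_true(is.na(empty$percent$passing))
})
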