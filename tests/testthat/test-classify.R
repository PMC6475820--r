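test_that("the feature matrix counts pre-index queries per concept", {
  sym <- shipped_symptoms()
  con <- shipped_conditions()
  t0 <- as.POSIXct("2017-10-10 12:00:00", tz = "UTC")
  recs <- make_records(
    user_id = c("t1", "t1", "t1", "t1", "t2", "c1", "c2"),
    timestamp = iso(c(t0 - 5 * 86400, t0 - 3 * 86400, t0 - 86400, t0 + 1,
                      t0 - 2 * 86400, t0 - 4 * 86400, t0 + 10 * 86400)),
    text = c("headache", "bad headache", "anxiety help",
             "headache after index does not count",
             "ibs flare", "weather", "headache too late")
  )
  targets <- data.table::data.table(user_id = c("t1", "t2"), t0 = t0)
  fm <- build_feature_matrix(targets, c("c1", "c2"), recs, sym, con,
                             seed = 1)
  expect_identical(dim(fm$X), c(4L, length(sym$entries) +
                                  length(con$entries)))
  expect_identical(fm$y, c(1L, 1L, 0L, 0L))
  expect_identical(unname(fm$X["t1", "symptom.headache"]), 2L)
  expect_identical(unname(fm$X["t1", "symptom.anxiety"]), 1L)
  expect_identical(sum(fm$X["t1", ]), 3L)
  expect_identical(unname(fm$X["t2", "condition.irritable bowel syndrome"]),
                   1L)
  # comparison users only count queries before their pseudo-index date;
  # c1 has a pre-index query that matches nothing, c2 only a late query
  expect_identical(sum(fm$X["c1", ]), 0L)
  expect_identical(sum(fm$X["c2", ]), 0L)
  # column order is fixed: symptoms lexicographic, then conditions
  expect_identical(colnames(fm$X),
                   c(paste0("symptom.", sort(lexicon_concepts(sym))),
                     paste0("condition.", sort(lexicon_concepts(con)))))
})

test_that("a feature equal to the label separates perfectly", {
  sym <- as_lexicon(list(marker = character(), foo = character()),
                    "symptom")
  con <- as_lexicon(list(bar = character()), "condition")
  n <- 60L
  t0 <- as.POSIXct("2017-10-10 12:00:00", tz = "UTC")
  uid <- sprintf("s%03d", 1:n)
  lab <- rep(c(1L, 0L), n / 2)
  text <- ifelse(lab == 1L, "marker", "foo")
  recs <- make_records(uid, iso(rep(t0 - 86400, n)), text)
  targets <- data.table::data.table(user_id = uid[lab == 1L], t0 = t0)
  fm <- build_feature_matrix(targets, uid[lab == 0L], recs, sym, con,
                             seed = 2)
  res <- evaluate_auc(fm, "linear_regression", folds = 5, seed = 3)
  expect_equal(res$mean_auc, 1.0)
  expect_length(res$fold_auc, 5L)
})

test_that("AUC is invariant to monotone transforms of the scores", {
  set.seed(21)
  y <- rep(c(0L, 1L), each = 40)
  score <- rnorm(80) + y
  a1 <- as.numeric(pROC::auc(pROC::roc(y, score, levels = c(0L, 1L),
                                       direction = "<", quiet = TRUE)))
  a2 <- as.numeric(pROC::auc(pROC::roc(y, exp(3 * score),
                                       levels = c(0L, 1L),
                                       direction = "<", quiet = TRUE)))
  expect_equal(a1, a2)
})

test_that("label-independent features give chance-level AUC", {
  sym <- as_lexicon(list(noisy = character()), "symptom")
  con <- as_lexicon(list(other = character()), "condition")
  n <- 400L
  t0 <- as.POSIXct("2017-10-10 12:00:00", tz = "UTC")
  uid <- sprintf("n%03d", 1:n)
  set.seed(31)
  k <- rpois(n, 3)
  recs <- make_records(rep(uid, k), iso(rep(t0 - 86400, sum(k))),
                       rep("noisy", sum(k)))
  targets <- data.table::data.table(user_id = uid[1:(n / 2)], t0 = t0)
  fm <- build_feature_matrix(targets, uid[(n / 2 + 1):n], recs, sym, con,
                             seed = 4)
  res <- evaluate_auc(fm, "linear_regression", folds = 5, seed = 5)
  expect_gt(res$mean_auc, 0.35)
  expect_lt(res$mean_auc, 0.65)
})

test_that("degenerate label sets are rejected", {
  sym <- as_lexicon(list(a = character()), "symptom")
  con <- as_lexicon(list(b = character()), "condition")
  t0 <- as.POSIXct("2017-10-10 12:00:00", tz = "UTC")
  uid <- sprintf("d%02d", 1:10)
  recs <- make_records(uid, iso(rep(t0 - 86400, 10)), rep("a", 10))
  targets <- data.table::data.table(user_id = uid, t0 = t0)
  fm <- build_feature_matrix(targets, character(), recs, sym, con,
                             seed = 6)
  expect_error(evaluate_auc(fm, "linear_regression"), "both classes")
})

test_that("evaluation is deterministic given a seed", {
  sym <- shipped_symptoms()
  con <- shipped_conditions()
  cfg <- sim_config(n_users = 150, background_rate = 0.6,
                    adopter_fraction = 0.5, seed = 77)
  sim <- generate_logs(cfg)
  ch <- build_cohort(sim$records, cohort_config())
  cmp <- sort(setdiff(unique(sim$records$user_id), ch$members$user_id))
  fm <- build_feature_matrix(ch$members, cmp, sim$records, sym, con,
                             seed = 9)
  r1 <- evaluate_auc(fm, "random_forest", n_trees = 15, folds = 4,
                     seed = 10)
  r2 <- evaluate_auc(fm, "random_forest", n_trees = 15, folds = 4,
                     seed = 10)
  expect_identical(r1$fold_auc, r2$fold_auc)
})
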