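test_that("identical config and seed give byte-identical logs", {
  cfg <- sim_config(n_users = 120, background_rate = 0.4,
                    adopter_fraction = 0.3, seed = 5)
  s1 <- generate_logs(cfg)
  s2 <- generate_logs(cfg)
  expect_identical(as.data.frame(s1$records), as.data.frame(s2$records))
  expect_identical(as.data.frame(s1$truth$users),
                   as.data.frame(s2$truth$users))
  # and files written from them are byte-identical too
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_query_log(s1$records, f1)
  write_query_log(s2$records, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("no adopters means no CRQs and an empty cohort", {
  cfg <- sim_config(n_users = 80, background_rate = 0.4,
                    adopter_fraction = 0, seed = 6)
  sim <- generate_logs(cfg)
  expect_false(any(is_crq(sim$records$norm_text)))
  ch <- build_cohort(sim$records, cohort_config())
  expect_identical(nrow(ch$members), 0L)
})

test_that("record emission matches the generator's internal tally", {
  cfg <- sim_config(n_users = 150, background_rate = 0.5,
                    adopter_fraction = 0.4, sustained_fraction = 0.3,
                    self_id_prob = 0.2, seed = 7)
  sim <- generate_logs(cfg)
  u <- sim$truth$users
  expect_identical(nrow(sim$records),
                   sum(u$n_background) + sum(u$n_crq_events) +
                     sum(u$n_self_id))
  expect_identical(sim$truth$tally, nrow(sim$records))
  # every adopter's log contains a CRQ at exactly t0
  ad <- u[u$adopter == TRUE]
  joined <- merge(sim$records, ad[, .(user_id, t0)], by = "user_id")
  at_t0 <- joined[timestamp == t0]
  expect_identical(sort(unique(at_t0$user_id)), sort(ad$user_id))
  expect_true(all(is_crq(at_t0$norm_text)))
})

test_that("planted labels agree with what the cohort filters compute", {
  cfg <- sim_config(n_users = 400, background_rate = 0.6,
                    adopter_fraction = 0.5, sustained_fraction = 0.25,
                    post_recipe_shift = 3, gf_recipe_prob = 0.004,
                    self_id_prob = 0.1, seed = 8)
  sim <- generate_logs(cfg)
  ch <- build_cohort(sim$records, cohort_config())
  truth <- sim$truth$users[sim$truth$users$adopter == TRUE]
  m <- merge(ch$members, truth[, .(user_id, truth_interest = interest)],
             by = "user_id")
  # all adopters with observable history become members, none besides
  expect_identical(nrow(ch$members), nrow(truth))
  expect_identical(m$interest, m$truth_interest)
})

test_that("the sustained share concentrates around its parameter", {
  cfg <- sim_config(n_users = 4000, background_rate = 0.15,
                    adopter_fraction = 1, sustained_fraction = 0.07,
                    seed = 9)
  sim <- generate_logs(cfg)
  share <- mean(sim$truth$users$interest == "sustained")
  expect_gte(share, 0.06)
  expect_lte(share, 0.08)
})

test_that("marginal concept frequencies follow the configured probabilities", {
  probs <- c(diarrhea = 0.05, headache = 0.03, anxiety = 0.02)
  cfg <- sim_config(n_users = 400, background_rate = 1,
                    adopter_fraction = 0, concept_probs = probs,
                    recipe_probs = stats::setNames(numeric(), character()),
                    decorate_prob = 0, seed = 10)
  sim <- generate_logs(cfg)
  expect_gt(nrow(sim$records), 1e5)
  sym <- shipped_symptoms()
  mm <- querysignal:::match_concepts_bulk(sim$records$norm_text, sym)
  obs <- table(factor(mm$concept_id, levels = names(probs)))
  n <- nrow(sim$records)
  expected <- c(probs * n, filler = n - sum(probs * n))
  observed <- c(as.numeric(obs), n - sum(obs))
  gof <- suppressWarnings(stats::chisq.test(observed, p = expected / n))
  expect_gt(gof$p.value, 0.01)
})

test_that("impossible configurations are rejected", {
  expect_error(sim_config(span = log_span("2017-08-01", "2017-10-31")),
               "washout")
  expect_error(sim_config(adopter_fraction = 1.5), "probabilities")
  expect_error(sim_config(concept_probs = c(diarrhea = 0.5,
                                            headache = 0.6)),
               "filler")
  expect_error(sim_config(pre_window_multipliers = c(nonexistent = 2)),
               "concept_probs")
})

test_that("parameter recovery flags planted effects correctly", {
  syms <- c("diarrhea", "headache", "anxiety", "bloating", "cough")
  cp <- stats::setNames(c(0.06, rep(0.03, 4)), syms)
  cfg <- sim_config(n_users = 1200, background_rate = 1,
                    adopter_fraction = 0.6, concept_probs = cp,
                    pre_window_multipliers = c(diarrhea = 3), seed = 12)
  sim <- generate_logs(cfg)
  ch <- build_cohort(sim$records, cohort_config())
  tab <- query_ratio_table(ch$members, sim$records, cfg$symptom_lexicon,
                           span = cfg$span)
  rep <- recover_parameters(sim$truth, ch, tab)
  dia <- rep$qr[concept_id == "diarrhea"]
  expect_false(dia$flagged)
  expect_gt(dia$qr, 2)  # planted elevation clearly recovered
  expect_false(rep$sustained$flagged)
})
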