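# --- synthetic query-log simulator ----------------------------------------
#
# Emulates the statistical structure the pipeline assumes: per-user
# background query streams (Poisson), a celiac-adopter subpopulation whose
# first CRQ falls in the index month after a clean washout, a
# passing/sustained interest mixture, elevated symptom-query rates in the
# window before the first CRQ, rare first-person self-identification
# queries, and a post-CRQ shift toward gluten-free recipe queries among
# sustained adopters. It does not attempt realistic natural language,
# search sessions, or diurnal rhythm — queries are template text with
# timestamps uniform within the day, which is all the day-level statistics
# see.

FILLER_QUERIES <- c(
  "weather forecast", "news headlines", "movie showtimes",
  "football scores", "driving directions", "cheap flights",
  "hotel deals", "currency exchange rate", "tv guide",
  "online banking login", "used cars for sale", "job openings near me",
  "math homework help", "birthday gift ideas", "phone screen repair",
  "lottery results", "local election results", "traffic report",
  "translate english to spanish", "printer drivers download"
)

CONCEPT_TEMPLATES <- c("%s", "%s symptoms", "%s treatment",
                       "what causes %s")
CONCEPT_TEMPLATE_PROBS <- c(0.4, 0.3, 0.15, 0.15)
DISH_TEMPLATES <- c("%s recipe", "how to make %s", "easy %s recipe")
CRQ_T0_QUERIES <- c("celiac disease", "celiac disease symptoms",
                    "what is celiac disease", "gluten intolerance",
                    "gluten sensitivity symptoms", "celiac disease test")
CRQ_FOLLOWUP_QUERIES <- c("gluten free diet", "celiac disease diet",
                          "gluten intolerance symptoms",
                          "is oatmeal gluten free")
SELF_ID_QUERIES <- c("i have celiac what can i eat",
                     "i was diagnosed with celiac disease")

#' Simulator configuration
#'
#' Parameters of the synthetic query-log generator. Defaults describe a
#' ten-month log (January through October 2017) whose index period is
#' October, matching the cohort filters' defaults: the washout is
#' observable in full. The sustained fraction defaults to 0.07 — roughly
#' one user in fourteen keeps querying over more than one day — and the
#' before/after half-window to 14 days. Background intensity and concept
#' probabilities are set to resemble sparse real-world health queries:
#' each user emits on average `background_rate` queries per day, and a
#' background query expresses a given concept with its `concept_probs`
#' entry (the rest is non-medical filler).
#'
#' @param n_users Number of users to simulate.
#' @param span A [log_span()] for the whole log.
#' @param index_start,index_end Index period in which adopters' first CRQ
#'   falls.
#' @param washout_months Months of CRQ-free history the cohort filters will
#'   demand; the span must cover them (validation only).
#' @param window_days Half-window length used for the pre-CRQ elevation.
#' @param background_rate Mean background queries per user-day (Poisson).
#' @param concept_probs Named numeric: probability that a background query
#'   expresses each concept. Defaults to 0.006 for every concept in the
#'   two lexicons.
#' @param adopter_fraction Probability a user is a celiac adopter (emits a
#'   first CRQ at a `t0` uniform in the index period).
#' @param sustained_fraction Probability an adopter has sustained interest
#'   (CRQs on more than one day).
#' @param pre_window_multipliers Named numeric: per-concept rate multiplier
#'   applied to queries in `[t0 - window_days, t0)`. Unlisted concepts get
#'   multiplier 1.
#' @param recipe_probs Named numeric: background per-dish query
#'   probability. Defaults to 0.002 for every non-gluten-free dish in the
#'   recipe map; gluten-free dishes (any synonym containing
#'   "gluten"/"celiac") have no background rate because querying them is
#'   itself a CRQ.
#' @param gf_recipe_prob Per-gluten-free-dish query probability for
#'   sustained adopters after `t0` (before scaling by
#'   `post_recipe_shift`).
#' @param post_recipe_shift Multiplier on `gf_recipe_prob` — the planted
#'   dietary shift.
#' @param self_id_prob Probability an adopter emits one self-identification
#'   query on the day of `t0`.
#' @param extra_crq_day_mean Mean number of *extra* distinct CRQ days for a
#'   sustained adopter (1 + geometric, so at least one extra day; the
#'   default mean of 2 gives about three CRQ days in total).
#' @param decorate_prob Fraction of queries written with capitalization and
#'   trailing punctuation, to exercise text normalization.
#' @param zip_prob Probability a query carries the user's 5-digit zip code.
#' @param symptom_lexicon,condition_lexicon,recipe_map Dictionaries used to
#'   phrase the queries; default to the demonstration files shipped with
#'   the package.
#' @param seed Integer seed; identical `(config, seed)` yields an
#'   identical log.
#' @return A `sim_config` object.
#' @export
sim_config <- function(n_users = 2000L,
                       span = log_span("2017-01-01", "2017-10-31"),
                       index_start = "2017-10-01",
                       index_end = "2017-10-31",
                       washout_months = 9L,
                       window_days = 14L,
                       background_rate = 0.5,
                       concept_probs = NULL,
                       adopter_fraction = 0.1,
                       sustained_fraction = 0.07,
                       pre_window_multipliers = NULL,
                       recipe_probs = NULL,
                       gf_recipe_prob = 0.002,
                       post_recipe_shift = 1,
                       self_id_prob = 0.005,
                       extra_crq_day_mean = 2,
                       decorate_prob = 0.1,
                       zip_prob = 0.8,
                       symptom_lexicon = NULL,
                       condition_lexicon = NULL,
                       recipe_map = NULL,
                       seed = 1L) {
  symptom_lexicon <- symptom_lexicon %||% load_lexicon(
    system.file("extdata", "symptoms.tsv", package = "querysignal"),
    "symptom")
  condition_lexicon <- condition_lexicon %||% load_lexicon(
    system.file("extdata", "conditions.tsv", package = "querysignal"),
    "condition")
  recipe_map <- recipe_map %||% load_recipe_map(
    system.file("extdata", "recipes.tsv", package = "querysignal"))

  all_concepts <- c(lexicon_concepts(symptom_lexicon),
                    lexicon_concepts(condition_lexicon))
  if (anyDuplicated(all_concepts)) {
    stop("symptom and condition lexicons share a concept id")
  }
  if (is.null(concept_probs)) {
    concept_probs <- stats::setNames(rep(0.006, length(all_concepts)),
                                     all_concepts)
  }
  if (!all(names(concept_probs) %in% all_concepts)) {
    stop("concept_probs names unknown to the lexicons: ",
         paste(setdiff(names(concept_probs), all_concepts),
               collapse = ", "))
  }

  gf <- gluten_free_dishes(recipe_map)
  if (is.null(recipe_probs)) {
    bg <- setdiff(recipe_ids(recipe_map), gf)
    recipe_probs <- stats::setNames(rep(0.002, length(bg)), bg)
  }
  if (any(names(recipe_probs) %in% gf)) {
    stop("recipe_probs must not include gluten-free dishes; their ",
         "queries are CRQs and are governed by gf_recipe_prob")
  }
  if (!all(names(recipe_probs) %in% recipe_ids(recipe_map))) {
    stop("recipe_probs names unknown to the recipe map")
  }

  # multipliers aligned to the concepts that actually have a background rate
  mult <- stats::setNames(rep(1, length(concept_probs)),
                          names(concept_probs))
  if (!is.null(pre_window_multipliers)) {
    if (!all(names(pre_window_multipliers) %in% names(concept_probs))) {
      stop("pre_window_multipliers must name concepts present in ",
           "concept_probs")
    }
    if (any(pre_window_multipliers <= 0)) {
      stop("pre-window multipliers must be positive")
    }
    mult[names(pre_window_multipliers)] <- pre_window_multipliers
  }

  cfg <- list(
    n_users = as.integer(n_users), span = span,
    index_start = as.Date(index_start), index_end = as.Date(index_end),
    washout_months = as.integer(washout_months),
    window_days = as.integer(window_days),
    background_rate = background_rate,
    concept_probs = concept_probs,
    adopter_fraction = adopter_fraction,
    sustained_fraction = sustained_fraction,
    pre_window_multipliers = mult,
    recipe_probs = recipe_probs,
    gf_recipe_prob = gf_recipe_prob,
    post_recipe_shift = post_recipe_shift,
    self_id_prob = self_id_prob,
    extra_crq_day_mean = extra_crq_day_mean,
    decorate_prob = decorate_prob,
    zip_prob = zip_prob,
    symptom_lexicon = symptom_lexicon,
    condition_lexicon = condition_lexicon,
    recipe_map = recipe_map,
    gf_dishes = gf,
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

gluten_free_dishes <- function(recipe_map) {
  ids <- recipe_ids(recipe_map)
  ids[vapply(ids, function(id) {
    any(is_crq(recipe_map$recipes[[id]]$synonyms))
  }, logical(1L))]
}

validate_sim_config <- function(cfg) {
  probs <- c(cfg$adopter_fraction, cfg$sustained_fraction,
             cfg$self_id_prob, cfg$decorate_prob, cfg$zip_prob,
             cfg$concept_probs, cfg$recipe_probs, cfg$gf_recipe_prob)
  if (any(probs < 0 | probs > 1)) {
    stop("sim_config: probabilities must lie in [0, 1]")
  }
  if (cfg$n_users < 1L) stop("sim_config: need at least one user")
  if (cfg$background_rate <= 0) {
    stop("sim_config: background_rate must be positive")
  }
  if (cfg$index_start > cfg$index_end) {
    stop("sim_config: index_start after index_end")
  }
  if (cfg$span$start > months_before(cfg$index_start, cfg$washout_months) ||
      cfg$span$end < cfg$index_end) {
    stop("sim_config: span must cover the washout months and the index ",
         "period")
  }
  base_total <- sum(cfg$concept_probs) + sum(cfg$recipe_probs)
  pre_total <- base_total +
    sum(cfg$concept_probs * (cfg$pre_window_multipliers - 1))
  post_total <- base_total +
    length(cfg$gf_dishes) * cfg$gf_recipe_prob * cfg$post_recipe_shift
  if (max(base_total, pre_total, post_total) >= 1) {
    stop("sim_config: concept/recipe probabilities leave no room for ",
         "filler queries (total >= 1)")
  }
  # background content must never look celiac-related, or planted labels
  # would drift from what the cohort filters compute
  syns <- c(unlist(cfg$symptom_lexicon$entries, use.names = FALSE),
            unlist(cfg$condition_lexicon$entries, use.names = FALSE))
  if (any(is_crq(syns))) {
    stop("sim_config: a symptom/condition synonym is itself a CRQ")
  }
  bg_dishes <- names(cfg$recipe_probs)
  bg_syn <- unlist(lapply(cfg$recipe_map$recipes[bg_dishes], `[[`,
                          "synonyms"), use.names = FALSE)
  if (any(is_crq(c(bg_syn, FILLER_QUERIES)))) {
    stop("sim_config: background dish/filler text is celiac-related")
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("<sim_config> %d users over %s..%s, rate=%.2g/day, adopters=%.0f%% (sustained %.0f%%), seed=%d\n",
              x$n_users, x$span$start, x$span$end, x$background_rate,
              100 * x$adopter_fraction, 100 * x$sustained_fraction,
              x$seed))
  planted <- x$pre_window_multipliers[x$pre_window_multipliers != 1]
  if (length(planted)) {
    cat("  planted pre-window multipliers:",
        paste(names(planted), signif(planted, 3), sep = "=",
              collapse = ", "), "\n")
  }
  invisible(x)
}

#' Generate a synthetic query log with ground truth
#'
#' Draws the log described by a [sim_config()]: every user emits background
#' queries as a Poisson process phrased from the lexicons and recipe map
#' (or as filler), adopters emit their first CRQ at a `t0` uniform in the
#' index period, sustained adopters add CRQs on further distinct days and
#' shift toward gluten-free recipe queries after `t0`, concept rates are
#' multiplied by the planted pre-window multipliers inside
#' `[t0 - window_days, t0)`, and a small fraction of adopters self-identify
#' on the day of `t0`. Identical `(config, seed)` produce identical output.
#'
#' A sustained adopter whose `t0` falls on the last day of the span has no
#' room for a second CRQ day and is relabelled passing in the ground truth,
#' keeping truth consistent with the emitted log.
#'
#' @param config A [sim_config()].
#' @return List of class `sim_result`: `records` (a records `data.table`
#'   sorted by user and time, as [read_query_log()] would return) and
#'   `truth` (class `ground_truth`: per-user `users` table with `adopter`,
#'   `t0`, `interest`, per-source emission counts; the planted
#'   `concept_multipliers`, `gf_dishes`, `post_recipe_shift`; and the
#'   emission `tally`).
#' @export
generate_logs <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, generate_logs_impl(config))
}

generate_logs_impl <- function(cfg) {
  sp0 <- span_start_instant(cfg$span)
  n_days <- as.integer(cfg$span$end - cfg$span$start) + 1L
  n <- cfg$n_users
  uid <- sprintf("u%06d", seq_len(n))
  user_zip <- sprintf("%05d", sample.int(100000L, n, replace = TRUE) - 1L)

  adopter <- runif(n) < cfg$adopter_fraction
  n_ad <- sum(adopter)
  idx_days <- seq(cfg$index_start, cfg$index_end, by = "day")
  t0 <- rep(parse_instant(NA_character_), n)
  if (n_ad) {
    t0_day <- idx_days[sample.int(length(idx_days), n_ad, replace = TRUE)]
    t0[adopter] <- as.POSIXct(paste(t0_day, "00:00:00"), tz = "UTC") +
      runif(n_ad, 0, DAY_SECONDS)
  }
  sustained <- rep(FALSE, n)
  sustained[adopter] <- runif(n_ad) < cfg$sustained_fraction
  # a t0 on the last span day leaves no room for a second CRQ day
  relabelled <- sustained & instant_date(t0) >= cfg$span$end
  sustained[relabelled] <- FALSE

  # ---- background stream ----
  nq <- rpois(n, cfg$background_rate * n_days)
  bu <- rep.int(seq_len(n), nq)
  bt <- sp0 + runif(length(bu), 0, n_days * DAY_SECONDS)
  w <- cfg$window_days * DAY_SECONDS
  delta <- as.numeric(bt) - as.numeric(t0[bu])
  stratum <- rep(1L, length(bu))
  stratum[!is.na(delta) & delta >= -w & delta < 0] <- 2L
  stratum[!is.na(delta) & delta > 0 & sustained[bu]] <- 3L

  items_base <- c(cfg$concept_probs, cfg$recipe_probs)
  items_pre <- c(cfg$concept_probs * cfg$pre_window_multipliers,
                 cfg$recipe_probs)
  gf_probs <- stats::setNames(
    rep(cfg$gf_recipe_prob * cfg$post_recipe_shift,
        length(cfg$gf_dishes)), cfg$gf_dishes)
  items_post <- c(items_base, gf_probs)
  draw_kind <- function(probs, m) {
    sample(c(names(probs), ".filler"), m, replace = TRUE,
           prob = c(probs, 1 - sum(probs)))
  }
  kind <- character(length(bu))
  for (s in 1L:3L) {
    idx <- which(stratum == s)
    if (!length(idx)) next
    probs <- switch(s, items_base, items_pre, items_post)
    kind[idx] <- draw_kind(probs, length(idx))
  }

  # ---- phrase the background queries ----
  text <- character(length(bu))
  fil <- kind == ".filler"
  if (any(fil)) {
    text[fil] <- FILLER_QUERIES[sample.int(length(FILLER_QUERIES),
                                           sum(fil), replace = TRUE)]
  }
  entries <- c(cfg$symptom_lexicon$entries, cfg$condition_lexicon$entries)
  dish_syn <- lapply(cfg$recipe_map$recipes, `[[`, "synonyms")
  for (k in unique(kind[!fil & nzchar(kind)])) {
    rows <- which(kind == k)
    if (k %in% names(entries)) {
      syn <- entries[[k]]
      ph <- syn[sample.int(length(syn), length(rows), replace = TRUE)]
      tpl <- CONCEPT_TEMPLATES[sample.int(length(CONCEPT_TEMPLATES),
                                          length(rows), replace = TRUE,
                                          prob = CONCEPT_TEMPLATE_PROBS)]
    } else {
      syn <- dish_syn[[k]]
      ph <- syn[sample.int(length(syn), length(rows), replace = TRUE)]
      tpl <- DISH_TEMPLATES[sample.int(length(DISH_TEMPLATES),
                                       length(rows), replace = TRUE)]
    }
    text[rows] <- sprintf(tpl, ph)
  }
  background <- data.table(u = bu, timestamp = bt, base_text = text)

  # ---- CRQ events ----
  ad_rows <- which(adopter)
  crq_events <- data.table(u = integer(), timestamp = bt[0],
                           base_text = character())
  n_extra <- integer(n)
  if (n_ad) {
    crq_events <- data.table(
      u = ad_rows, timestamp = t0[ad_rows],
      base_text = CRQ_T0_QUERIES[sample.int(length(CRQ_T0_QUERIES), n_ad,
                                            replace = TRUE)])
    sus_rows <- which(sustained)
    if (length(sus_rows)) {
      want <- 1L + rgeom(length(sus_rows),
                         prob = 1 / cfg$extra_crq_day_mean)
      extras <- vector("list", length(sus_rows))
      for (j in seq_along(sus_rows)) {
        i <- sus_rows[j]
        avail <- seq(instant_date(t0[i]) + 1L, cfg$span$end, by = "day")
        take <- min(want[j], length(avail))
        days <- avail[sample.int(length(avail), take)]
        extras[[j]] <- data.table(
          u = i,
          timestamp = as.POSIXct(paste(days, "00:00:00"), tz = "UTC") +
            runif(take, 0, DAY_SECONDS),
          base_text = CRQ_FOLLOWUP_QUERIES[
            sample.int(length(CRQ_FOLLOWUP_QUERIES), take,
                       replace = TRUE)])
        n_extra[i] <- take
      }
      crq_events <- rbind(crq_events, rbindlist(extras))
    }
  }

  # ---- self-identification, on the day of t0 ----
  sid <- adopter & runif(n) < cfg$self_id_prob
  self_events <- data.table(u = integer(), timestamp = bt[0],
                            base_text = character())
  if (any(sid)) {
    rows <- which(sid)
    left <- DAY_SECONDS - (as.numeric(t0[rows]) %% DAY_SECONDS)
    self_events <- data.table(
      u = rows,
      timestamp = t0[rows] + runif(length(rows), 0, left),
      base_text = SELF_ID_QUERIES[sample.int(length(SELF_ID_QUERIES),
                                             length(rows),
                                             replace = TRUE)])
  }

  ev <- rbind(background, crq_events, self_events)

  # ---- surface form: light decoration, zip codes ----
  dec <- runif(nrow(ev)) < cfg$decorate_prob
  raw <- ev$base_text
  if (any(dec)) {
    punct <- c("?", "!", ".")[sample.int(3L, sum(dec), replace = TRUE)]
    raw[dec] <- paste0(toupper(substring(raw[dec], 1L, 1L)),
                       substring(raw[dec], 2L), punct)
  }
  zip <- fifelse(runif(nrow(ev)) < cfg$zip_prob, user_zip[ev$u],
                 NA_character_)
  records <- data.table(user_id = uid[ev$u], timestamp = ev$timestamp,
                        raw_text = raw, norm_text = normalize_text(raw),
                        zip_code = zip)
  setorderv(records, c("user_id", "timestamp"))

  interest <- rep(NA_character_, n)
  interest[adopter] <- fifelse(sustained[adopter], "sustained", "passing")
  users <- data.table(
    user_id = uid, adopter = adopter, t0 = t0, interest = interest,
    n_background = nq,
    n_crq_events = as.integer(adopter) + n_extra,
    n_self_id = as.integer(sid)
  )
  truth <- structure(list(
    users = users,
    concept_multipliers = cfg$pre_window_multipliers,
    gf_dishes = cfg$gf_dishes,
    post_recipe_shift = cfg$post_recipe_shift,
    sustained_fraction = cfg$sustained_fraction,
    adopter_fraction = cfg$adopter_fraction,
    tally = nrow(records),
    seed = cfg$seed
  ), class = "ground_truth")

  structure(list(records = records, truth = truth), class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  u <- x$truth$users
  cat(sprintf("<sim_result> %d records from %d users (%d adopters, %d sustained)\n",
              nrow(x$records), nrow(u), sum(u$adopter),
              sum(u$interest == "sustained", na.rm = TRUE)))
  invisible(x)
}

#' Write simulator ground truth to JSON
#'
#' @param truth A `ground_truth` object from [generate_logs()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  u <- copy(truth$users)
  u[, t0 := fifelse(is.na(t0), NA_character_, format_instant(t0))]
  jsonlite::write_json(list(
    users = u,
    concept_multipliers = as.list(truth$concept_multipliers),
    gf_dishes = truth$gf_dishes,
    post_recipe_shift = truth$post_recipe_shift,
    sustained_fraction = truth$sustained_fraction,
    adopter_fraction = truth$adopter_fraction,
    tally = truth$tally,
    seed = truth$seed
  ), path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
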