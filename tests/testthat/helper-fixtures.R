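library(data.table)

# Build a records table from plain vectors (timestamps as ISO strings).
make_records <- function(user_id, timestamp, text, zip = NA_character_) {
  dt <- data.table(
    user_id = user_id,
    timestamp = as.POSIXct(timestamp, format = "%Y-%m-%dT%H:%M:%S",
                           tz = "UTC"),
    raw_text = text,
    norm_text = normalize_text(text),
    zip_code = rep_len(zip, length(user_id))
  )
  setorderv(dt, c("user_id", "timestamp"))
  dt[]
}

iso <- function(x) format(x, "%Y-%m-%dT%H:%M:%S", tz = "UTC")

# Small lexicon exercising multi-word synonyms and the cross-concept
# word-prefix case ("red fox" vs "red fox trot").
tiny_lexicon <- function(category = "symptom") {
  as_lexicon(list(
    alpha = c("red fox"),
    beta = c("red fox trot"),
    gamma = c("gamma"),
    delta = c("blue moon")
  ), category)
}

shipped_symptoms <- function() {
  load_lexicon(system.file("extdata", "symptoms.tsv",
                           package = "querysignal"), "symptom")
}
shipped_conditions <- function() {
  load_lexicon(system.file("extdata", "conditions.tsv",
                           package = "querysignal"), "condition")
}
shipped_recipes <- function() {
  load_recipe_map(system.file("extdata", "recipes.tsv",
                              package = "querysignal"))
}

# Random word-soup log over a fixed vocabulary, for oracle-equivalence
# tests. Returns records plus a member table with t0 mid-span.
random_small_log <- function(seed, n_users = 8L, max_queries = 120L,
                             span = log_span("2017-09-01", "2017-11-30")) {
  set.seed(seed)
  vocab <- c("red", "fox", "trot", "blue", "moon", "gamma", "noise",
             "quick", "brown", "celiac", "gluten", "weather")
  n_days <- as.integer(span$end - span$start) + 1L
  users <- sprintf("w%03d", seq_len(n_users))
  recs <- lapply(seq_len(n_users), function(i) {
    nq <- sample.int(max_queries, 1L)
    nwords <- sample(1:4, nq, replace = TRUE)
    text <- vapply(nwords, function(k) {
      paste(sample(vocab, k, replace = TRUE), collapse = " ")
    }, "")
    secs <- sort(runif(nq, 0, n_days * 86400))
    data.table(user_id = users[i],
               timestamp = as.POSIXct(paste(span$start, "00:00:00"),
                                      tz = "UTC") + secs,
               raw_text = text, norm_text = text,
               zip_code = NA_character_)
  })
  records <- rbindlist(recs)
  setorderv(records, c("user_id", "timestamp"))
  member_users <- sample(users, max(2L, n_users %/% 2L))
  t0 <- as.POSIXct("2017-10-01 00:00:00", tz = "UTC") +
    runif(length(member_users), 0, 31 * 86400)
  members <- data.table(user_id = member_users, t0 = t0)
  setorderv(members, "user_id")
  list(records = records, members = members, span = span)
}
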