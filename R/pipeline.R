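#' Default end-to-end pipeline configuration
#'
#' Returns the configuration list [run_pipeline()] starts from; a user
#' config (list or YAML file) is merged over it, so only deviations need
#' to be given. Either a `simulate` block (passed to [sim_config()]) or a
#' `log` path must be present. One top-level `seed` fans out to the
#' per-stage seeds by fixed offsets, so a single value controls full
#' reproducibility.
#'
#' @return Nested configuration list.
#' @export
default_pipeline_config <- function() {
  list(
    seed = 1L,
    simulate = list(n_users = 500L),
    log = NULL,
    header = FALSE,
    span = list(start = "2017-01-01", end = "2017-10-31"),
    lexicons = list(
      symptom = system.file("extdata", "symptoms.tsv",
                            package = "querysignal"),
      condition = system.file("extdata", "conditions.tsv",
                              package = "querysignal")
    ),
    recipe_map = system.file("extdata", "recipes.tsv",
                             package = "querysignal"),
    cohort = list(index_start = "2017-10-01", index_end = "2017-10-31",
                  history_cutoff = "2017-09-01", washout_months = 9L),
    window_days = 14L,
    min_support = 10L,
    denominator = "after",
    top_k = 10L,
    profile = list(concept = "diarrhea", range_days = 30L),
    recipes = list(min_support = 5L, sustained_only = FALSE),
    classify = list(model = "random_forest", trees = 50L, folds = 10L,
                    comparison_ratio = 5L, target_class = "sustained",
                    min_targets = 20L)
  )
}

merge_config <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(user[[nm]]) && is.list(base[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], user[[nm]])
    } else {
      base[[nm]] <- user[[nm]]
    }
  }
  base
}

#' Run the full query-log analysis pipeline
#'
#' Orchestrates simulate (optional) -> ingest -> cohort -> query ratios ->
#' temporal profile -> dietary shifts -> classifier into an output
#' directory, with a machine-readable run report. Outputs: `sim.tsv` and
#' `truth.json` (when simulating), `cohort.tsv`, `exclusions.json`,
#' `qr_all.tsv`, `qr_sustained.tsv`, `profile_<concept>.tsv`,
#' `food_changes.tsv`, `auc.json`, `report.json`. Rerunning with the same
#' configuration and seed reproduces every data output byte for byte;
#' `report.json` differs only in its wall-clock fields.
#'
#' Degenerate inputs are not errors: an empty log yields empty outputs and
#' a zero-count report, and the classifier stage is skipped (recorded as
#' such in `auc.json`) when either class is too small.
#'
#' @param config A configuration list or path to a YAML file; merged over
#'   [default_pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @param force Overwrite an existing completed run directory.
#' @param quiet Suppress per-stage progress messages.
#' @return The run report, invisibly (also written to `report.json`).
#' @export
run_pipeline <- function(config = list(), out_dir, force = FALSE,
                         quiet = TRUE) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  cfg <- merge_config(default_pipeline_config(), config)
  if (!is.null(cfg$log)) cfg$simulate <- NULL

  if (dir.exists(out_dir) &&
      file.exists(file.path(out_dir, "report.json")) && !force) {
    stop("output directory already holds a completed run; use force = TRUE")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  say <- function(...) if (!quiet) message(sprintf(...))
  stages <- list()
  stage <- function(name, n_in, expr) {
    t0 <- proc.time()[["elapsed"]]
    val <- force(expr)
    stages[[length(stages) + 1L]] <<- list(
      name = name, n_in = n_in,
      n_out = if (is.data.frame(val)) nrow(val) else NA,
      wall_clock = round(proc.time()[["elapsed"]] - t0, 3))
    val
  }

  span <- log_span(cfg$span$start, cfg$span$end)
  seed <- as.integer(cfg$seed)

  # ---- simulate / ingest ----
  if (!is.null(cfg$simulate)) {
    say("simulating query log")
    sim_args <- cfg$simulate
    sim_args$seed <- seed
    sim_args$span <- span
    scfg <- do.call(sim_config, sim_args)
    simres <- generate_logs(scfg)
    stage("simulate", NA, simres$records)
    log_path <- file.path(out_dir, "sim.tsv")
    write_query_log(simres$records, log_path)
    write_ground_truth(simres$truth, file.path(out_dir, "truth.json"))
  } else {
    log_path <- cfg$log
  }
  say("ingesting %s", log_path)
  ql <- read_query_log(log_path, span, header = isTRUE(cfg$header))
  records <- stage("ingest", ql$report$n_lines, ql$records)

  sym <- load_lexicon(cfg$lexicons$symptom, "symptom")
  con <- load_lexicon(cfg$lexicons$condition, "condition")
  rmap <- load_recipe_map(cfg$recipe_map)

  # ---- cohort ----
  say("building cohort")
  ccfg <- cohort_config(cfg$cohort$index_start, cfg$cohort$index_end,
                        cfg$cohort$history_cutoff,
                        cfg$cohort$washout_months, cfg$window_days)
  ch <- build_cohort(records, ccfg)
  members <- stage("cohort", nrow(records), ch$members)
  write_members(members, file.path(out_dir, "cohort.tsv"))
  jsonlite::write_json(ch$exclusions, file.path(out_dir,
                                                "exclusions.json"),
                       auto_unbox = TRUE, digits = NA)

  # ---- query ratios (Table-1 style, full cohort and sustained) ----
  say("computing query ratios")
  qr_for <- function(mem) {
    rbindlist(lapply(list(sym, con), function(lex) {
      tab <- query_ratio_table(mem, records, lex, cfg$window_days,
                               cfg$min_support,
                               denominator = cfg$denominator, span = span)
      rank_concepts(tab, top_k = cfg$top_k)
    }), use.names = TRUE, fill = TRUE)
  }
  qr_all <- stage("qr_all", nrow(members), qr_for(members))
  qr_sus <- stage("qr_sustained", sum(members$interest == "sustained"),
                  qr_for(members[interest == "sustained"]))
  fwrite_tsv(qr_all, file.path(out_dir, "qr_all.tsv"))
  fwrite_tsv(qr_sus, file.path(out_dir, "qr_sustained.tsv"))

  # ---- temporal profile ----
  pconcept <- cfg$profile$concept
  plex <- if (pconcept %in% lexicon_concepts(sym)) sym else con
  prof <- stage("profile", nrow(members),
                temporal_profile(members, records, plex, pconcept,
                                 cfg$profile$range_days))
  fwrite_tsv(prof, file.path(out_dir, paste0(
    "profile_", gsub("[^a-z0-9]+", "_", pconcept), ".tsv")))

  # ---- dietary shifts ----
  say("ranking food changes")
  fc <- rank_food_changes(members, records, rmap, cfg$window_days,
                          cfg$recipes$min_support, cfg$top_k,
                          isTRUE(cfg$recipes$sustained_only), span)
  stage("recipes", nrow(members), fc$changes)
  fwrite_tsv(food_change_table(fc), file.path(out_dir,
                                              "food_changes.tsv"))

  # ---- classifier ----
  say("evaluating classifier")
  auc_out <- classify_stage(cfg, members, records, sym, con, seed)
  stage("classify", nrow(members),
        if (is.null(auc_out$fold_auc)) NULL else
          as.data.table(auc_out["fold_auc"]))
  jsonlite::write_json(auc_out, file.path(out_dir, "auc.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")

  report <- list(seed = seed, config = config_echo(cfg),
                 exclusions = ch$exclusions, stages = stages)
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  say("done: %s", out_dir)
  invisible(report)
}

classify_stage <- function(cfg, members, records, sym, con, seed) {
  cc <- cfg$classify
  targets <- switch(cc$target_class,
                    all = members,
                    members[interest == cc$target_class])
  others <- setdiff(unique(records$user_id), members$user_id)
  n_cmp <- min(length(others), cc$comparison_ratio * nrow(targets))
  if (nrow(targets) < cc$min_targets || n_cmp < cc$min_targets) {
    return(list(model = cc$model, skipped = TRUE,
                reason = "too few users in a class",
                n_target = nrow(targets), n_comparison = n_cmp,
                mean_auc = NULL, fold_auc = NULL))
  }
  cmp <- with_seed(seed + 1L,
                   sort(others)[sample.int(length(others), n_cmp)])
  fm <- build_feature_matrix(targets, cmp, records, sym, con,
                             seed = seed + 2L)
  res <- evaluate_auc(fm, cc$model, cc$trees, cc$folds, seed = seed + 3L)
  list(model = res$model, skipped = FALSE, folds = res$folds,
       n_target = nrow(targets), n_comparison = n_cmp,
       mean_auc = res$mean_auc, fold_auc = res$fold_auc)
}

write_members <- function(members, path) {
  out <- copy(members)
  out[, t0 := format_instant(t0)]
  fwrite(out, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Read a cohort members table written by [run_pipeline()]
#' @param path Path to `cohort.tsv`.
#' @return Members `data.table` with parsed `t0`.
#' @export
read_members <- function(path) {
  m <- fread(path, sep = "\t", colClasses = list(character = "t0"))
  m[, t0 := parse_instant(t0)]
  m[]
}

fwrite_tsv <- function(x, path) {
  fwrite(format_numeric_cols(x), path, sep = "\t", quote = FALSE)
  invisible(path)
}

# fixed-format numbers so outputs are byte-stable across platforms
format_numeric_cols <- function(x) {
  x <- as.data.table(x)
  out <- copy(x)
  for (cn in names(out)) {
    if (is.double(out[[cn]])) {
      set(out, j = cn, value = sprintf("%.10g", out[[cn]]))
    }
  }
  out
}

config_echo <- function(cfg) {
  cfg$lexicons <- lapply(cfg$lexicons, basename)
  cfg$recipe_map <- basename(cfg$recipe_map)
  if (!is.null(cfg$log)) cfg$log <- basename(cfg$log)
  cfg
}
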