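#' Load a recipe-to-ingredient map
#'
#' File format (UTF-8, `#` comment lines ignored): one recipe per line with
#' tab-separated fields `recipe_id`, zero or more synonym phrases, a literal
#' `|` separator field, then one or more ingredient names:
#'
#' ```
#' cucumber_salad<TAB>cucumber salad recipe<TAB>|<TAB>cucumber<TAB>vinegar
#' ```
#'
#' The recipe id, normalized (underscores become spaces), is always added
#' as a synonym. Every recipe must have at least one ingredient; ingredient
#' ids are shared across recipes, which is what lets ingredient-level
#' counts inherit from every dish containing them. A demonstration map with
#' gluten-free and conventional dishes ships under
#' `system.file("extdata", "recipes.tsv", package = "querysignal")`.
#'
#' @param path Path to the map file.
#' @return A `recipe_map` object: `recipes` (named list with `synonyms`
#'   and `ingredients` per recipe) plus a flat synonym table.
#' @export
load_recipe_map <- function(path) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path)) {
    stop("cannot read recipe map file: ", path)
  }
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (!length(lines)) stop("empty recipe map file: ", path)
  recipes <- list()
  for (ln in lines) {
    f <- trimws(strsplit(ln, "\t", fixed = TRUE)[[1L]])
    bar <- which(f == "|")
    if (length(bar) != 1L || bar == length(f)) {
      stop("malformed recipe map line (need id, synonyms, '|', ",
           "ingredients): ", ln)
    }
    id <- f[1L]
    syn <- unique(c(normalize_text(id),
                    normalize_text(f[seq_len(bar - 1L)][-1L])))
    syn <- syn[nzchar(syn)]
    ingredients <- unique(normalize_text(f[(bar + 1L):length(f)]))
    ingredients <- ingredients[nzchar(ingredients)]
    if (!length(ingredients)) stop("recipe '", id, "' has no ingredients")
    if (id %in% names(recipes)) stop("duplicate recipe id: ", id)
    recipes[[id]] <- list(synonyms = syn, ingredients = ingredients)
  }
  syn_table <- data.table(
    recipe_id = rep(names(recipes),
                    vapply(recipes, function(r) length(r$synonyms), 0L)),
    phrase = unlist(lapply(recipes, `[[`, "synonyms"), use.names = FALSE)
  )
  dup <- syn_table[, .(n = uniqueN(recipe_id)), by = phrase][n > 1L]
  if (nrow(dup)) {
    stop("recipe synonym maps to more than one recipe: '", dup$phrase[1L],
         "'")
  }
  syn_table[, nwords := lengths(strsplit(phrase, " ", fixed = TRUE))]
  setorderv(syn_table, c("nwords", "phrase"), order = c(-1L, 1L))
  structure(list(recipes = recipes, syn_table = syn_table),
            class = "recipe_map")
}

#' @export
print.recipe_map <- function(x, ...) {
  n_ing <- length(unique(unlist(lapply(x$recipes, `[[`, "ingredients"))))
  cat(sprintf("<recipe_map> %d recipes, %d distinct ingredients\n",
              length(x$recipes), n_ing))
  invisible(x)
}

#' Recipe ids defined by a map
#' @param recipe_map A `recipe_map`.
#' @return Character vector of recipe ids.
#' @export
recipe_ids <- function(recipe_map) names(recipe_map$recipes)

#' Ingredient ids defined by a map
#' @param recipe_map A `recipe_map`.
#' @return Sorted character vector of distinct ingredient ids.
#' @export
ingredient_ids <- function(recipe_map) {
  sort(unique(unlist(lapply(recipe_map$recipes, `[[`, "ingredients"),
                     use.names = FALSE)))
}

#' Detect recipe queries
#'
#' A query is a recipe query for a dish when a dish synonym matches at word
#' boundaries and either the query carries a recipe-intent cue word
#' (recipe, recipes, how to make, bake, baking, cook, cooking) or the
#' matched synonym has two or more words (multi-word dish names are
#' unambiguous on their own). When several dish synonyms match, the longest
#' wins.
#'
#' @param norm_text Character vector of normalized query text.
#' @param recipe_map A `recipe_map`.
#' @return Character vector of recipe ids (`NA` where no dish is
#'   detected).
#' @examples
#' \dontrun{
#' detect_recipe_query("gluten free banana bread recipe", rmap)
#' }
#' @export
detect_recipe_query <- function(norm_text, recipe_map) {
  n <- length(norm_text)
  out <- rep(NA_character_, n)
  if (!n) return(out)
  pad <- pad_words(norm_text)
  cues <- c("recipe", "recipes", "how to make", "bake", "baking", "cook",
            "cooking")
  has_cue <- rep(FALSE, n)
  for (cc in cues) has_cue <- has_cue | grepl(pad_words(cc), pad,
                                              fixed = TRUE)
  st <- recipe_map$syn_table  # sorted longest-first
  for (j in seq_len(nrow(st))) {
    open <- is.na(out)
    if (!any(open)) break
    hit <- open & grepl(pad_words(st$phrase[j]), pad, fixed = TRUE) &
      (has_cue | st$nwords[j] >= 2L)
    out[hit] <- st$recipe_id[j]
  }
  out
}

#' Rank foods and ingredients by change across the first CRQ
#'
#' Detects recipe queries in each admitted member's before and after
#' windows, pools dish counts over members, propagates them to ingredients
#' through the recipe-to-ingredient map (an ingredient's count is the sum
#' over all dishes containing it), and scores each item with the smoothed
#' log-ratio `log((n_after + 0.5) / (n_before + 0.5))` — positive when the
#' item was searched more after the first CRQ. Items with fewer than
#' `min_support` total counts are dropped; "increased" is the `top_k` items
#' by descending score and "decreased" by ascending score, ties broken by
#' larger total count then lexicographic id. Swapping the before and after
#' windows negates every score exactly.
#'
#' @inheritParams query_ratio_table
#' @param recipe_map A `recipe_map` from [load_recipe_map()].
#' @param min_support Minimum `n_before + n_after` for an item to be
#'   ranked.
#' @param top_k Rows per direction and item kind.
#' @param sustained_only If `TRUE`, restrict to sustained-interest members.
#' @return List of class `food_changes`: `changes` (all scored items:
#'   `item_id`, `item_kind` food/ingredient, `n_before`, `n_after`,
#'   `change_score`), and per-kind `increased`/`decreased` top lists under
#'   `foods` and `ingredients`.
#' @export
rank_food_changes <- function(members, records, recipe_map,
                              window_days = 14L, min_support = 5L,
                              top_k = 10L, sustained_only = FALSE,
                              span = NULL) {
  if (inherits(members, "cohort")) members <- members$members
  span <- span %||% span_from_records(records)
  if (sustained_only && nrow(members)) {
    members <- members[interest == "sustained"]
  }
  adm <- member_windows(members, window_days, span, "complete")
  wq <- window_queries(adm, records, window_days)

  food <- data.table(item_id = recipe_ids(recipe_map), item_kind = "food")
  if (nrow(wq)) {
    rid <- detect_recipe_query(wq$norm_text, recipe_map)
    tab <- data.table(item_id = rid, side = wq$side)[!is.na(item_id)]
    cnt <- dcast(tab, item_id ~ side, fun.aggregate = length,
                 value.var = "item_id")
    for (cn in c("before", "after")) {
      if (!cn %in% names(cnt)) cnt[, (cn) := 0L]
    }
    food <- merge(food, cnt[, .(item_id, n_before = before,
                                n_after = after)],
                  by = "item_id", all.x = TRUE)
  } else {
    food[, `:=`(n_before = 0L, n_after = 0L)]
  }
  for (cn in c("n_before", "n_after")) {
    set(food, which(is.na(food[[cn]])), cn, 0L)
  }

  # ingredient counts are a linear image of food counts through the
  # recipe -> ingredient incidence structure
  inc <- rbindlist(lapply(recipe_ids(recipe_map), function(id) {
    data.table(item_id = recipe_map$recipes[[id]]$ingredients,
               recipe_id = id)
  }))
  ing <- merge(inc, food[, .(recipe_id = item_id, n_before, n_after)],
               by = "recipe_id")[
    , .(n_before = sum(n_before), n_after = sum(n_after)), by = item_id]
  ing <- merge(data.table(item_id = ingredient_ids(recipe_map)), ing,
               by = "item_id", all.x = TRUE)
  for (cn in c("n_before", "n_after")) {
    set(ing, which(is.na(ing[[cn]])), cn, 0L)
  }
  ing[, item_kind := "ingredient"]

  changes <- rbind(food[, .(item_id, item_kind, n_before, n_after)],
                   ing[, .(item_id, item_kind, n_before, n_after)])
  changes[, change_score := log((n_after + 0.5) / (n_before + 0.5))]
  setorderv(changes, c("item_kind", "item_id"))

  kept <- changes[n_before + n_after >= min_support]
  top <- function(kind, direction) {
    x <- kept[item_kind == kind]
    if (!nrow(x)) return(x)
    x <- copy(x)[, n_total := n_before + n_after]
    ord <- if (direction == "increased") -1L else 1L
    setorderv(x, c("change_score", "n_total", "item_id"),
              order = c(ord, -1L, 1L))
    head(x[, n_total := NULL], top_k)
  }
  structure(list(
    changes = changes,
    foods = list(increased = top("food", "increased"),
                 decreased = top("food", "decreased")),
    ingredients = list(increased = top("ingredient", "increased"),
                       decreased = top("ingredient", "decreased")),
    n_members = nrow(adm)
  ), class = "food_changes")
}

#' Flatten a `food_changes` result into one table
#'
#' All scored items with a `direction` column marking membership in the
#' top increased/decreased lists (empty otherwise).
#'
#' @param fc A `food_changes` object from [rank_food_changes()].
#' @return `data.table` with columns `item_id`, `item_kind`, `n_before`,
#'   `n_after`, `change_score`, `direction`.
#' @export
food_change_table <- function(fc) {
  stopifnot(inherits(fc, "food_changes"))
  out <- copy(fc$changes)
  up <- rbind(fc$foods$increased, fc$ingredients$increased)
  down <- rbind(fc$foods$decreased, fc$ingredients$decreased)
  out[, direction := ""]
  out[up, on = c("item_id", "item_kind"), direction := "increased"]
  out[down, on = c("item_id", "item_kind"), direction := "decreased"]
  out[]
}

#' @export
print.food_changes <- function(x, ...) {
  cat(sprintf("<food_changes> %d items scored over %d members\n",
              nrow(x$changes), x$n_members))
  if (nrow(x$foods$increased)) {
    cat("  top increased foods:",
        paste(head(x$foods$increased$item_id, 5L), collapse = ", "), "\n")
  }
  if (nrow(x$foods$decreased)) {
    cat("  top decreased foods:",
        paste(head(x$foods$decreased$item_id, 5L), collapse = ", "), "\n")
  }
  invisible(x)
}
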