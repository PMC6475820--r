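#' Build a concept lexicon from a synonym table
#'
#' A lexicon maps canonical concept ids (e.g. symptom names) to lists of
#' synonym phrases. All phrases are normalized with [normalize_text()]; the
#' concept id itself (normalized) is always included as a synonym. A phrase
#' may belong to only one concept within a category: duplicates across
#' concepts are an error naming the offending phrase.
#'
#' @param entries Named list: concept id -> character vector of synonym
#'   phrases (possibly empty; the concept name itself is always added).
#' @param category One of `"symptom"`, `"condition"`, `"indicator"`,
#'   `"recipe"`.
#' @return A `lexicon` object.
#' @export
as_lexicon <- function(entries,
                       category = c("symptom", "condition", "indicator",
                                    "recipe")) {
  category <- match.arg(category)
  if (!length(entries) || is.null(names(entries))) {
    stop("lexicon entries must be a non-empty named list")
  }
  ids <- names(entries)
  entries <- lapply(seq_along(entries), function(i) {
    syn <- unique(c(normalize_text(ids[[i]]),
                    normalize_text(as.character(entries[[i]]))))
    syn <- syn[nzchar(syn)]
    if (!length(syn)) stop("concept '", ids[[i]], "' has no usable synonym")
    syn
  })
  names(entries) <- ids

  phrases <- data.table(
    concept_id = rep(ids, lengths(entries)),
    phrase = unlist(entries, use.names = FALSE)
  )
  dup <- phrases[, .(n = uniqueN(concept_id)), by = phrase][n > 1L]
  if (nrow(dup)) {
    stop("synonym phrase maps to more than one concept: '",
         dup$phrase[1L], "'")
  }
  phrases <- unique(phrases)
  phrases[, nwords := lengths(strsplit(phrase, " ", fixed = TRUE))]

  structure(list(category = category, entries = entries, phrases = phrases,
                 prefix_pairs = word_prefix_pairs(phrases)),
            class = "lexicon")
}

# Pairs of phrases from *different* concepts where `short` is a word-prefix
# of `long`; used for the longest-phrase-wins rule at match time.
word_prefix_pairs <- function(phrases) {
  out <- list()
  ph <- phrases$phrase
  cid <- phrases$concept_id
  for (i in seq_along(ph)) {
    longer <- startsWith(ph, paste0(ph[i], " ")) & cid != cid[i]
    if (any(longer)) {
      out[[length(out) + 1L]] <- data.table(short = ph[i],
                                            long = ph[longer])
    }
  }
  if (length(out)) rbindlist(out) else data.table(short = character(),
                                                  long = character())
}

#' Load a concept lexicon from a TSV file
#'
#' File format: `concept_id<TAB>synonym`, one synonym per line, UTF-8,
#' lines starting with `#` ignored. The concept id is implicitly its own
#' synonym. Small demonstration symptom and condition lexicons ship with the
#' package under `system.file("extdata", package = "querysignal")`; full
#' production lexicons (e.g. a 195-symptom list) are supplied by the user in
#' the same format.
#'
#' @param path Path to the TSV file.
#' @inheritParams as_lexicon
#' @return A `lexicon` object.
#' @examples
#' lex <- load_lexicon(system.file("extdata", "symptoms.tsv",
#'                                 package = "querysignal"), "symptom")
#' lex
#' @export
load_lexicon <- function(path,
                         category = c("symptom", "condition", "indicator",
                                      "recipe")) {
  category <- match.arg(category)
  if (!is.character(path) || length(path) != 1L || !file.exists(path)) {
    stop("cannot read lexicon file: ", path)
  }
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (!length(lines)) stop("empty lexicon file: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 2L)) {
    stop("malformed lexicon line (need concept_id<TAB>synonym) in ", path)
  }
  concept <- trimws(vapply(parts, `[[`, "", 1L))
  synonym <- vapply(parts, `[[`, "", 2L)
  entries <- split(synonym, factor(concept, levels = unique(concept)))
  as_lexicon(as.list(entries), category)
}

#' @export
print.lexicon <- function(x, ...) {
  cat(sprintf("<lexicon> category=%s, %d concepts, %d synonym phrases\n",
              x$category, length(x$entries), nrow(x$phrases)))
  invisible(x)
}

#' Concept ids defined by a lexicon
#' @param lexicon A `lexicon` object.
#' @return Character vector of concept ids.
#' @export
lexicon_concepts <- function(lexicon) names(lexicon$entries)

#' Match lexicon concepts in one normalized query
#'
#' A synonym matches iff it occurs in `norm_text` as a contiguous word
#' sequence at word boundaries ("cardiarrhea" does not match "diarrhea").
#' Each concept is reported at most once per query. When one matched synonym
#' is a word-prefix of another matched synonym from a different concept and
#' occurs only as that prefix, only the longer phrase's concept is kept.
#'
#' @param norm_text A single normalized query string (see
#'   [normalize_text()]).
#' @param lexicon A `lexicon` object.
#' @return `data.table` with columns `concept_id`, `category`, `phrase`
#'   (zero rows when nothing matches).
#' @examples
#' lex <- as_lexicon(list(diarrhea = "loose stools", headache = character()),
#'                   "symptom")
#' match_concepts("i have diarrhea and headache", lex)
#' @export
match_concepts <- function(norm_text, lexicon) {
  stopifnot(length(norm_text) == 1L)
  hits <- match_concepts_bulk(norm_text, lexicon, keep_phrase = TRUE)
  hits[, .(concept_id, category = lexicon$category, phrase)]
}

# Vectorized matcher used throughout the pipeline. Returns a data.table with
# one row per (query index, concept) pair: columns `.idx`, `concept_id`
# (plus `phrase` when keep_phrase). Queries are indexed into `texts`.
match_concepts_bulk <- function(texts, lexicon, keep_phrase = FALSE) {
  empty <- data.table(.idx = integer(), concept_id = character(),
                      phrase = character())
  if (!length(texts)) {
    return(if (keep_phrase) empty else empty[, .(.idx, concept_id)])
  }
  pad <- pad_words(texts)
  ph <- lexicon$phrases
  hits <- vector("list", nrow(ph))
  for (j in seq_len(nrow(ph))) {
    idx <- grep(pad_words(ph$phrase[j]), pad, fixed = TRUE)
    if (length(idx)) {
      hits[[j]] <- data.table(.idx = idx, concept_id = ph$concept_id[j],
                              phrase = ph$phrase[j])
    }
  }
  H <- rbindlist(hits)
  if (!nrow(H)) {
    return(if (keep_phrase) empty else empty[, .(.idx, concept_id)])
  }
  H <- resolve_prefix_matches(H, pad, lexicon$prefix_pairs)
  H <- unique(H, by = c(".idx", "concept_id"))
  if (keep_phrase) H[order(.idx, concept_id)] else
    H[order(.idx, concept_id), .(.idx, concept_id)]
}

# Drop a matched short phrase when every occurrence of it in the query is
# the word-prefix of an occurrence of a longer matched phrase belonging to a
# different concept. Word positions are compared on a double-spaced copy of
# the text so that adjacent occurrences are all enumerable with fixed-string
# search.
resolve_prefix_matches <- function(H, pad, prefix_pairs) {
  if (!nrow(prefix_pairs)) return(H)
  pp <- prefix_pairs[short %in% H$phrase & long %in% H$phrase]
  if (!nrow(pp)) return(H)
  drop <- vector("list", 0L)
  for (k in seq_len(nrow(pp))) {
    p <- pp$short[k]; q <- pp$long[k]
    both <- intersect(H[phrase == p, .idx], H[phrase == q, .idx])
    for (i in both) {
      txt2 <- gsub(" ", "  ", pad[i], fixed = TRUE)
      pat_p <- pad_words(gsub(" ", "  ", p, fixed = TRUE))
      pat_q <- pad_words(gsub(" ", "  ", q, fixed = TRUE))
      sp <- gregexpr(pat_p, txt2, fixed = TRUE)[[1L]]
      sq <- gregexpr(pat_q, txt2, fixed = TRUE)[[1L]]
      if (sp[1L] != -1L && sq[1L] != -1L && all(sp %in% sq)) {
        drop[[length(drop) + 1L]] <- data.table(.idx = i, phrase = p)
      }
    }
  }
  if (!length(drop)) return(H)
  drop <- rbindlist(drop)
  H[!drop, on = c(".idx", "phrase")]
}

utils::globalVariables(c("short", "long", "n"))
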