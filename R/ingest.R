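#' Normalize free query text
#'
#' Lowercases the text, replaces every maximal run of non-alphanumeric
#' characters (punctuation, hyphens, extra whitespace, non-ASCII symbols) by a
#' single space, and strips leading/trailing spaces. All phrase matching in
#' the package operates on text in this form, so "gluten-free" and
#' "gluten free" are indistinguishable downstream. The function is
#' idempotent: `normalize_text(normalize_text(x)) == normalize_text(x)`.
#'
#' @param x Character vector of raw query text (may be empty strings).
#' @return Character vector of the same length, normalized.
#' @examples
#' normalize_text("Gluten-Free Pancakes!")
#' @export
normalize_text <- function(x) {
  x <- tolower(as.character(x))
  x <- gsub("[^a-z0-9]+", " ", x)
  trimws(x)
}

#' Read and validate a per-user query log
#'
#' Reads a tab-separated query log (columns: `user_id`,
#' ISO-8601 timestamp `YYYY-MM-DDTHH:MM:SS`, query text, optional 5-character
#' zip code; UTF-8; no header unless `header = TRUE`), normalizes query text,
#' and rejects malformed lines with an itemized report. Accepted records are
#' returned sorted by `(user_id, timestamp)` with a stable sort, so ties at
#' identical timestamps keep file order and downstream "first CRQ" selection
#' is deterministic. Timestamps are timezone-naive and interpreted on a
#' single log-local clock.
#'
#' A line is rejected (and counted once, under the first failing check) when
#' it has fewer than 3 or more than 4 tab-separated fields, its timestamp
#' does not parse, its date falls outside `span`, or its query text is empty
#' after trimming. Lines with 3 fields are accepted with an empty zip code.
#'
#' @param path Path to the log file.
#' @param span A [log_span()]; records dated outside it are rejected.
#' @param header If `TRUE`, skip one header line.
#' @return A list of class `query_log` with elements `records` (a
#'   `data.table` with columns `user_id`, `timestamp` (POSIXct), `raw_text`,
#'   `norm_text`, `zip_code`) and `report` (line counts:
#'   `n_lines`, `n_accepted`, and rejected counts `wrong_columns`,
#'   `bad_timestamp`, `out_of_span`, `empty_query`).
#' @seealso [write_query_log()]
#' @export
read_query_log <- function(path, span, header = FALSE) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path)) {
    stop("cannot read query log file: ", path)
  }
  stopifnot(inherits(span, "log_span"))
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  if (header && length(lines)) lines <- lines[-1L]
  n_lines <- length(lines)

  rep0 <- list(n_lines = n_lines, n_accepted = 0L,
               rejected = list(wrong_columns = 0L, bad_timestamp = 0L,
                               out_of_span = 0L, empty_query = 0L))
  if (n_lines == 0L) {
    return(structure(list(records = empty_records(), report = rep0),
                     class = "query_log"))
  }

  parts <- data.table::tstrsplit(lines, "\t", fixed = TRUE)
  # tstrsplit drops trailing empty fields, so an empty zip yields 3 fields
  if (length(parts) < 4L) {
    parts <- c(parts, rep(list(rep(NA_character_, n_lines)),
                          4L - length(parts)))
  }
  nf <- Reduce(`+`, lapply(parts, function(p) !is.na(p)))
  ok_cols <- nf >= 3L & nf <= 4L

  ts <- parse_instant(parts[[2L]])
  ok_ts <- ok_cols & !is.na(ts)
  qdate <- instant_date(ts)
  ok_span <- ok_ts & !is.na(qdate) & qdate >= span$start & qdate <= span$end
  text <- trimws(parts[[3L]])
  ok_text <- ok_span & !is.na(text) & nzchar(text)

  rejected <- list(
    wrong_columns = sum(!ok_cols),
    bad_timestamp = sum(ok_cols & !ok_ts),
    out_of_span = sum(ok_ts & !ok_span),
    empty_query = sum(ok_span & !ok_text)
  )
  n_rej <- sum(unlist(rejected))
  if (n_rej > 0.5 * n_lines) {
    stop(sprintf(
      "more than half of the lines in '%s' were rejected (%d of %d); %s",
      path, n_rej, n_lines, "is this really a 4-column TSV query log?"))
  }

  keep <- which(ok_text)
  zip <- parts[[4L]][keep]
  zip[is.na(zip) | !nzchar(trimws(zip))] <- NA_character_
  records <- data.table(
    user_id = parts[[1L]][keep],
    timestamp = ts[keep],
    raw_text = parts[[3L]][keep],
    norm_text = normalize_text(parts[[3L]][keep]),
    zip_code = trimws(zip)
  )
  setorderv(records, c("user_id", "timestamp"))  # radix sort: stable on ties

  report <- list(n_lines = n_lines, n_accepted = length(keep),
                 rejected = rejected)
  structure(list(records = records, report = report), class = "query_log")
}

empty_records <- function() {
  data.table(user_id = character(), timestamp = parse_instant(character()),
             raw_text = character(), norm_text = character(),
             zip_code = character())
}

#' @export
print.query_log <- function(x, ...) {
  r <- x$report
  cat(sprintf("<query_log> %d records accepted of %d lines\n",
              r$n_accepted, r$n_lines))
  rej <- unlist(r$rejected)
  if (sum(rej) > 0) {
    cat("  rejected:", paste(names(rej), rej, sep = "=", collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Write query records back to the on-disk log format
#'
#' Inverse of [read_query_log()]: records written with this function and
#' re-read (under a covering span) yield an identical record sequence.
#'
#' @param records A records `data.table` as returned by [read_query_log()]
#'   or [generate_logs()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_query_log <- function(records, path) {
  out <- data.table(
    records$user_id,
    format_instant(records$timestamp),
    records$raw_text,
    fifelse(is.na(records$zip_code), "", records$zip_code)
  )
  fwrite(out, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}
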