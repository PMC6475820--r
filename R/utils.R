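DAY_SECONDS <- 86400

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

parse_instant <- function(x) {
  as.POSIXct(x, format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")
}

format_instant <- function(ts) format(ts, "%Y-%m-%dT%H:%M:%S", tz = "UTC")

instant_date <- function(ts) as.Date(ts, tz = "UTC")

#' Define an inclusive calendar span for a query log
#'
#' @param start,end First and last calendar date covered by the log
#'   (inclusive), as `Date` or `"YYYY-MM-DD"` strings.
#' @return A `log_span` object (list with `start` and `end` dates).
#' @examples
#' log_span("2017-01-01", "2017-10-31")
#' @export
log_span <- function(start, end) {
  start <- as.Date(start)
  end <- as.Date(end)
  if (is.na(start) || is.na(end)) stop("log_span: unparseable date")
  if (start > end) stop("log_span: start date is after end date")
  structure(list(start = start, end = end), class = "log_span")
}

#' @export
print.log_span <- function(x, ...) {
  cat(sprintf("<log_span> %s .. %s (%d days)\n", x$start, x$end,
              as.integer(x$end - x$start) + 1L))
  invisible(x)
}

span_start_instant <- function(span) {
  as.POSIXct(paste(span$start, "00:00:00"), tz = "UTC")
}

# First instant *after* the span (exclusive upper bound).
span_end_instant <- function(span) {
  as.POSIXct(paste(span$end + 1L, "00:00:00"), tz = "UTC")
}

# Span inferred from the data when the caller does not supply one.
span_from_records <- function(records) {
  d <- instant_date(records$timestamp)
  log_span(min(d), max(d))
}

months_before <- function(date, k) {
  seq(as.Date(date), by = paste0("-", k, " month"), length.out = 2L)[2L]
}

pad_words <- function(x) paste0(" ", x, " ")

# Rate rounding used for cohort summaries: one decimal at or above 1%,
# two decimals below (matches how small subgroup rates are usually printed).
round_rate <- function(x) ifelse(x >= 1, round(x, 1), round(x, 2))
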