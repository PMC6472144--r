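#' Read a tweet table from JSONL or CSV
#'
#' Reads one tweet per row/line into a data frame with columns
#' `user_id`, `timestamp` (POSIXct, UTC-stored), `text` and
#' `is_retweet`. JSONL files carry one JSON object per line; CSV files
#' need a header. Column names can be remapped through `columns`.
#' Unparseable rows (bad JSON, missing fields, bad timestamps) are
#' skipped and counted; more than `tolerance` bad rows is an error.
#'
#' @param path Input file.
#' @param format `"jsonl"` or `"csv"`; default guessed from extension.
#' @param columns Named character vector mapping the canonical names
#'   `user_id`, `timestamp`, `text`, `is_retweet` to the file's column
#'   names. `is_retweet` may be absent (then `NA`, see
#'   [filter_original()]).
#' @param tolerance Maximum number of unparseable rows (default 0).
#' @return Data frame of tweet records, in file order; attribute
#'   `n_bad_rows` counts skipped rows.
#' @export
read_tweets <- function(path,
                        format = c("auto", "jsonl", "csv"),
                        columns = c(user_id = "user_id",
                                    timestamp = "timestamp",
                                    text = "text",
                                    is_retweet = "is_retweet"),
                        tolerance = 0L) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv"
              else "jsonl"
  }
  defaults <- c(user_id = "user_id", timestamp = "timestamp",
                text = "text", is_retweet = "is_retweet")
  defaults[names(columns)] <- columns
  columns <- defaults

  if (format == "csv") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE,
                          check.names = FALSE)
    for (fld in c("user_id", "timestamp", "text")) {
      if (!columns[[fld]] %in% names(df))
        stop("tweet CSV '", path, "' is missing mandatory column '",
             columns[[fld]], "' (", fld, ")")
    }
    raw <- data.frame(
      user_id = as.character(df[[columns[["user_id"]]]]),
      timestamp_raw = as.character(df[[columns[["timestamp"]]]]),
      text = as.character(df[[columns[["text"]]]]),
      is_retweet = if (columns[["is_retweet"]] %in% names(df))
        as.logical(df[[columns[["is_retweet"]]]]) else NA,
      stringsAsFactors = FALSE)
    line_no <- seq_len(nrow(raw)) + 1L
  } else {
    lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
    keep <- nzchar(trimws(lines))
    lines <- lines[keep]
    line_no <- which(keep)
    objs <- lapply(lines, function(ln)
      tryCatch(jsonlite::fromJSON(ln), error = function(e) NULL))
    get_chr <- function(o, fld) {
      v <- o[[columns[[fld]]]]
      if (is.null(v) || length(v) != 1L) NA_character_ else as.character(v)
    }
    raw <- data.frame(
      user_id = vapply(objs, function(o)
        if (is.null(o)) NA_character_ else get_chr(o, "user_id"), ""),
      timestamp_raw = vapply(objs, function(o)
        if (is.null(o)) NA_character_ else get_chr(o, "timestamp"), ""),
      text = vapply(objs, function(o)
        if (is.null(o)) NA_character_ else get_chr(o, "text"), ""),
      is_retweet = vapply(objs, function(o) {
        if (is.null(o)) return(NA)
        v <- o[[columns[["is_retweet"]]]]
        if (is.null(v) || length(v) != 1L) NA else as.logical(v)
      }, NA),
      stringsAsFactors = FALSE)
  }

  ts <- parse_timestamp(raw$timestamp_raw)
  bad <- is.na(ts) | is.na(raw$user_id) | !nzchar(raw$user_id) |
    is.na(raw$text)
  if (sum(bad) > tolerance) {
    stop("'", path, "': ", sum(bad), " unparseable row(s) exceed ",
         "tolerance ", tolerance, "; first bad line: ",
         line_no[which(bad)[1L]])
  }
  out <- data.frame(user_id = raw$user_id[!bad],
                    timestamp = ts[!bad],
                    text = raw$text[!bad],
                    is_retweet = raw$is_retweet[!bad],
                    stringsAsFactors = FALSE)
  attr(out, "n_bad_rows") <- sum(bad)
  out
}

# ISO-8601 (with optional offset / 'Z') or "YYYY-mm-dd HH:MM:SS";
# returns POSIXct in UTC
parse_timestamp <- function(x) {
  x <- trimws(x)
  x[!nzchar(x)] <- NA
  iso <- sub("Z$", "+0000", x)
  iso <- sub("([+-][0-9]{2}):([0-9]{2})$", "\\1\\2", iso)
  fmts <- c("%Y-%m-%dT%H:%M:%S%z", "%Y-%m-%d %H:%M:%S%z",
            "%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S", "%Y-%m-%d")
  out <- as.POSIXct(rep(NA_real_, length(x)), origin = "1970-01-01",
                    tz = "UTC")
  left <- !is.na(x)
  for (f in fmts) {
    if (!any(left)) break
    p <- as.POSIXct(iso[left], format = f, tz = "UTC")
    got <- !is.na(p)
    out[which(left)[got]] <- p[got]
    left[left] <- !got
  }
  out
}

#' Keep only original tweets
#'
#' Drops retweets: records whose `is_retweet` flag is `TRUE`, and — when
#' the flag is absent (`NA`) — records whose text starts with the
#' literal prefix `"RT @"`. Idempotent.
#'
#' @param records Tweet data frame as from [read_tweets()].
#' @return The filtered data frame.
#' @export
filter_original <- function(records) {
  rt <- records$is_retweet
  if (is.null(rt)) rt <- rep(NA, nrow(records))
  drop <- (!is.na(rt) & rt) |
    (is.na(rt) & startsWith(records$text, "RT @"))
  out <- records[!drop, , drop = FALSE]
  if (nrow(out) == 0L && nrow(records) > 0L)
    warning("filter_original: all ", nrow(records),
            " records were retweets")
  rownames(out) <- NULL
  out
}

#' Assign each record to a local calendar day
#'
#' Maps timestamps to the calendar date and weekday under a timezone.
#' Day boundaries follow the affected community's local midnight
#' (default Europe/Paris). Weekday convention: Monday = 0 ... Sunday = 6.
#'
#' @param timestamps POSIXct vector (or a tweet data frame, in which
#'   case its `timestamp` column is used).
#' @param tz Timezone name; default `"Europe/Paris"`.
#' @return Data frame with columns `date` (Date) and `weekday`
#'   (integer 0-6, Monday = 0).
#' @export
assign_day <- function(timestamps, tz = "Europe/Paris") {
  if (is.data.frame(timestamps)) timestamps <- timestamps$timestamp
  if (!tz %in% OlsonNames())
    stop("unknown timezone: '", tz, "'")
  local <- format(timestamps, tz = tz, format = "%Y-%m-%d")
  date <- as.Date(local)
  # %u: Monday = 1 ... Sunday = 7
  wd <- as.integer(format(date, "%u")) - 1L
  data.frame(date = date, weekday = wd)
}

#' Analysis windows around the event day
#'
#' Bundles the four time windows of the individual-level analysis: a
#' pre-event baseline, the event day, a short post-event window and a
#' long post-event window. Defaults reproduce a 3-month baseline, a
#' 2-week short window starting on the event day, and the following
#' 3 months.
#'
#' @param event_day Event date (`Date` or string).
#' @param baseline_start,baseline_end Baseline window (default: 92 days
#'   ending the day before `event_day`).
#' @param short_start,short_end Short window (default: `event_day` and
#'   the following 14 days).
#' @param long_start,long_end Long window (default: the 3 months after
#'   the short window).
#' @return An object of class `study_windows`.
#' @examples
#' study_windows("2015-11-13")
#' @export
study_windows <- function(event_day,
                          baseline_start = NULL, baseline_end = NULL,
                          short_start = NULL, short_end = NULL,
                          long_start = NULL, long_end = NULL) {
  event_day <- as.Date(event_day)
  baseline_end <- if (is.null(baseline_end)) event_day - 1L
                  else as.Date(baseline_end)
  baseline_start <- if (is.null(baseline_start)) event_day - 92L
                    else as.Date(baseline_start)
  short_start <- if (is.null(short_start)) event_day
                 else as.Date(short_start)
  short_end <- if (is.null(short_end)) event_day + 14L
               else as.Date(short_end)
  long_start <- if (is.null(long_start)) short_end + 1L
                else as.Date(long_start)
  long_end <- if (is.null(long_end)) short_end + 92L
              else as.Date(long_end)
  if (!(baseline_start <= baseline_end && baseline_end < event_day))
    stop("study_windows: baseline must end before event_day")
  if (!(event_day <= short_start && short_start <= short_end))
    stop("study_windows: short window must start on or after event_day")
  if (!(short_end < long_start && long_start <= long_end))
    stop("study_windows: long window must follow the short window")
  structure(list(baseline_start = baseline_start,
                 baseline_end = baseline_end,
                 event_day = event_day,
                 short_start = short_start, short_end = short_end,
                 long_start = long_start, long_end = long_end),
            class = "study_windows")
}

#' @export
print.study_windows <- function(x, ...) {
  cat("<study_windows>\n",
      "  baseline: ", format(x$baseline_start), " .. ",
      format(x$baseline_end), "\n",
      "  event:    ", format(x$event_day), "\n",
      "  short:    ", format(x$short_start), " .. ",
      format(x$short_end), "\n",
      "  long:     ", format(x$long_start), " .. ",
      format(x$long_end), "\n", sep = "")
  invisible(x)
}

#' Write a tweet table as JSONL
#'
#' One JSON object per line with fields `user_id`, `timestamp`
#' (ISO-8601 with numeric offset), `text`, `is_retweet`; the format
#' [read_tweets()] reads back.
#'
#' @param records Tweet data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tweets_jsonl <- function(records, path) {
  ts <- format(records$timestamp, format = "%Y-%m-%dT%H:%M:%S%z")
  lines <- vapply(seq_len(nrow(records)), function(i)
    jsonlite::toJSON(list(user_id = records$user_id[i],
                          timestamp = ts[i],
                          text = records$text[i],
                          is_retweet = isTRUE(records$is_retweet[i])),
                     auto_unbox = TRUE), "")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

# which window does each date fall in? -> factor baseline/short/long/NA
window_of <- function(dates, windows) {
  out <- rep(NA_character_, length(dates))
  out[dates >= windows$baseline_start &
        dates <= windows$baseline_end] <- "baseline"
  out[dates >= windows$short_start & dates <= windows$short_end] <- "short"
  out[dates >= windows$long_start & dates <= windows$long_end] <- "long"
  out
}
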