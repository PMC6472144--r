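#' Daily mean lexical indicator over a tweet stream
#'
#' Computes, for each local calendar day, the unweighted mean of the
#' per-tweet indicator fractions for one lexicon. Tweets with no tokens
#' carry no fraction and are excluded; days with no usable tweets get a
#' missing mean. All days spanned by the data appear in the result.
#'
#' @param records Tweet data frame ([read_tweets()] layout).
#' @param lex A [lexicon()].
#' @param tz Timezone for day boundaries (default Europe/Paris).
#' @return Data frame of class `daily_series`: `date`, `weekday`
#'   (Monday = 0), `n_tweets` (usable tweets), `mean_fraction`. The
#'   per-tweet fractions of each day are kept in attribute
#'   `day_fractions` for bootstrap use.
#' @export
daily_mean <- function(records, lex, tz = "Europe/Paris") {
  stopifnot(is_lexicon(lex))
  fr <- indicator_fractions(records$text, lex)
  day <- assign_day(records$timestamp, tz = tz)
  ok <- !is.na(fr)
  all_days <- seq(min(day$date), max(day$date), by = "day")
  f_by_day <- split(fr[ok], factor(as.character(day$date[ok]),
                                   levels = as.character(all_days)))
  out <- data.frame(
    date = all_days,
    weekday = as.integer(format(all_days, "%u")) - 1L,
    n_tweets = as.integer(lengths(f_by_day)),
    mean_fraction = vapply(f_by_day, function(v)
      if (length(v)) mean(v) else NA_real_, 0.0))
  rownames(out) <- NULL
  attr(out, "day_fractions") <- f_by_day
  attr(out, "indicator") <- lex$name
  class(out) <- c("daily_series", "data.frame")
  out
}

#' Per-weekday baseline of a daily series
#'
#' Averages the daily mean fractions over a pre-event baseline window,
#' separately for each weekday, to absorb the weekly oscillation of
#' term frequencies.
#'
#' @param series A `daily_series` from [daily_mean()] (or any data frame
#'   with `date`, `weekday`, `mean_fraction`).
#' @param baseline_start,baseline_end Baseline window (inclusive); it
#'   must lie wholly before the event day being studied, which is the
#'   caller's responsibility.
#' @return Numeric vector `b[1..7]`, names `"0"`..`"6"` (Monday = 0).
#' @export
weekday_baseline <- function(series, baseline_start, baseline_end) {
  baseline_start <- as.Date(baseline_start)
  baseline_end <- as.Date(baseline_end)
  sel <- series$date >= baseline_start & series$date <= baseline_end &
    !is.na(series$mean_fraction)
  sub <- series[sel, , drop = FALSE]
  b <- vapply(0:6, function(w) {
    v <- sub$mean_fraction[sub$weekday == w]
    if (length(v)) mean(v) else NA_real_
  }, 0.0)
  names(b) <- as.character(0:6)
  if (anyNA(b)) {
    wd_names <- c("Monday", "Tuesday", "Wednesday", "Thursday",
                  "Friday", "Saturday", "Sunday")
    stop("weekday_baseline: no baseline data for ",
         paste(wd_names[which(is.na(b))], collapse = ", "))
  }
  b
}

#' Weekday-normalized daily log-ratio score
#'
#' The daily score of an indicator is the log of its daily mean over
#' the weekday-matched baseline, `s_t = log((m_t + eps) / (b_w + eps))`.
#' The additive smoothing `eps` is half the smallest non-zero daily mean
#' of the series when any daily mean is exactly zero, and zero
#' otherwise, so the log stays defined on sparse days and the score is
#' untouched on dense data.
#'
#' @param series A `daily_series` from [daily_mean()].
#' @param baselines Weekday baseline vector from [weekday_baseline()].
#' @return The series with columns `baseline` and `score` added;
#'   attribute `epsilon` records the smoothing used.
#' @export
normalized_score <- function(series, baselines) {
  if (any(baselines <= 0))
    stop("normalized_score: all weekday baselines must be positive")
  m <- series$mean_fraction
  eps <- 0
  if (any(m == 0, na.rm = TRUE)) {
    nz <- m[!is.na(m) & m > 0]
    if (length(nz) == 0L)
      stop("normalized_score: series has no non-zero daily means")
    eps <- min(nz) / 2
  }
  b <- unname(baselines[as.character(series$weekday)])
  series$baseline <- b
  series$score <- log((m + eps) / (b + eps))
  attr(series, "epsilon") <- eps
  series
}

#' Bootstrap uncertainty of one day's mean indicator
#'
#' Resamples the day's per-tweet fractions with replacement `B` times,
#' recomputing the day mean each time; reports the percentile median and
#' the `1 - alpha` interval.
#'
#' @param day_fractions Numeric vector of per-tweet fractions (no NAs).
#' @param B Number of bootstrap resamples (default 10000).
#' @param alpha Interval tail mass (default 0.05 for a 95% CI).
#' @param seed Integer seed; resampling is deterministic given it.
#' @return Named numeric: `median`, `ci_low`, `ci_high`.
#' @export
bootstrap_day <- function(day_fractions, B = 10000L, alpha = 0.05,
                          seed = 1L) {
  if (length(day_fractions) == 0L)
    stop("bootstrap_day: empty day")
  stopifnot(B >= 1L)
  n <- length(day_fractions)
  means <- with_seed(seed, {
    vapply(seq_len(B), function(i)
      mean(day_fractions[sample.int(n, n, replace = TRUE)]), 0.0)
  })
  q <- stats::quantile(means, c(alpha / 2, 0.5, 1 - alpha / 2),
                       names = FALSE)
  c(median = q[2L], ci_low = q[1L], ci_high = q[3L])
}

#' Full daily score pipeline for one indicator
#'
#' Convenience wrapper: daily means, weekday baselines over a stated
#' pre-event window, normalized scores, and (optionally) per-day
#' bootstrap summaries.
#'
#' @inheritParams daily_mean
#' @param baseline_start,baseline_end Baseline window for
#'   [weekday_baseline()].
#' @param B Bootstrap resamples per day; `0` skips the bootstrap.
#' @param alpha Bootstrap tail mass.
#' @param seed Seed for the per-day bootstrap.
#' @return A `daily_series` with `baseline`, `score` and (if `B > 0`)
#'   `boot_median`, `ci_low`, `ci_high` columns.
#' @export
score_daily <- function(records, lex, baseline_start, baseline_end,
                        tz = "Europe/Paris", B = 0L, alpha = 0.05,
                        seed = 1L) {
  series <- daily_mean(records, lex, tz = tz)
  b <- weekday_baseline(series, baseline_start, baseline_end)
  series <- normalized_score(series, b)
  if (B > 0L) {
    fr <- attr(series, "day_fractions")
    boot <- matrix(NA_real_, nrow(series), 3L)
    for (i in seq_len(nrow(series))) {
      v <- fr[[as.character(series$date[i])]]
      if (length(v))
        boot[i, ] <- bootstrap_day(v, B = B, alpha = alpha,
                                   seed = seed + i)
    }
    series$boot_median <- boot[, 1L]
    series$ci_low <- boot[, 2L]
    series$ci_high <- boot[, 3L]
  }
  series
}

#' Export a daily series to CSV
#'
#' @param series A `daily_series`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_daily_series <- function(series, path) {
  utils::write.csv(as.data.frame(series), path, row.names = FALSE)
  invisible(path)
}

# run code under a temporary RNG state seeded with `seed`
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  code
}
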