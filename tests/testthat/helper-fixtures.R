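# shared fixtures: tiny lexicons and tweet-table builders

toy_lexicon <- function() {
  lexicon("posemo", c("heureux", "content*", "joie"))
}

# build a tweet data frame from texts on given dates (noon, Paris time)
tweet_table <- function(texts, dates, user_id = "u1",
                        is_retweet = FALSE) {
  data.frame(
    user_id = rep_len(user_id, length(texts)),
    timestamp = as.POSIXct(paste(dates, "12:00:00"),
                           tz = "Europe/Paris"),
    text = texts,
    is_retweet = rep_len(is_retweet, length(texts)),
    stringsAsFactors = FALSE)
}

# daily_series-shaped frame built directly from scores/means
make_series <- function(dates, mean_fraction) {
  dates <- as.Date(dates)
  structure(
    data.frame(date = dates,
               weekday = as.integer(format(dates, "%u")) - 1L,
               n_tweets = 100L,
               mean_fraction = mean_fraction),
    class = c("daily_series", "data.frame"))
}

# simulate an AR(1) + impulse-shock daily score series for recovery
# tests: s_t = c + phi s_{t-1} + beta [t == event] + N(0, sd)
sim_shock_series <- function(phi, beta, n_before = 28L, n_after = 28L,
                             sd = 0.1, c0 = 0, event = as.Date("2015-11-13")) {
  dates <- seq(event - n_before, event + n_after, by = "day")
  n <- length(dates)
  s <- numeric(n)
  s[1L] <- stats::rnorm(1L, c0 / (1 - phi), sd / sqrt(1 - phi^2))
  for (t in 2:n)
    s[t] <- c0 + phi * s[t - 1L] + beta * (dates[t] == event) +
      stats::rnorm(1L, 0, sd)
  data.frame(date = dates, score = s)
}
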