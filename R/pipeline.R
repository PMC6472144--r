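#' Tweet stream to shock-model fit in one call
#'
#' Convenience pipeline for the collective-level analysis: daily mean
#' indicator, weekday baseline over a pre-event window, normalized
#' log-ratio scores, exogenous-shock memory-model fit.
#'
#' @param records Tweet data frame.
#' @param lex A [lexicon()].
#' @param event_day Event date.
#' @param baseline_start,baseline_end Baseline window for the weekday
#'   baselines; default the 183 days ending the day before
#'   `event_day`, truncated to the data span.
#' @param window_days Fit window half-width (see [fit_shock_model()]).
#' @param variant Shock form.
#' @param prior_scale Prior scale of the penalized fit.
#' @param tz Timezone for day boundaries.
#' @return A `shock_fit` (see [fit_shock_model()]); the scored
#'   `daily_series` is attached as attribute `series`.
#' @export
fit_collective_pipeline <- function(records, lex, event_day,
                                    baseline_start = NULL,
                                    baseline_end = NULL,
                                    window_days = 28L,
                                    variant = "impulse",
                                    prior_scale = 2.5,
                                    tz = "Europe/Paris") {
  event_day <- as.Date(event_day)
  series <- daily_mean(records, lex, tz = tz)
  if (is.null(baseline_end)) baseline_end <- event_day - 1L
  if (is.null(baseline_start))
    baseline_start <- max(min(series$date), event_day - 183L)
  b <- weekday_baseline(series, baseline_start, baseline_end)
  series <- normalized_score(series, b)
  fit <- fit_shock_model(series, event_day, window_days = window_days,
                         variant = variant, prior_scale = prior_scale)
  attr(fit, "series") <- series
  fit
}
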