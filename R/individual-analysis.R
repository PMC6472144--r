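#' Per-user window summaries of lexical indicators
#'
#' Pools each user's tokens within the baseline, short and long study
#' windows and computes per-category word-count fractions
#' (category tokens / all tokens) plus the quantities the downstream
#' analysis needs: the personality-related vector (positive affect,
#' negative affect, social processes, first-person singular; baseline
#' window), the log of the baseline post count, combined affect
#' (positive + negative pooled) per window, and short-window
#' emotionality. Users without at least one tweet carrying at least
#' one token in *every* window are excluded (count kept in attribute
#' `n_excluded`).
#'
#' @param records Tweet data frame ([read_tweets()] layout).
#' @param lexicons Named list of [lexicon()]s; must include `posemo`
#'   and `negemo` (affect), plus any further categories to summarize.
#' @param windows A [study_windows()].
#' @param tz Timezone for day assignment.
#' @return Data frame, one row per retained user: `user_id`,
#'   `n_posts_*`, `n_tokens_*`, `<window>_<category>` fractions,
#'   `<window>_affect`, `log_posts`, `emotionality_short`.
#' @export
summarize_users <- function(records, lexicons, windows,
                            tz = "Europe/Paris") {
  if (nrow(records) == 0L) stop("summarize_users: empty corpus")
  stopifnot(inherits(windows, "study_windows"))
  if (!all(c("posemo", "negemo") %in% names(lexicons)))
    stop("summarize_users: lexicons must include 'posemo' and 'negemo'")

  day <- assign_day(records$timestamp, tz = tz)
  win <- window_of(day$date, windows)
  keep <- !is.na(win)
  records <- records[keep, , drop = FALSE]
  win <- win[keep]
  if (nrow(records) == 0L)
    stop("summarize_users: no records fall inside the study windows")

  users <- sort(unique(records$user_id))
  ui <- match(records$user_id, users)
  wi <- match(win, c("baseline", "short", "long"))
  rec_key <- (ui - 1L) * 3L + wi
  n_keys <- length(users) * 3L

  toks <- tokenize_all(records$text)
  n_tok <- lengths(toks)
  flat <- unlist(toks, use.names = FALSE)
  tok_key <- rep.int(rec_key, n_tok)

  posts <- tabulate(rec_key[n_tok > 0L], nbins = n_keys)
  tokens <- tabulate(tok_key, nbins = n_keys)

  cat_frac <- lapply(lexicons, function(lex) {
    hits <- match_tokens(flat, lex)
    cnt <- tabulate(tok_key[hits], nbins = n_keys)
    ifelse(tokens > 0L, cnt / tokens, NA_real_)
  })
  aff_hits <- match_tokens(flat, lexicons$posemo) |
    match_tokens(flat, lexicons$negemo)
  aff_cnt <- tabulate(tok_key[aff_hits], nbins = n_keys)
  aff_frac <- ifelse(tokens > 0L, aff_cnt / tokens, NA_real_)

  idx <- function(w) seq(w, n_keys, by = 3L)  # keys of window w per user
  out <- data.frame(user_id = users, stringsAsFactors = FALSE)
  wnames <- c("baseline", "short", "long")
  for (w in 1:3) {
    out[[paste0("n_posts_", wnames[w])]] <- posts[idx(w)]
    out[[paste0("n_tokens_", wnames[w])]] <- tokens[idx(w)]
  }
  for (cn in names(lexicons)) {
    for (w in 1:3)
      out[[paste0(wnames[w], "_", cn)]] <- cat_frac[[cn]][idx(w)]
  }
  for (w in 1:3)
    out[[paste0(wnames[w], "_affect")]] <- aff_frac[idx(w)]

  active <- out$n_posts_baseline >= 1L & out$n_posts_short >= 1L &
    out$n_posts_long >= 1L
  n_excluded <- sum(!active)
  out <- out[active, , drop = FALSE]
  rownames(out) <- NULL
  out$log_posts <- log(out$n_posts_baseline)
  out$emotionality_short <- out$short_affect
  attr(out, "n_excluded") <- n_excluded
  attr(out, "windows") <- windows
  out
}

#' Self-selection-corrected short-term emotionality
#'
#' Regresses short-window emotional expression on the baseline
#' personality-related lexical vector plus the log post count
#' (user-engagement), by ordinary least squares, and returns the
#' residuals: the component of short-term emotionality not explained
#' by who the user already was. This is the treatment variable of the
#' mediation analysis.
#'
#' @param summaries Output of [summarize_users()].
#' @param personality_cols Personality predictor columns.
#' @param engagement_col Engagement column (default `log_posts`).
#' @param emotionality_col Response column.
#' @return `summaries` with a `corrected_emotionality` column added;
#'   the fitted `lm` is kept in attribute `selection_model`.
#' @export
corrected_emotionality <- function(summaries,
                                   personality_cols = c(
                                     "baseline_posemo", "baseline_negemo",
                                     "baseline_social", "baseline_i"),
                                   engagement_col = "log_posts",
                                   emotionality_col =
                                     "emotionality_short") {
  cols <- c(personality_cols, engagement_col)
  missing_cols <- setdiff(c(cols, emotionality_col), names(summaries))
  if (length(missing_cols))
    stop("corrected_emotionality: missing columns: ",
         paste(missing_cols, collapse = ", "))
  X <- as.matrix(summaries[, cols, drop = FALSE])
  y <- summaries[[emotionality_col]]
  n <- nrow(X)
  p <- ncol(X) + 1L
  if (n < 10L * p)
    stop("corrected_emotionality: need at least ", 10L * p,
         " users for ", p, " predictors, have ", n)
  design <- cbind(`(Intercept)` = 1, X)
  qr_d <- qr(design)
  if (qr_d$rank < ncol(design)) {
    dropped <- colnames(design)[qr_d$pivot[(qr_d$rank + 1L):
                                             ncol(design)]]
    stop("corrected_emotionality: rank-deficient design; collinear ",
         "column(s): ", paste(dropped, collapse = ", "))
  }
  fit <- stats::lm.fit(design, y)
  summaries$corrected_emotionality <- unname(fit$residuals)
  attr(summaries, "selection_model") <- fit
  summaries
}

#' Emotional-synchronization groups
#'
#' Labels a user `"high"` when their combined affect frequency
#' (pooled positive + negative) in the short post-event window strictly
#' exceeds their own baseline-window frequency, `"low"` otherwise
#' (ties are `"low"`: synchronization requires using affect terms
#' *more* frequently).
#'
#' @param summaries Output of [summarize_users()].
#' @return `summaries` with a `sync_group` factor column added.
#' @export
synchronization_groups <- function(summaries) {
  stopifnot(all(c("short_affect", "baseline_affect") %in%
                  names(summaries)))
  high <- !is.na(summaries$short_affect) &
    !is.na(summaries$baseline_affect) &
    summaries$short_affect > summaries$baseline_affect
  summaries$sync_group <- factor(ifelse(high, "high", "low"),
                                 levels = c("high", "low"))
  summaries
}

#' Sliding-window group difference in a lexical indicator
#'
#' For each sliding-window endpoint, computes each user's pooled
#' category fraction over the trailing window, averages within the
#' high- and low-synchronization groups, and reports the difference
#' (high minus low) with a bootstrap confidence interval obtained by
#' resampling *users* (not tweets) with replacement within each group.
#'
#' @param records Tweet data frame.
#' @param groups Either a data frame with `user_id` and `sync_group`
#'   (e.g. from [synchronization_groups()]) or a named character
#'   vector `user_id -> "high"/"low"`.
#' @param lex A [lexicon()].
#' @param window_days Trailing window length in days (default 30, a
#'   1-month sliding window).
#' @param step_days Spacing of window endpoints (default 7).
#' @param B Bootstrap draws (default 1000).
#' @param alpha Interval tail mass.
#' @param seed Integer seed.
#' @param tz Timezone for day assignment.
#' @return Data frame: `window_end`, `diff`, `ci_low`, `ci_high`,
#'   `n_high`, `n_low` (users contributing per window).
#' @export
sliding_group_difference <- function(records, groups, lex,
                                     window_days = 30L, step_days = 7L,
                                     B = 1000L, alpha = 0.05, seed = 1L,
                                     tz = "Europe/Paris") {
  stopifnot(is_lexicon(lex))
  if (is.data.frame(groups)) {
    grp <- stats::setNames(as.character(groups$sync_group),
                           groups$user_id)
  } else grp <- groups
  users <- names(grp)[grp %in% c("high", "low")]
  grp <- grp[users]
  if (sum(grp == "high") < 2L || sum(grp == "low") < 2L)
    stop("sliding_group_difference: need at least 2 users per group")

  records <- records[records$user_id %in% users, , drop = FALSE]
  day <- assign_day(records$timestamp, tz = tz)
  all_days <- seq(min(day$date), max(day$date), by = "day")
  nd <- length(all_days)
  if (window_days > nd)
    stop("sliding_group_difference: window (", window_days,
         " days) exceeds the data span (", nd, " days)")

  toks <- tokenize_all(records$text)
  n_tok <- lengths(toks)
  flat <- unlist(toks, use.names = FALSE)
  hits <- match_tokens(flat, lex)
  ui <- match(records$user_id, users)
  di <- match(day$date, all_days)
  key <- (rep.int(ui, n_tok) - 1L) * nd + rep.int(di, n_tok)
  nu <- length(users)
  Tmat <- matrix(tabulate(key, nbins = nu * nd), nu, nd, byrow = TRUE)
  Cmat <- matrix(tabulate(key[hits], nbins = nu * nd), nu, nd,
                 byrow = TRUE)

  Tc <- cbind(0, t(apply(Tmat, 1L, cumsum)))
  Cc <- cbind(0, t(apply(Cmat, 1L, cumsum)))
  ends <- seq(window_days, nd, by = step_days)
  Wt <- Tc[, ends + 1L, drop = FALSE] -
    Tc[, ends - window_days + 1L, drop = FALSE]
  Wc <- Cc[, ends + 1L, drop = FALSE] -
    Cc[, ends - window_days + 1L, drop = FALSE]
  Fmat <- ifelse(Wt > 0L, Wc / Wt, NA_real_)  # users x positions

  hi <- which(grp == "high")
  lo <- which(grp == "low")
  diff_obs <- colMeans(Fmat[hi, , drop = FALSE], na.rm = TRUE) -
    colMeans(Fmat[lo, , drop = FALSE], na.rm = TRUE)

  boot <- with_seed(seed, {
    vapply(seq_len(B), function(i) {
      bh <- hi[sample.int(length(hi), replace = TRUE)]
      bl <- lo[sample.int(length(lo), replace = TRUE)]
      colMeans(Fmat[bh, , drop = FALSE], na.rm = TRUE) -
        colMeans(Fmat[bl, , drop = FALSE], na.rm = TRUE)
    }, numeric(length(ends)))
  })
  if (is.null(dim(boot))) boot <- matrix(boot, nrow = 1L)
  qs <- apply(boot, 1L, stats::quantile,
              probs = c(alpha / 2, 1 - alpha / 2), na.rm = TRUE)

  data.frame(window_end = all_days[ends],
             diff = diff_obs,
             ci_low = qs[1L, ], ci_high = qs[2L, ],
             n_high = colSums(!is.na(Fmat[hi, , drop = FALSE])),
             n_low = colSums(!is.na(Fmat[lo, , drop = FALSE])))
}

#' Causal mediation analysis (ADE / ACME) with bootstrap uncertainty
#'
#' Linear no-interaction mediation: fits the mediator model
#' `M = a0 + a1 T + a' X` and the outcome model
#' `Y = b0 + c T + b M + b' X` by OLS and reports the average causal
#' mediation effect `ACME = a1 b (t1 - t0)`, the average direct effect
#' `ADE = c (t1 - t0)` and the total effect for a treatment contrast
#' from `t0` (25th percentile of `T`) to `t1` (75th percentile). For
#' nested linear models the total effect equals ADE + ACME exactly.
#' Uncertainty comes from a nonparametric bootstrap over observations
#' (users); deterministic given `seed`.
#'
#' @param treatment Numeric treatment vector (typically
#'   `corrected_emotionality`).
#' @param mediator,outcome Numeric vectors (short- and long-window
#'   levels of the studied indicator).
#' @param covariates Optional numeric matrix / data frame of
#'   covariates (personality vector, activity).
#' @param B Bootstrap draws (default 10000).
#' @param seed Integer seed.
#' @param standardize Rescale all variables to unit variance before
#'   fitting (default `TRUE`, for comparable estimates across
#'   indicators)? Effects are then on the standardized scale.
#' @param conf Confidence level (default 0.95).
#' @param probs Treatment-contrast percentiles (default 25th/75th).
#' @return Object of class `mediation_fit`: `acme`, `ade`,
#'   `total_effect`, their CIs and bootstrap p-values, `t0`, `t1`,
#'   coefficient estimates `a1`, `b`, `c`.
#' @examples
#' set.seed(7)
#' t <- rnorm(200); m <- 0.5 * t + rnorm(200)
#' y <- 0.3 * t + 0.4 * m + rnorm(200)
#' mediate(t, m, y, B = 200, seed = 1)
#' @export
mediate <- function(treatment, mediator, outcome, covariates = NULL,
                    B = 10000L, seed = 1L, standardize = TRUE,
                    conf = 0.95, probs = c(0.25, 0.75)) {
  X <- if (is.null(covariates)) NULL else as.matrix(covariates)
  cc <- stats::complete.cases(treatment, mediator, outcome,
                              if (is.null(X)) rep(TRUE,
                                                  length(treatment))
                              else X)
  treatment <- treatment[cc]; mediator <- mediator[cc]
  outcome <- outcome[cc]
  if (!is.null(X)) X <- X[cc, , drop = FALSE]
  n <- length(treatment)
  if (n < 100L)
    stop("mediate: need at least 100 complete cases, have ", n)
  if (standardize) {
    std <- function(v) as.numeric(scale(v))
    treatment <- std(treatment); mediator <- std(mediator)
    outcome <- std(outcome)
    if (!is.null(X)) X <- apply(X, 2L, std)
  }
  design_m <- cbind(1, treatment, X)
  design_y <- cbind(1, treatment, mediator, X)
  if (qr(design_y)$rank < ncol(design_y))
    stop("mediate: collinear design (treatment/mediator/covariates)")
  tq <- stats::quantile(treatment, probs, names = FALSE)
  t0 <- tq[1L]; t1 <- tq[2L]

  point <- mediation_paths(design_m, design_y, mediator, outcome,
                           t1 - t0)
  draws <- with_seed(seed, {
    vapply(seq_len(B), function(i) {
      idx <- sample.int(n, n, replace = TRUE)
      mediation_paths(design_m[idx, , drop = FALSE],
                      design_y[idx, , drop = FALSE],
                      mediator[idx], outcome[idx], t1 - t0)
    }, numeric(3L))
  })
  alpha <- 1 - conf
  ci <- apply(draws, 1L, stats::quantile,
              probs = c(alpha / 2, 1 - alpha / 2))
  pval <- function(d) min(1, 2 * min((1 + sum(d <= 0)) / (1 + length(d)),
                                     (1 + sum(d >= 0)) / (1 + length(d))))
  structure(list(
    acme = unname(point[1L]), ade = unname(point[2L]),
    total_effect = unname(point[3L]),
    ci_acme = ci[, 1L], ci_ade = ci[, 2L], ci_total = ci[, 3L],
    p_acme = pval(draws[1L, ]), p_ade = pval(draws[2L, ]),
    p_total = pval(draws[3L, ]),
    t0 = t0, t1 = t1, n = n, B = B, seed = seed,
    standardized = standardize,
    paths = attr(point, "paths")),
    class = "mediation_fit")
}

# ACME / ADE / total for one (possibly resampled) dataset. The total
# comes from its own nested regression (mediator omitted); for nested
# OLS it equals ADE + ACME up to floating-point error -- an identity
# the tests assert.
mediation_paths <- function(design_m, design_y, mediator, outcome,
                            contrast) {
  a1 <- stats::lm.fit(design_m, mediator)$coefficients[2L]
  cf <- stats::lm.fit(design_y, outcome)$coefficients
  c_dir <- cf[2L]; b <- cf[3L]
  c_tot <- stats::lm.fit(design_m, outcome)$coefficients[2L]
  out <- c(acme = unname(a1 * b * contrast),
           ade = unname(c_dir * contrast),
           total = unname(c_tot * contrast))
  attr(out, "paths") <- c(a1 = unname(a1), b = unname(b),
                          c_direct = unname(c_dir))
  out
}

#' @export
print.mediation_fit <- function(x, ...) {
  cat("<mediation_fit> n =", x$n, " B =", x$B,
      if (x$standardized) "(standardized scale)" else "", "\n")
  cat(sprintf("  ACME  = %8.4f  [%.4f, %.4f]  p = %.3g\n",
              x$acme, x$ci_acme[1L], x$ci_acme[2L], x$p_acme))
  cat(sprintf("  ADE   = %8.4f  [%.4f, %.4f]  p = %.3g\n",
              x$ade, x$ci_ade[1L], x$ci_ade[2L], x$p_ade))
  cat(sprintf("  total = %8.4f  [%.4f, %.4f]  p = %.3g\n",
              x$total_effect, x$ci_total[1L], x$ci_total[2L],
              x$p_total))
  cat(sprintf("  treatment contrast: t0 = %.3f (q25), t1 = %.3f (q75)\n",
              x$t0, x$t1))
  invisible(x)
}

#' Lagged tweet-pair association between two lexical categories
#'
#' Within a time window, tests whether a user's tweet containing the
#' predictor category makes the *next* tweet by the same user more
#' likely to contain the outcome category. Fits a mixed-effects
#' logistic regression with a per-user random intercept:
#' `logit P(y_t) = b0 + beta x_{t-1} + rho y_{t-1} +
#'  gamma x_{t-1} y_{t-1} + u_i`,
#' where `y_{t-1}` corrects for autocorrelation and the interaction is
#' included as in the source design. Only consecutive tweets of the
#' same user inside the window form pairs; a user with a single tweet
#' contributes none.
#'
#' @param records Tweet data frame.
#' @param lexicon_outcome,lexicon_predictor [lexicon()]s for the
#'   outcome and predictor categories.
#' @param window Length-2 vector of dates bounding the window
#'   (default: event day 2015-11-13 plus 14 days, configurable).
#' @param min_users Minimum users with at least 2 pairs (default 30).
#' @param nAGQ Integration points for [lme4::glmer()] (0 = fastest
#'   penalized approximation, 1 = Laplace, default).
#' @param tz Timezone for windowing.
#' @return Object of class `sequential_fit`: `beta` (coefficient of
#'   the lagged predictor), `ci`, `p`, full fixed-effect table,
#'   `n_pairs`, `n_users`.
#' @export
sequential_association <- function(records, lexicon_outcome,
                                   lexicon_predictor,
                                   window = as.Date(c("2015-11-13",
                                                      "2015-11-27")),
                                   min_users = 30L, nAGQ = 1L,
                                   tz = "Europe/Paris") {
  stopifnot(is_lexicon(lexicon_outcome), is_lexicon(lexicon_predictor))
  window <- as.Date(window)
  day <- assign_day(records$timestamp, tz = tz)$date
  records <- records[day >= window[1L] & day <= window[2L], ,
                     drop = FALSE]
  if (nrow(records) < 2L)
    stop("sequential_association: no tweet pairs inside the window")
  ord <- order(records$user_id, records$timestamp)
  records <- records[ord, , drop = FALSE]

  toks <- tokenize_all(records$text)
  y_all <- vapply(toks, function(tk)
    length(tk) > 0L && any(match_tokens(tk, lexicon_outcome)),
    logical(1))
  x_all <- vapply(toks, function(tk)
    length(tk) > 0L && any(match_tokens(tk, lexicon_predictor)),
    logical(1))

  same_user <- c(FALSE,
                 records$user_id[-1L] == records$user_id[-nrow(records)])
  cur <- which(same_user)
  df <- data.frame(user = records$user_id[cur],
                   y = as.integer(y_all[cur]),
                   x_prev = as.integer(x_all[cur - 1L]),
                   y_prev = as.integer(y_all[cur - 1L]),
                   stringsAsFactors = FALSE)
  pair_counts <- table(df$user)
  n_users_ok <- sum(pair_counts >= 2L)
  if (n_users_ok < min_users)
    stop("sequential_association: only ", n_users_ok,
         " users with >= 2 tweet pairs; need ", min_users)
  if (length(unique(df$y)) < 2L)
    stop("sequential_association: outcome is constant (all ",
         df$y[1L], ")")

  fit <- lme4::glmer(y ~ x_prev + y_prev + x_prev:y_prev + (1 | user),
                     data = df, family = stats::binomial(),
                     nAGQ = nAGQ,
                     control = lme4::glmerControl(
                       calc.derivs = FALSE,
                       check.conv.singular = lme4::.makeCC(
                         action = "ignore", tol = 1e-4)))
  sm <- summary(fit)$coefficients
  est <- sm["x_prev", "Estimate"]
  se <- sm["x_prev", "Std. Error"]
  z <- stats::qnorm(0.975)
  structure(list(beta = est, se = se,
                 ci = c(est - z * se, est + z * se),
                 p = sm["x_prev", "Pr(>|z|)"],
                 coefficients = sm,
                 n_pairs = nrow(df),
                 n_users = length(unique(df$user)),
                 model = fit),
            class = "sequential_fit")
}

#' @export
print.sequential_fit <- function(x, ...) {
  cat("<sequential_fit> ", x$n_pairs, " tweet pairs from ",
      x$n_users, " users\n", sep = "")
  cat(sprintf("  lagged predictor beta = %.4f  [%.4f, %.4f]  p = %.3g\n",
              x$beta, x$ci[1L], x$ci[2L], x$p))
  invisible(x)
}

#' Zero-inflated negative-binomial model of event-reference counts
#'
#' Regresses each user's long-window count of event-reference terms on
#' their corrected short-term emotionality, with the log of long-window
#' post volume as an exposure offset and a constant zero-inflation
#' component. A negative coefficient means highly emotional users
#' referenced the event *less* in the long run.
#'
#' @param counts Nonnegative integer vector of event-term counts.
#' @param emotionality Corrected emotionality per user.
#' @param exposure Exposure offset: `log(long-window post count)`.
#' @return Object of class `attack_reference_fit`: `coef` (the
#'   emotionality coefficient), `ci`, `p`, `dispersion` (the
#'   negative-binomial size; large values approach the Poisson limit),
#'   `zero_inflation` (structural-zero probability).
#' @export
attack_reference_model <- function(counts, emotionality, exposure) {
  if (any(counts < 0) || any(counts != round(counts)))
    stop("attack_reference_model: counts must be nonnegative integers")
  if (all(counts == 0))
    stop("attack_reference_model: all counts are zero")
  df <- data.frame(counts = as.integer(counts),
                   emotionality = emotionality,
                   exposure = exposure)
  fit <- glmmTMB::glmmTMB(counts ~ emotionality + offset(exposure),
                          ziformula = ~1,
                          family = glmmTMB::nbinom2(), data = df)
  sm <- summary(fit)$coefficients$cond
  est <- sm["emotionality", "Estimate"]
  se <- sm["emotionality", "Std. Error"]
  z <- stats::qnorm(0.975)
  zi <- stats::plogis(summary(fit)$coefficients$zi[1L, "Estimate"])
  structure(list(coef = est, se = se,
                 ci = c(est - z * se, est + z * se),
                 p = sm["emotionality", "Pr(>|z|)"],
                 dispersion = glmmTMB::sigma(fit),
                 zero_inflation = zi,
                 model = fit),
            class = "attack_reference_fit")
}

#' @export
print.attack_reference_fit <- function(x, ...) {
  cat("<attack_reference_fit>\n")
  cat(sprintf("  emotionality coef = %.4f  [%.4f, %.4f]  p = %.3g\n",
              x$coef, x$ci[1L], x$ci[2L], x$p))
  cat(sprintf("  NB dispersion (size) = %.2f   zero-inflation = %.3f\n",
              x$dispersion, x$zero_inflation))
  invisible(x)
}
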