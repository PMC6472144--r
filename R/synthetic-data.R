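#' Configuration of the collective-emotion agent simulation
#'
#' Parameters of a discrete-time valence-arousal-field model of
#' collective emotions. Each agent carries a signed valence
#' `v in [-1, 1]` and an arousal `a in [0, 1]`; a global communication
#' field `h` (the decaying mean of recently expressed valence) couples
#' agents when `coupling_on = TRUE`. Per step:
#' \itemize{
#'   \item `v <- v (1 - gamma_v) + b h [coupling] + N(0, sigma_v)`
#'   \item `a <- a (1 - gamma_a) + r_i + d |h| [coupling] + N(0, sigma_a)`
#'   \item an agent posts when `a > theta`, then `a` resets to 0
#'   \item `h <- h (1 - gamma_h) + gamma_h mean(v of posting agents)`
#' }
#' `r_i` is the agent's baseline activity drive (a trait, drawn once
#' per agent), without which uncoupled agents would never post. On the
#' first step of the event day every agent receives `shock_valence`
#' (negative: the event injects negative emotion) and `shock_arousal`.
#'
#' With coupling off, individual valence relaxes within the day and
#' consecutive daily scores are unrelated; with subcritical coupling
#' the field carries deviations across days, which downstream shows up
#' as a positive memory coefficient `phi`.
#'
#' @param n_agents Number of agents.
#' @param n_days Days simulated.
#' @param event_day Day index of the shock (1-based).
#' @param coupling_on Couple agents through the field?
#' @param gamma_v,gamma_a,gamma_h Per-step decay rates in (0, 1].
#' @param b Field-to-valence gain. The default 0.25 keeps the coupled
#'   (valence, field) linearization subcritical (spectral radius about
#'   0.97 per step, i.e. roughly half of a day-scale deviation
#'   surviving to the next day) while well separated from the
#'   uncoupled arm.
#' @param d Field-to-arousal gain.
#' @param theta Posting threshold in (0, 1).
#' @param shock_arousal,shock_valence Event-day perturbations.
#' @param sigma_v,sigma_a Per-step noise standard deviations.
#' @param activity_range Range of the per-agent baseline drive `r_i`.
#' @param steps_per_day Simulation steps per day.
#' @param tokens_mean Mean extra tokens per tweet (6 + Poisson).
#' @param emo_gain Slope of affect word probability in `max(0, -v)`
#'   (negative affect) and `max(0, v)` (positive affect).
#' @param weekend_amp Weekend elevation of positive/social word rates.
#' @param start_date Calendar date of day 1.
#' @param seed Mandatory integer seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_agents = 500L, n_days = 120L, event_day = 60L,
                       coupling_on = TRUE,
                       gamma_v = 0.3, gamma_a = 0.2, gamma_h = 0.4,
                       b = 0.25, d = 0.5, theta = 0.7,
                       shock_arousal = 0.5, shock_valence = -0.6,
                       sigma_v = 0.15, sigma_a = 0.05,
                       activity_range = c(0.10, 0.18),
                       steps_per_day = 24L, tokens_mean = 6,
                       emo_gain = 0.25, weekend_amp = 0.25,
                       start_date = "2015-09-15", seed) {
  if (missing(seed)) stop("sim_config: seed is mandatory")
  cfg <- list(n_agents = as.integer(n_agents),
              n_days = as.integer(n_days),
              event_day = as.integer(event_day),
              coupling_on = isTRUE(coupling_on),
              gamma_v = gamma_v, gamma_a = gamma_a, gamma_h = gamma_h,
              b = b, d = d, theta = theta,
              shock_arousal = shock_arousal,
              shock_valence = shock_valence,
              sigma_v = sigma_v, sigma_a = sigma_a,
              activity_range = activity_range,
              steps_per_day = as.integer(steps_per_day),
              tokens_mean = tokens_mean, emo_gain = emo_gain,
              weekend_amp = weekend_amp,
              start_date = as.Date(start_date),
              seed = as.integer(seed))
  for (g in c("gamma_v", "gamma_a", "gamma_h"))
    if (cfg[[g]] <= 0 || cfg[[g]] > 1)
      stop("sim_config: ", g, " must be in (0, 1]")
  if (cfg$theta <= 0 || cfg$theta >= 1)
    stop("sim_config: theta must be in (0, 1)")
  if (cfg$n_agents < 2L || cfg$n_days < 2L ||
      cfg$event_day < 1L || cfg$event_day > cfg$n_days)
    stop("sim_config: invalid sizes")
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate a tweet stream from the collective-emotion agent model
#'
#' Runs the valence-arousal-field dynamics of [sim_config()] and emits
#' one tweet per posting event. Tweet tokens are drawn from the demo
#' lexicon pack: the probability of negative-affect words grows with
#' the poster's negative valence (`max(0, -v)`), positive-affect words
#' with positive valence, other categories (social, prosocial, shared
#' values, first-person) at fixed base rates with a weekend elevation
#' of positive/social rates; remaining tokens are neutral filler.
#' Deterministic given `cfg$seed`.
#'
#' @param cfg A [sim_config()].
#' @return List with `tweets` (tweet data frame in [read_tweets()]
#'   layout), `state` (per-step hidden state: `step`, `day`, `h`,
#'   `mean_valence`, `mean_arousal`, `n_posts`), `event_date`, `config`.
#' @examples
#' sim <- simulate_collective(sim_config(n_agents = 50, n_days = 10,
#'                                       event_day = 5, seed = 1))
#' head(sim$tweets$text)
#' @export
simulate_collective <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed, {
    nA <- cfg$n_agents
    spd <- cfg$steps_per_day
    n_steps <- cfg$n_days * spd
    r <- stats::runif(nA, cfg$activity_range[1L], cfg$activity_range[2L])
    v <- stats::rnorm(nA, 0, cfg$sigma_v)
    a <- stats::runif(nA, 0, cfg$theta)
    h <- 0
    coup <- as.numeric(cfg$coupling_on)
    shock_step <- (cfg$event_day - 1L) * spd + 1L

    post_agent <- vector("list", n_steps)
    post_val <- vector("list", n_steps)
    st_h <- st_mv <- st_ma <- numeric(n_steps)
    st_np <- integer(n_steps)

    for (s in seq_len(n_steps)) {
      v <- v * (1 - cfg$gamma_v) + coup * cfg$b * h +
        stats::rnorm(nA, 0, cfg$sigma_v)
      a <- a * (1 - cfg$gamma_a) + r + coup * cfg$d * abs(h) +
        stats::rnorm(nA, 0, cfg$sigma_a)
      if (s == shock_step) {
        a <- a + cfg$shock_arousal
        v <- v + cfg$shock_valence
      }
      v <- pmin(1, pmax(-1, v))
      a <- pmin(1, pmax(0, a))
      posting <- a > cfg$theta
      np <- sum(posting)
      h <- h * (1 - cfg$gamma_h) +
        cfg$gamma_h * (if (np > 0L) mean(v[posting]) else 0)
      if (np > 0L) {
        post_agent[[s]] <- which(posting)
        post_val[[s]] <- v[posting]
        a[posting] <- 0
      }
      st_h[s] <- h
      st_mv[s] <- mean(v)
      st_ma[s] <- mean(a)
      st_np[s] <- np
    }

    agent_id <- unlist(post_agent, use.names = FALSE)
    val <- unlist(post_val, use.names = FALSE)
    step <- rep.int(seq_len(n_steps), st_np)
    n_posts <- length(agent_id)

    day_idx <- (step - 1L) %/% spd + 1L
    dates <- cfg$start_date + (day_idx - 1L)
    hour <- ((step - 1L) %% spd) * (24 / spd)
    ts <- as.POSIXct(paste(dates, "00:00:00"), tz = "Europe/Paris") +
      round(hour * 3600) + sample.int(3599L, n_posts, replace = TRUE)

    weekend <- as.integer(format(dates, "%u")) >= 6L
    text <- emit_agent_texts(val, weekend, cfg)

    tweets <- data.frame(
      user_id = sprintf("agent%04d", agent_id),
      timestamp = ts,
      text = text,
      is_retweet = FALSE,
      stringsAsFactors = FALSE)
    tweets <- tweets[order(tweets$timestamp), , drop = FALSE]
    rownames(tweets) <- NULL

    list(tweets = tweets,
         state = data.frame(step = seq_len(n_steps), day = rep(
           seq_len(cfg$n_days), each = spd), h = st_h,
           mean_valence = st_mv, mean_arousal = st_ma, n_posts = st_np),
         event_date = cfg$start_date + (cfg$event_day - 1L),
         config = cfg)
  })
}

# token emission for the agent simulator; valence drives affect rates
emit_agent_texts <- function(val, weekend, cfg) {
  n_posts <- length(val)
  if (n_posts == 0L) return(character(0))
  n_tok <- 6L + stats::rpois(n_posts, cfg$tokens_mean)
  wk <- 1 + cfg$weekend_amp * weekend
  p_neg <- 0.02 + cfg$emo_gain * pmax(0, -val)
  p_pos <- 0.04 * wk + cfg$emo_gain * pmax(0, val)
  p_soc <- 0.05 * wk
  probs <- cbind(negemo = p_neg, posemo = p_pos, social = p_soc,
                 prosocial = 0.015, values = 0.008, i = 0.07)
  sample_category_tokens(probs, n_tok)
}

# Draw tokens for many texts at once. `probs`: one row per text,
# one column per demo category; remaining mass emits filler words.
# Returns the pasted texts.
sample_category_tokens <- function(probs, n_tok) {
  cats <- colnames(probs)
  n_text <- nrow(probs)
  total <- sum(n_tok)
  text_idx <- rep.int(seq_len(n_text), n_tok)
  cum <- t(apply(probs, 1L, cumsum))
  if (any(cum[, ncol(cum)] >= 1))
    stop("category probabilities exceed 1")
  u <- stats::runif(total)
  cat_code <- rep.int(length(cats) + 1L, total)  # default: filler
  for (k in rev(seq_along(cats)))
    cat_code[u < cum[text_idx, k]] <- k
  words <- character(total)
  for (k in seq_along(cats)) {
    sel <- cat_code == k
    if (any(sel)) {
      pool <- demo_emission_words(cats[k])
      words[sel] <- pool[sample.int(length(pool), sum(sel),
                                    replace = TRUE)]
    }
  }
  filler_sel <- cat_code == length(cats) + 1L
  if (any(filler_sel)) {
    pool <- demo_filler_words()
    words[filler_sel] <- pool[sample.int(length(pool), sum(filler_sel),
                                         replace = TRUE)]
  }
  unname(vapply(split(words, text_idx), paste, "", collapse = " "))
}

#' Configuration of the user-panel generator
#'
#' Defines a panel of users with a known individual-level causal
#' structure around the event. Per user, with `P` a latent personality
#' factor (standard normal) and `g` its loading:
#' \itemize{
#'   \item short-term emotionality `E = g P + N(0, sigma_e)`
#'   \item mediator (short-window category level)
#'     `M = a_path E + g P + N(0, sigma_m)`
#'   \item long-window outcome category level
#'     `Y = c_direct E + b_path M + g P + N(0, sigma_y)`
#' }
#' so the true mediated effect of `E` on `Y` is `a_path * b_path` per
#' unit of `E` and the direct effect is `c_direct`. Latent levels map
#' to word-emission probabilities through a logistic link bounded in
#' (0, 0.5): `p = 0.5 plogis(q + link_slope * latent)`. Tweets are
#' emitted at Poisson times with weekday rate modulation; affect words
#' in the short window follow `E`, the mediator category follows `M`
#' (short window) and `Y` (long window), and baseline rates of the four
#' personality categories (positive affect, negative affect, social,
#' first-person) follow `g P + noise`.
#'
#' @param n_users Panel size.
#' @param windows A [study_windows()].
#' @param a_path,b_path,c_direct Causal path coefficients.
#' @param g Personality loading.
#' @param sigma_e,sigma_m,sigma_y Structural noise sds.
#' @param link_slope Latent-to-logit slope of the emission link.
#' @param tweets_per_day Mean tweets per user-day (modulated by a
#'   lognormal per-user activity factor).
#' @param tokens_mean Mean extra tokens per tweet (4 + Poisson).
#' @param weekend_amp Weekend elevation of tweet volume.
#' @param mediator_category Demo category carrying mediator/outcome
#'   (default `"social"`).
#' @param emit_text Generate tweet text (set `FALSE` for ground-truth
#'   -only studies at large `n_users`).
#' @param seed Mandatory integer seed.
#' @return A `panel_config` list.
#' @export
panel_config <- function(n_users = 500L,
                         windows = study_windows("2015-11-13"),
                         a_path = 0.5, b_path = 0.4, c_direct = 0.3,
                         g = 0.5, sigma_e = 1, sigma_m = 1, sigma_y = 1,
                         link_slope = 0.5, tweets_per_day = 2,
                         tokens_mean = 8, weekend_amp = 0.2,
                         mediator_category = "social",
                         emit_text = TRUE, seed) {
  if (missing(seed)) stop("panel_config: seed is mandatory")
  stopifnot(inherits(windows, "study_windows"))
  cfg <- list(n_users = as.integer(n_users), windows = windows,
              a_path = a_path, b_path = b_path, c_direct = c_direct,
              g = g, sigma_e = sigma_e, sigma_m = sigma_m,
              sigma_y = sigma_y, link_slope = link_slope,
              tweets_per_day = tweets_per_day,
              tokens_mean = tokens_mean, weekend_amp = weekend_amp,
              mediator_category = mediator_category,
              emit_text = isTRUE(emit_text), seed = as.integer(seed))
  if (!all(is.finite(unlist(cfg[c("a_path", "b_path", "c_direct", "g",
                                  "sigma_e", "sigma_m", "sigma_y")]))))
    stop("panel_config: path coefficients and noise sds must be finite")
  if (cfg$n_users < 2L) stop("panel_config: need at least 2 users")
  class(cfg) <- "panel_config"
  cfg
}

# emission link: latent level -> word probability in (0, 0.5)
panel_link <- function(q, latent, slope) {
  p <- 0.5 * stats::plogis(q + slope * latent)
  if (any(p <= 0 | p >= 0.5))
    stop("panel_config: emission probability outside (0, 0.5)")
  p
}

#' Simulate a user panel with known mediation ground truth
#'
#' Draws the causal latents of [panel_config()] for every user,
#' optionally emits the corresponding tweet stream, and returns the
#' ground-truth table. Deterministic given `cfg$seed`.
#'
#' @param cfg A [panel_config()].
#' @return List with `truth` (data frame: `user_id`, `personality`,
#'   `activity`, `log_posts_baseline`, `emotionality`, `mediator`,
#'   `outcome`, realized per-window post counts) and `tweets` (tweet
#'   data frame, `NULL` when `emit_text = FALSE`), plus `config`.
#' @export
simulate_user_panel <- function(cfg) {
  stopifnot(inherits(cfg, "panel_config"))
  with_seed(cfg$seed, {
    n <- cfg$n_users
    P <- stats::rnorm(n)
    E <- cfg$g * P + stats::rnorm(n, 0, cfg$sigma_e)
    M <- cfg$a_path * E + cfg$g * P + stats::rnorm(n, 0, cfg$sigma_m)
    Y <- cfg$c_direct * E + cfg$b_path * M + cfg$g * P +
      stats::rnorm(n, 0, cfg$sigma_y)
    L_pos <- cfg$g * P + stats::rnorm(n, 0, 0.5)
    L_neg <- cfg$g * P + stats::rnorm(n, 0, 0.5)
    L_soc <- cfg$g * P + stats::rnorm(n, 0, 0.5)
    L_i <- cfg$g * P + stats::rnorm(n, 0, 0.5)
    activity <- stats::rlnorm(n, 0, 0.4)

    truth <- data.frame(
      user_id = sprintf("user%05d", seq_len(n)),
      personality = P, activity = activity,
      emotionality = E, mediator = M, outcome = Y,
      stringsAsFactors = FALSE)

    w <- cfg$windows
    days <- list(
      baseline = seq(w$baseline_start, w$baseline_end, by = "day"),
      short = seq(w$short_start, w$short_end, by = "day"),
      long = seq(w$long_start, w$long_end, by = "day"))

    counts <- sapply(days, function(dd)
      stats::rpois(n, cfg$tweets_per_day * length(dd) * activity))
    truth$n_posts_baseline <- counts[, "baseline"]
    truth$n_posts_short <- counts[, "short"]
    truth$n_posts_long <- counts[, "long"]
    truth$log_posts_baseline <- log(pmax(1L, counts[, "baseline"]))

    tweets <- NULL
    if (cfg$emit_text) {
      k <- cfg$link_slope
      med <- cfg$mediator_category
      # per-user per-window category probabilities
      rates <- list(
        baseline = cbind(posemo = panel_link(-2.2, L_pos, k),
                         negemo = panel_link(-2.4, L_neg, k),
                         social = panel_link(-2.0, L_soc, k),
                         i = panel_link(-1.8, L_i, k)),
        short = cbind(posemo = panel_link(-2.6, E, k),
                      negemo = panel_link(-2.6, E, k),
                      social = panel_link(-2.0, L_soc, k),
                      i = panel_link(-1.8, L_i, k)),
        long = cbind(posemo = panel_link(-2.2, L_pos, k),
                     negemo = panel_link(-2.4, L_neg, k),
                     social = panel_link(-2.0, L_soc, k),
                     i = panel_link(-1.8, L_i, k)))
      rates$short[, med] <- panel_link(-2.0, M, k)
      rates$long[, med] <- panel_link(-2.0, Y, k)

      parts <- lapply(names(days), function(win) {
        n_tw <- counts[, win]
        if (sum(n_tw) == 0L) return(NULL)
        user_idx <- rep.int(seq_len(n), n_tw)
        dd <- days[[win]]
        wt <- 1 + cfg$weekend_amp *
          (as.integer(format(dd, "%u")) >= 6L)
        day_pick <- dd[sample.int(length(dd), length(user_idx),
                                  replace = TRUE, prob = wt)]
        ts <- as.POSIXct(paste(day_pick, "00:00:00"),
                         tz = "Europe/Paris") +
          sample.int(86399L, length(user_idx), replace = TRUE)
        n_tok <- 4L + stats::rpois(length(user_idx), cfg$tokens_mean)
        text <- sample_category_tokens(rates[[win]][user_idx, ,
                                                    drop = FALSE], n_tok)
        data.frame(user_id = truth$user_id[user_idx], timestamp = ts,
                   text = text, is_retweet = FALSE,
                   stringsAsFactors = FALSE)
      })
      tweets <- do.call(rbind, parts)
      tweets <- tweets[order(tweets$user_id, tweets$timestamp), ,
                       drop = FALSE]
      rownames(tweets) <- NULL
    }
    list(truth = truth, tweets = tweets, config = cfg)
  })
}

#' Simulate lagged tweet pairs with a known sequential dependence
#'
#' Generates per-user time-ordered tweets in a window where the
#' presence of the outcome category in tweet `t` depends on the
#' predictor category in tweet `t - 1` through a logistic model with a
#' per-user random intercept:
#' `logit P(y_t = 1) = alpha + beta x_{t-1} + rho y_{t-1} + u_i`.
#' Ground truth for validating [sequential_association()].
#'
#' @param n_users Users.
#' @param n_tweets Tweets per user.
#' @param beta True lagged cross-category coefficient.
#' @param rho True autocorrelation coefficient.
#' @param alpha Baseline logit.
#' @param sd_u Sd of the per-user random intercept.
#' @param p_x Marginal probability of the predictor category.
#' @param predictor_category,outcome_category Demo categories.
#' @param start Start time of the window.
#' @param seed Mandatory integer seed.
#' @return List `records` (tweet data frame) and `params`.
#' @export
simulate_tweet_pairs <- function(n_users = 500L, n_tweets = 30L,
                                 beta = 0.08, rho = 0.3, alpha = -1,
                                 sd_u = 0.3, p_x = 0.3,
                                 predictor_category = "posemo",
                                 outcome_category = "social",
                                 start = "2015-11-13", seed) {
  if (missing(seed)) stop("simulate_tweet_pairs: seed is mandatory")
  with_seed(seed, {
    u <- stats::rnorm(n_users, 0, sd_u)
    x <- matrix(stats::rbinom(n_users * n_tweets, 1L, p_x),
                n_users, n_tweets)
    y <- matrix(0L, n_users, n_tweets)
    y[, 1L] <- stats::rbinom(n_users, 1L, stats::plogis(alpha + u))
    for (t in 2:n_tweets) {
      eta <- alpha + beta * x[, t - 1L] + rho * y[, t - 1L] + u
      y[, t] <- stats::rbinom(n_users, 1L, stats::plogis(eta))
    }
    pred_pool <- demo_emission_words(predictor_category)
    out_pool <- demo_emission_words(outcome_category)
    filler <- demo_filler_words()
    n_total <- n_users * n_tweets
    xv <- as.vector(t(x)); yv <- as.vector(t(y))
    base <- matrix(filler[sample.int(length(filler), 3L * n_total,
                                     replace = TRUE)], n_total, 3L)
    text <- paste(base[, 1L], base[, 2L], base[, 3L])
    text <- ifelse(xv == 1L,
                   paste(text, pred_pool[sample.int(length(pred_pool),
                                                    n_total,
                                                    replace = TRUE)]),
                   text)
    text <- ifelse(yv == 1L,
                   paste(text, out_pool[sample.int(length(out_pool),
                                                   n_total,
                                                   replace = TRUE)]),
                   text)
    t0 <- as.POSIXct(paste(start, "08:00:00"), tz = "Europe/Paris")
    records <- data.frame(
      user_id = rep(sprintf("user%05d", seq_len(n_users)),
                    each = n_tweets),
      timestamp = t0 + rep(seq_len(n_tweets) * 3600, n_users),
      text = text, is_retweet = FALSE, stringsAsFactors = FALSE)
    list(records = records,
         params = list(beta = beta, rho = rho, alpha = alpha,
                       sd_u = sd_u, p_x = p_x,
                       predictor_category = predictor_category,
                       outcome_category = outcome_category))
  })
}
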