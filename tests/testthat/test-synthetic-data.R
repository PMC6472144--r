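small_cfg <- function(seed = 101L, ...) {
  sim_config(n_agents = 60L, n_days = 14L, event_day = 7L,
             steps_per_day = 12L, seed = seed, ...)
}

test_that("agent simulation is deterministic given the seed", {
  s1 <- simulate_collective(small_cfg())
  s2 <- simulate_collective(small_cfg())
  expect_identical(s1$tweets, s2$tweets)
  expect_identical(s1$state, s2$state)
  s3 <- simulate_collective(small_cfg(seed = 102L))
  expect_false(identical(s1$tweets$text, s3$tweets$text))
})

test_that("agent state respects its bounds and logs every step", {
  sim <- simulate_collective(small_cfg())
  expect_equal(nrow(sim$state), 14L * 12L)
  expect_true(all(abs(sim$state$mean_valence) <= 1))
  expect_true(all(sim$state$mean_arousal >= 0 &
                    sim$state$mean_arousal <= 1))
  expect_true(all(abs(sim$state$h) <= 1))
  expect_gt(nrow(sim$tweets), 0L)
})

test_that("the event day shows up as a negative valence shock", {
  sim <- simulate_collective(small_cfg(coupling_on = FALSE))
  v_day <- tapply(sim$state$mean_valence, sim$state$day, mean)
  expect_lt(v_day[["7"]], min(v_day[as.character(1:6)]))
})

test_that("uncoupled valence decays like AR(1) with rate 1 - gamma_v", {
  cfg <- sim_config(n_agents = 300L, n_days = 30L, event_day = 15L,
                    coupling_on = FALSE, shock_valence = 0,
                    shock_arousal = 0, steps_per_day = 24L,
                    gamma_v = 0.3, seed = 55L)
  sim <- simulate_collective(cfg)
  v <- sim$state$mean_valence
  # mean valence of independent AR(1) agents is AR(1) with the same rate
  ac <- stats::cor(v[-1], v[-length(v)])
  expect_equal(ac, 1 - cfg$gamma_v, tolerance = 0.06)
})

test_that("generated text carries the demo-category signal", {
  sim <- simulate_collective(small_cfg())
  lex <- demo_lexicons("negemo")[[1]]
  fr <- indicator_fractions(sim$tweets$text, lex)
  expect_true(mean(fr, na.rm = TRUE) > 0.01)
})

test_that("weekend word rates are elevated by the stated amplitude", {
  cfg <- sim_config(n_agents = 200L, n_days = 28L, event_day = 14L,
                    shock_valence = 0, shock_arousal = 0,
                    coupling_on = FALSE, steps_per_day = 12L,
                    weekend_amp = 0.25, seed = 67L)
  sim <- simulate_collective(cfg)
  frp <- indicator_fractions(sim$tweets$text,
                             demo_lexicons("posemo")[[1]])
  wd <- assign_day(sim$tweets$timestamp)$weekday
  diff <- mean(frp[wd >= 5], na.rm = TRUE) -
    mean(frp[wd < 5], na.rm = TRUE)
  # base positive rate 0.04 is scaled by 1.25 on weekends
  expect_equal(diff, 0.25 * 0.04, tolerance = 0.5)
  expect_gt(diff, 0)
})

test_that("invalid simulator configurations are rejected", {
  expect_error(sim_config(seed = 1, gamma_v = 0), "gamma_v")
  expect_error(sim_config(seed = 1, theta = 1.2), "theta")
  expect_error(sim_config(n_agents = 1, seed = 1), "invalid sizes")
  expect_error(sim_config(), "seed is mandatory")
})

test_that("panel generation is deterministic and well-formed", {
  cfg <- panel_config(n_users = 40L, tweets_per_day = 1, seed = 77L)
  p1 <- simulate_user_panel(cfg)
  p2 <- simulate_user_panel(cfg)
  expect_identical(p1$truth, p2$truth)
  expect_identical(p1$tweets, p2$tweets)
  expect_equal(nrow(p1$truth), 40L)
  expect_true(all(c("personality", "emotionality", "mediator",
                    "outcome") %in% names(p1$truth)))
  # tweets live inside the study windows
  d <- assign_day(p1$tweets$timestamp)$date
  w <- cfg$windows
  expect_true(all(d >= w$baseline_start & d <= w$long_end))
})

test_that("panel latent correlations match the generative algebra", {
  cfg <- panel_config(n_users = 20000L, emit_text = FALSE, seed = 31L)
  tr <- simulate_user_panel(cfg)$truth
  g <- cfg$g; a <- cfg$a_path
  var_e <- g^2 + cfg$sigma_e^2
  cov_em <- a * var_e + g^2          # cov(E, aE + gP + noise)
  var_m <- a^2 * var_e + g^2 + cfg$sigma_m^2 + 2 * a * g^2
  r_expected <- cov_em / sqrt(var_e * var_m)
  expect_equal(cor(tr$emotionality, tr$mediator), r_expected,
               tolerance = 0.02)
})

test_that("panel word rates respond to the causal latents", {
  pan <- simulate_user_panel(panel_config(n_users = 250L, seed = 13L))
  su <- summarize_users(pan$tweets,
                        demo_lexicons(c("posemo", "negemo", "social",
                                        "i")),
                        pan$config$windows)
  tr <- pan$truth[match(su$user_id, pan$truth$user_id), ]
  expect_gt(cor(su$short_affect, tr$emotionality), 0.5)
  expect_gt(cor(su$short_social, tr$mediator), 0.5)
  expect_gt(cor(su$long_social, tr$outcome), 0.5)
})

test_that("tweet-pair generator reproduces its logistic dependence", {
  sp <- simulate_tweet_pairs(n_users = 400L, n_tweets = 25L,
                             beta = 1.5, seed = 19L)
  rec <- sp$records
  toks <- tokenize_all(rec$text)
  x <- vapply(toks, function(tk)
    any(match_tokens(tk, demo_lexicons("posemo")[[1]])), logical(1))
  y <- vapply(toks, function(tk)
    any(match_tokens(tk, demo_lexicons("social")[[1]])), logical(1))
  same <- c(FALSE, rec$user_id[-1] == rec$user_id[-nrow(rec)])
  cur <- which(same)
  # strong true effect leaves a visible marginal association
  tab <- table(x[cur - 1], y[cur])
  or <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  expect_gt(or, 1.5)
  expect_identical(
    simulate_tweet_pairs(n_users = 20, n_tweets = 5, seed = 3)$records,
    simulate_tweet_pairs(n_users = 20, n_tweets = 5, seed = 3)$records)
})
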