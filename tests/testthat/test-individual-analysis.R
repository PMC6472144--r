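# shared small text panel for the user-level pipeline tests
panel_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      pan <- simulate_user_panel(panel_config(n_users = 250L,
                                              seed = 501L))
      su <- summarize_users(pan$tweets,
                            demo_lexicons(c("posemo", "negemo",
                                            "social", "i")),
                            pan$config$windows)
      cache <<- list(pan = pan, su = su)
    }
    cache
  }
})

test_that("user summaries pool word counts per window and category", {
  w <- study_windows("2015-11-13")
  tw <- rbind(
    tweet_table(c("mes amis sont là", "rien de rien",
                  "la famille aussi ce soir"),
                c("2015-09-01", "2015-10-01", "2015-10-02"), "u1"),
    tweet_table("peur et colère ce soir", "2015-11-20", "u1"),
    tweet_table("le calme est revenu chez nous", "2015-12-15", "u1"),
    tweet_table("un tweet seulement", "2015-09-05", "u2"))
  su <- summarize_users(tw, demo_lexicons(c("posemo", "negemo",
                                            "social", "i")), w)
  expect_equal(nrow(su), 1L)              # u2 fails the 3-window filter
  expect_equal(attr(su, "n_excluded"), 1L)
  # baseline: 12 tokens, "amis" + "famille" social, "mes" first-person
  expect_equal(su$n_tokens_baseline, 12L)
  expect_equal(su$baseline_social, 2 / 12)
  expect_equal(su$baseline_i, 1 / 12)
  # short window: 5 tokens, "peur" + "colère" negative
  expect_equal(su$short_negemo, 2 / 5)
  expect_equal(su$short_affect, 2 / 5)
  expect_equal(su$log_posts, log(3))
})

test_that("summaries exclude exactly the users inactive in a window", {
  pan <- simulate_user_panel(panel_config(n_users = 120L,
                                          tweets_per_day = 0.05,
                                          seed = 11L))
  su <- summarize_users(pan$tweets,
                        demo_lexicons(c("posemo", "negemo")),
                        pan$config$windows)
  active <- with(pan$truth, n_posts_baseline >= 1 & n_posts_short >= 1 &
                   n_posts_long >= 1)
  expect_equal(nrow(su), sum(active))
  expect_equal(attr(su, "n_excluded"),
               length(unique(pan$tweets$user_id)) - sum(active))
})

test_that("corrected emotionality is the OLS residual", {
  fx <- panel_fixture()
  su <- corrected_emotionality(fx$su)
  # residuals orthogonal to every design column
  n <- nrow(su)
  for (cl in c("baseline_posemo", "baseline_negemo", "baseline_social",
               "baseline_i", "log_posts"))
    expect_lt(abs(sum(su$corrected_emotionality * su[[cl]])), 1e-8 * n)
  expect_lt(abs(sum(su$corrected_emotionality)), 1e-8 * n)

  # exact linear response leaves zero residuals
  su2 <- fx$su
  su2$emotionality_short <- 0.2 + 0.3 * su2$baseline_posemo -
    0.1 * su2$log_posts
  su2 <- corrected_emotionality(su2)
  expect_lt(max(abs(su2$corrected_emotionality)), 1e-10)

  # emotionality independent of personality: residual ~ centered value
  set.seed(91)
  su3 <- fx$su
  su3$emotionality_short <- rnorm(nrow(su3))
  su3 <- corrected_emotionality(su3)
  expect_gt(cor(su3$corrected_emotionality,
                su3$emotionality_short -
                  mean(su3$emotionality_short)), 0.98)
})

test_that("rank deficiency and tiny samples are rejected with names", {
  fx <- panel_fixture()
  su <- fx$su
  su$baseline_i <- su$baseline_posemo * 2
  expect_error(corrected_emotionality(su), "baseline_i")
  expect_error(corrected_emotionality(fx$su[1:20, ]), "at least")
})

test_that("synchronization split is strict on ties", {
  su <- data.frame(user_id = c("a", "b", "c"),
                   baseline_affect = c(0.04, 0.06, 0.05),
                   short_affect = c(0.06, 0.06, 0.03))
  out <- synchronization_groups(su)
  expect_identical(as.character(out$sync_group), c("high", "low", "low"))
})

test_that("sliding group difference recovers an injected long-term gap", {
  # two groups whose social rate diverges by a known step after the
  # event; g = 0 so groups are unconfounded at baseline
  set.seed(303)
  pan <- simulate_user_panel(panel_config(
    n_users = 160L, g = 0, a_path = 0, b_path = 0, c_direct = 0,
    tweets_per_day = 3, seed = 404L))
  tr <- pan$truth
  grp <- stats::setNames(
    ifelse(seq_len(nrow(tr)) <= 80L, "high", "low"), tr$user_id)
  tw <- pan$tweets
  # inject: high-group users use extra social words after the event
  d <- assign_day(tw$timestamp)$date
  sel <- grp[tw$user_id] == "high" & d >= as.Date("2015-11-13")
  tw$text[sel] <- paste(tw$text[sel], "ensemble")
  sd <- sliding_group_difference(tw, grp,
                                 demo_lexicons("social")[[1]],
                                 window_days = 30L, step_days = 14L,
                                 B = 300L, seed = 5L)
  pre <- sd$window_end < as.Date("2015-11-13")
  post <- sd$window_end >= as.Date("2015-12-13")
  expect_lt(max(abs(sd$diff[pre])), 0.02)     # placebo: no gap before
  expect_true(all(sd$diff[post] > 0.02))       # clear gap after
  expect_true(all(sd$ci_low[post] > 0))
  # placebo windows: CI covers zero
  expect_true(all(sd$ci_low[pre] <= 0 & sd$ci_high[pre] >= 0))
})

test_that("sliding difference validates its inputs", {
  fx <- panel_fixture()
  su <- synchronization_groups(fx$su)
  expect_error(
    sliding_group_difference(fx$pan$tweets,
                             stats::setNames(rep("high", 10),
                                             su$user_id[1:10]),
                             demo_lexicons("social")[[1]]),
    "2 users per group")
  expect_error(
    sliding_group_difference(fx$pan$tweets, su,
                             demo_lexicons("social")[[1]],
                             window_days = 10000L),
    "exceeds the data span")
})

test_that("mediation effects add up exactly and are reproducible", {
  set.seed(17)
  n <- 300
  t <- rnorm(n); m <- 0.5 * t + rnorm(n)
  y <- 0.3 * t + 0.4 * m + rnorm(n)
  x <- cbind(z = rnorm(n))
  f1 <- mediate(t, m, y, covariates = x, B = 300, seed = 9)
  expect_equal(f1$ade + f1$acme, f1$total_effect, tolerance = 1e-10)
  f2 <- mediate(t, m, y, covariates = x, B = 300, seed = 9)
  expect_identical(unclass(f1), unclass(f2))
  f3 <- mediate(t, m, y, covariates = x, B = 300, seed = 10)
  expect_false(identical(f1$ci_acme, f3$ci_acme))
})

test_that("a null mediator path yields an ACME interval around zero", {
  set.seed(18)
  n <- 400
  t <- rnorm(n); m <- 0.5 * t + rnorm(n)
  y <- 0.3 * t + 0 * m + rnorm(n)
  f <- mediate(t, m, y, B = 500, seed = 2)
  expect_true(f$ci_acme[1] <= 0 && 0 <= f$ci_acme[2])
  expect_gt(f$p_acme, 0.05)
})

test_that("mediate rejects insufficient or collinear input", {
  set.seed(19)
  t <- rnorm(50)
  expect_error(mediate(t, t + rnorm(50), rnorm(50)), "at least 100")
  t <- rnorm(200)
  expect_error(mediate(t, m = t, outcome = rnorm(200), B = 10),
               "collinear")
})

test_that("sequential association recovers a strong planted effect", {
  sp <- simulate_tweet_pairs(n_users = 400L, n_tweets = 25L,
                             beta = 1, seed = 23L)
  fit <- sequential_association(sp$records,
                                demo_lexicons("social")[[1]],
                                demo_lexicons("posemo")[[1]],
                                nAGQ = 0L)
  expect_gt(fit$beta, 0)
  expect_lt(fit$p, 0.01)
  expect_true(fit$ci[1] <= 1 && 1 <= fit$ci[2] + 0.25)
  expect_equal(fit$n_pairs, 400L * 24L)
})

test_that("single-tweet users contribute no pairs", {
  sp <- simulate_tweet_pairs(n_users = 60L, n_tweets = 10L,
                             beta = 0.5, seed = 29L)
  lone <- tweet_table("un seul message ici", "2015-11-14", "lonely")
  fit1 <- sequential_association(sp$records,
                                 demo_lexicons("social")[[1]],
                                 demo_lexicons("posemo")[[1]],
                                 nAGQ = 0L)
  fit2 <- sequential_association(rbind(sp$records, lone),
                                 demo_lexicons("social")[[1]],
                                 demo_lexicons("posemo")[[1]],
                                 nAGQ = 0L)
  expect_equal(fit1$n_pairs, fit2$n_pairs)
  expect_equal(fit1$beta, fit2$beta, tolerance = 1e-6)
})

test_that("sequential association guards its preconditions", {
  sp <- simulate_tweet_pairs(n_users = 10L, n_tweets = 10L,
                             beta = 0, seed = 31L)
  expect_error(sequential_association(sp$records,
                                      demo_lexicons("social")[[1]],
                                      demo_lexicons("posemo")[[1]],
                                      min_users = 30L),
               "need 30")
  tw <- tweet_table(rep("rien du tout", 60),
                    rep(c("2015-11-14", "2015-11-15", "2015-11-16"),
                        20),
                    user_id = rep(sprintf("u%02d", 1:20), each = 3))
  expect_error(sequential_association(tw, demo_lexicons("social")[[1]],
                                      demo_lexicons("posemo")[[1]],
                                      min_users = 10L),
               "constant")
})

test_that("the ZINB event-reference model recovers a negative effect", {
  set.seed(37)
  n <- 5000
  emo <- rnorm(n)
  expo <- log(rpois(n, 40) + 1)
  mu <- exp(0.5 - 0.3 * emo + expo - mean(expo))
  counts <- ifelse(runif(n) < 0.25, 0L,
                   rnbinom(n, size = 2, mu = mu))
  fit <- attack_reference_model(counts, emo, expo - mean(expo))
  expect_lt(fit$coef, 0)
  expect_lt(fit$ci[2], 0)
  expect_equal(fit$coef, -0.3, tolerance = 0.05)
  expect_equal(fit$zero_inflation, 0.25, tolerance = 0.05)
})

test_that("near-Poisson counts drive the dispersion to its limit", {
  set.seed(38)
  n <- 3000
  emo <- rnorm(n)
  counts <- rpois(n, exp(1 + 0.2 * emo))
  fit <- attack_reference_model(counts, emo, rep(0, n))
  # nbinom2 size -> large means Poisson; accept anything > 20
  expect_gt(fit$dispersion, 20)
})

test_that("the ZINB model validates its counts", {
  expect_error(attack_reference_model(c(-1, 2), rnorm(2), c(0, 0)),
               "nonnegative")
  expect_error(attack_reference_model(c(0.5, 2), rnorm(2), c(0, 0)),
               "integers")
  expect_error(attack_reference_model(rep(0L, 10), rnorm(10),
                                      rep(0, 10)), "all counts")
})
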