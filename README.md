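# effervescence

Collective emotion dynamics and solidarity indicators in tweet streams.

After a collective trauma — a terrorist attack, a disaster — affected
communities talk intensely about the event. Durkheim's theory of
*collective effervescence* predicts that this synchronized emotional
exchange strengthens solidarity. `effervescence` is an R package for
testing that prediction in social-media text, for computational social
scientists and psycholinguists working with tweet tables and
LIWC-style dictionaries.

## What it computes

**Lexical indicators.** For a word category $C$ (a lexicon of literal
words and `stem*` patterns), the indicator of a text is the fraction
of its tokens matching $C$. Parsers are included for the LIWC `.dic`
dialect and a plain JSON format; a small synthetic demo dictionary
ships with the package (the licensed French LIWC dictionary does not).

**Daily scores.** Per-day means $m_t$ of tweet-level fractions are
normalized against per-weekday pre-event baselines $b_w$:

$$s_t = \log\frac{m_t + \varepsilon}{b_{w(t)} + \varepsilon},$$

with bootstrap CIs per day, correcting for the weekly oscillation of
word frequencies.

**Collective dynamics.** Daily scores are fitted with an
exogenous-shock memory model

$$s_t = c + \phi\, s_{t-1} + \beta X_t + \epsilon_t,$$

($X_t$: event-day impulse, or step) by penalized ML with weakly
informative Gaussian priors. The memory coefficient $\phi$ is the
headline statistic: individual emotional reactions relax within a
day, so $\phi \approx 0$ under independent behavior, while emotional
feedback across users sustains deviations day-to-day and yields
$\phi > 0$. Residual diagnostics (Shapiro–Wilk, Ljung–Box, ADF,
Breusch–Pagan) come with the fit.

**Individual-level analysis.** Per-user window summaries
(3-month baseline / 2-week short / 3-month long), self-selection
correction of short-term emotionality by residualizing on a
personality-related lexical vector, high/low emotional-synchronization
groups, sliding-window group contrasts with user-level bootstrap,
causal mediation (ADE/ACME, product of coefficients, bootstrap CIs),
lagged tweet-pair mixed-effects logistic association, and a
zero-inflated negative-binomial model of event-reference counts.

**Synthetic generators with ground truth.** An agent-based
valence–arousal–field simulator of collective emotions (coupling
switchable on/off) and a user-panel generator with known mediation
paths, used to validate every stage of the pipeline.

## Worked example

Simulate a coupled tweet stream (500 agents, 120 days, event shock on
day 60), score negative affect, and fit the shock model:

```r
library(effervescence)

lex <- demo_lexicons()
sim <- simulate_collective(sim_config(coupling_on = TRUE, seed = 2024))
fit <- fit_collective_pipeline(sim$tweets, lex$negemo, sim$event_date)
fit
#> <shock_fit> impulse shock at 2015-11-13, n = 57 days
#>   memory  phi  =  0.431  [0.296, 0.566]  p = 3.98e-10
#>   shock   beta =  1.050  [0.865, 1.235]  p = 7.75e-29
#>   intercept c  = -0.014   sigma = 0.093
diagnose(fit)
#> <shock_diagnostics> n = 57
#>   Shapiro-Wilk normality    p = 0.873
#>   Ljung-Box serial corr.    p = 0.680
#>   ADF stationarity          p = 0.022 (small = stationary)
#>   Breusch-Pagan heterosc.   p = 0.605
```

The memory coefficient $\phi = 0.43$ with a CI far from zero is the
signature of collective dynamics: the event-day spike ($\beta = 1.05$
on the log-ratio scale, i.e. nearly triple the weekday baseline)
relaxes over several days instead of vanishing overnight. Rerunning
with `coupling_on = FALSE` gives a $\phi$ indistinguishable from zero.

Scoring a single text against the bundled demo dictionary:

```r
dic <- read_liwc_dic(system.file("extdata", "demo_french.dic",
                                 package = "effervescence"))
indicator_fraction(
  tokenize("Quelle tristesse et quelle peur ce soir à #Paris"),
  dic$negemo)
#> [1] 0.2222222   # 2 of 9 tokens (tristesse, peur)
```

Individual-level pipeline on a synthetic user panel with known causal
paths, mediation of emotionality effects on long-term social-process
terms through their short-term level:

```r
pan <- simulate_user_panel(panel_config(n_users = 300, seed = 99))
su <- summarize_users(pan$tweets,
                      demo_lexicons(c("posemo", "negemo", "social", "i")),
                      pan$config$windows)
su <- corrected_emotionality(su)
su <- synchronization_groups(su)
table(su$sync_group)
#> high  low
#>   75  225

med <- mediate(su$corrected_emotionality, su$short_social, su$long_social,
               covariates = su[, c("baseline_posemo", "baseline_negemo",
                                   "baseline_social", "baseline_i",
                                   "log_posts")],
               B = 1000, seed = 1)
med
#> <mediation_fit> n = 300  B = 1000 (standardized scale)
#>   ACME  =   0.1077  [0.0583, 0.1692]  p = 0.002
#>   ADE   =   0.2651  [0.1336, 0.4301]  p = 0.002
#>   total =   0.3727  [0.2410, 0.5395]  p = 0.002
#>   treatment contrast: t0 = -0.670 (q25), t1 = 0.446 (q75)
```

Both the direct effect of corrected emotionality on long-term
social-term use (ADE) and the component mediated through short-term
use (ACME) are positive, as built into the generator; the total effect
equals their sum exactly.

Real data enter through `read_tweets()` (JSONL or CSV, with column
mapping), `filter_original()` (drops retweets) and user-supplied
lexicons; see the methods vignette
(`vignettes/effervescence-methods.Rmd`) for the full model
descriptions, parameter defaults and validation design.

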