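---
title: "Measuring collective emotions and solidarity in tweet streams"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring collective emotions and solidarity in tweet streams}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(effervescence)
```

## The scientific problem

After a collective trauma — a terrorist attack, a disaster — members of
the affected community talk profusely about the event and their
feelings. Durkheim's notion of *collective effervescence* predicts that
this synchronized emotional exchange is not mere venting: it should
strengthen solidarity in the community. `effervescence` implements a
complete observational pipeline for testing this idea in tweet streams:

1. **Lexical scoring** — dictionary-based (LIWC-style) indicators: the
   fraction of a tweet's tokens that belong to a word category
   (positive/negative affect, sadness, anxiety, anger, social
   processes, prosocial behavior, shared values, first-person
   singular, event-reference terms).
2. **Daily scores** — per-day means of the tweet-level fractions,
   normalized against per-weekday baselines by a log ratio, with
   per-day bootstrap uncertainty.
3. **Collective dynamics** — an exogenous-shock AR(1) model whose
   memory coefficient $\phi$ separates collective behavior from
   individual relaxation.
4. **Individual-level analysis** — self-selection-corrected short-term
   emotionality, emotional-synchronization groups, sliding-window
   group contrasts, causal mediation (ADE/ACME), lagged tweet-pair
   association, and a zero-inflated negative-binomial model of
   event-reference counts.
5. **Synthetic generators** — an agent-based collective-emotion
   simulator and a user panel with known causal ground truth, so every
   stage can be validated against effects that are known by
   construction.

The package ships only a small synthetic demo dictionary; real studies
supply their own lexicons (e.g. a licensed LIWC dictionary) through
`read_liwc_dic()` or `read_lexicon_json()`.

## Lexical indicators

A `lexicon` is a set of literal tokens and stem patterns (`solidar*`
matches every token starting with `solidar`). The indicator of a text
is the fraction of its tokens matching any entry; a token matching
several entries of one category counts once, and categories are scored
independently (the LIWC convention).

The tokenizer is deliberately simple and fully deterministic:
lowercase; URLs and `@`-mentions deleted; `#` stripped so the hashtag
word itself is kept; tokens are runs of Unicode letters, with internal
apostrophes kept (`l'égalité` is one token); digit-only strings are
never tokens. Emoji and punctuation are ignored. These rules are a
design choice of this package — reasonable for French Twitter text,
stated here so that their consequences (e.g. elisions count as single
tokens) are explicit.

## Daily scores

For day $t$ with weekday $w(t)$,

$$ s_t = \log\frac{m_t + \varepsilon}{b_{w(t)} + \varepsilon}, $$

where $m_t$ is the unweighted mean of the per-tweet fractions on day
$t$ (tweets with no tokens are excluded) and $b_w$ averages $m_t$ over
a pre-event baseline window, separately per weekday — absorbing the
strong weekly oscillation of word frequencies. The smoothing
$\varepsilon$ is half the smallest non-zero daily mean, and is applied
only when some day has $m_t = 0$; on dense data $\varepsilon = 0$ and
the score is the plain log ratio. The log form removes skewness and
makes scores comparable across indicators of very different base
rates.

Two conventions are configurable but fixed by default:

* **Per-tweet mean, not word-pooled ratio.** The daily mean weights
  each tweet equally. (A pooled variant — total category tokens over
  total tokens — weights by tweet length; user-level summaries use
  pooling, see below, where low-volume robustness matters more.)
* **Baseline window.** Daily-score baselines default to the ~6 months
  before the event (183 days, truncated to the data span);
  user-window analyses use the 3 months before the event.

Uncertainty of $m_t$ comes from a percentile bootstrap over the day's
tweets (default $B = 10\,000$, 95% intervals). The bootstrap is
deterministic given a seed, degenerate-exact (a day of identical
fractions has a zero-width interval), and its width tracks the
$2 \times 1.96\,\sigma/\sqrt{n}$ CLT prediction.

## The exogenous-shock memory model

Daily scores are fitted with

$$ s_t = c + \phi\, s_{t-1} + \beta X_t + \epsilon_t, $$

where $X_t$ is an impulse (1 on the event day only; default) or a step
(1 from the event day on). The impulse form encodes the observed
shape of such episodes: a spike followed by slow relaxation, with the
relaxation rate carried by $\phi$. The interpretation is the
package's central statistic: individual emotional reactions relax
within a day, so under independent behavior consecutive *daily*
deviations are unrelated and $\phi$ is indistinguishable from zero;
reciprocal stimulation (a collective emotion) makes deviations feed
the next day's deviations and yields $\phi > 0$.

Estimation is penalized maximum likelihood equivalent to independent
Gaussian priors of scale 2.5 on the sd-standardized slopes (a standard
weakly informative default), with the intercept free and the residual
variance profiled. With `prior_scale = Inf` the estimate is exactly
OLS — asserted in the tests to $10^{-6}$. Inference uses the
large-sample normal approximation. The fit window defaults to 28 days
on each side of the event (an 8-week span); missing days break the lag
chain rather than being imputed. Known small-sample AR bias
($\approx -(1+3\phi)/n$, about $-0.05$ at $\phi = 0.6$, $n = 56$) is
accepted and covered by the recovery tolerances.

Residual checks (`diagnose()`): Shapiro–Wilk normality, Ljung–Box
serial correlation, augmented Dickey–Fuller stationarity (drift case;
implemented in-package with the standard tau quantile table, p-values
clipped to [0.01, 0.99]), and a Koenker-form Breusch–Pagan test
against the fitted values.

## The agent-based collective-emotion simulator

`simulate_collective()` implements a discrete-time valence–arousal–
field model. Each agent has a signed valence $v_i \in [-1, 1]$ and an
arousal $a_i \in [0, 1]$; a global field $h$ stores the decaying mean
of recently *expressed* valence:

$$ v_i \leftarrow v_i(1-\gamma_v) + b\,h\,[\text{coupling}] +
   \mathcal N(0, \sigma_v), \qquad
   a_i \leftarrow a_i(1-\gamma_a) + r_i + d\,|h|\,[\text{coupling}] +
   \mathcal N(0, \sigma_a), $$

an agent posts when $a_i > \theta$ (then $a_i$ resets), and
$h \leftarrow h(1-\gamma_h) + \gamma_h \overline{v}_{\text{posters}}$.
The event adds a negative valence shock and an arousal burst to every
agent on the first step of the event day. The baseline drive $r_i$
(an agent trait) is what makes uncoupled agents post at all; without
it the uncoupled arm would be silent, which no real stream is.

Default rates are $\gamma_v = 0.3$, $\gamma_a = 0.2$,
$\gamma_h = 0.4$, $\theta = 0.7$, $\sigma_v = 0.15$, 24 steps per day,
500 agents, 120 days. The coupling gain defaults to $b = 0.25$: the
linearized (mean valence, field) system then has per-step spectral
radius $\approx 0.97$ — subcritical, so the pre-event stream is calm,
but slow enough that roughly half of a day-scale deviation survives
into the next day. This value was fixed from the linearization to
realize the qualitative regime the simulator exists to produce
(clear $\phi$ separation between the coupled and uncoupled arms);
with the field gain at the supercritical level the dynamics saturate
spontaneously before the event, which no plausible baseline stream
does. The calibration is an artifact choice of this package, not an
empirical fit.

Posted texts draw tokens from the demo lexicon pack: negative-affect
word probability rises with $\max(0, -v)$, positive with
$\max(0, v)$; social/prosocial/shared-values/first-person words have
fixed base rates; positive and social rates are elevated by 25% on
weekends (giving the weekday seasonality the baseline correction
exists for); the rest is neutral filler.

What the simulator deliberately does **not** emulate: network
topology (the field is global, as in the mean-field framework),
bursty human circadian rhythms, retweets, bots, topic drift, and
vocabulary beyond the demo lexicons. Passing the discrimination test
therefore shows that the *pipeline* separates coupled from uncoupled
dynamics under realistic volumes and noise — not that any particular
real stream is coupled.

## The user panel and mediation ground truth

`simulate_user_panel()` draws, per user, a latent personality $P$,
emotionality $E = gP + \epsilon_E$, a short-window mediator
$M = aE + gP + \epsilon_M$ and a long-window outcome
$Y = c'E + bM + gP + \epsilon_Y$ (defaults $a = 0.5$, $b = 0.4$,
$c' = 0.3$, $g = 0.5$, unit noise). Latent levels map to
word-emission probabilities through a logistic link bounded in
$(0, 0.5)$; tweets arrive at Poisson times with weekend-modulated
volume and a lognormal per-user activity factor.

The analysis mirror is `summarize_users()` (pooled word-count
fractions per user and window; users must post in all three windows),
`corrected_emotionality()` (OLS residual of short-window affect on the
baseline personality vector — positive affect, negative affect,
social processes, first-person singular — plus log post count, which
removes self-selection along measured traits), and `mediate()`.

`mediate()` is a linear, no-interaction product-of-coefficients
implementation: ACME $= \hat a_1 \hat b\,(t_1 - t_0)$ and ADE
$= \hat c\,(t_1 - t_0)$ for a treatment contrast between the 25th and
75th percentiles of the (corrected) treatment; the total effect comes
from its own nested regression and equals ADE + ACME to floating-point
precision — an identity the tests assert at $10^{-10}$. Uncertainty
is a nonparametric bootstrap over users (default $B = 10\,000$;
validation uses 1 000), with percentile intervals and sign-based
p-values. `standardize = TRUE` (default) rescales all variables first
for comparability across indicators; recovery checks against the
known paths run with `standardize = FALSE`, since the
product-of-coefficients ground truth lives on the generator's raw
scale and standardization rescales each path by a variance ratio.

Recovery validation uses the generator's ground-truth table directly
(true $E$, $M$, $Y$, $P$): there the closed form
ACME $= a\,b\,\Delta$, ADE $= c'\Delta$ holds in population and the
10% tolerance covers only sampling noise at $n = 5\,000$. Running the
same check through emitted text would confound it with measurement
attenuation (finite tokens per user) and link curvature — real
phenomena, but not defects of the estimator; text-based checks are
therefore qualitative (sign and correlation with truth) at smaller
panels.

## Synchronization groups and sliding contrasts

A user is in the **high-emotional-synchronization group** when their
pooled affect frequency in the two weeks after the event strictly
exceeds their own 3-month baseline ("more frequently" is strict, so
ties go to low). `sliding_group_difference()` then tracks
high-minus-low group means of any indicator over trailing 1-month
windows, with CIs from resampling users — not tweets — so the
uncertainty respects the user-level sampling design. The null
calibration uses panels with all paths and the personality loading set
to zero; with $g \neq 0$ the groups (defined through $E$) correlate
with personality-driven baseline rates and a pre-event gap is
expected, which is exactly the self-selection problem the corrected
treatment addresses.

## Sequential association and event-reference counts

`sequential_association()` tests whether a tweet containing one
category predicts the same user's *next* tweet containing another,
within a window (default: the two weeks after the event). It fits a
mixed-effects logistic regression with per-user random intercepts and
an autocorrelation correction plus its interaction
(`y ~ x_prev + y_prev + x_prev:y_prev + (1 | user)`), via
`lme4::glmer`. Any consistent approximation of the integral is
acceptable for this design; the Laplace default is used for reported
fits and the faster `nAGQ = 0` approximation in replicate-heavy
calibration runs.

`attack_reference_model()` asks whether highly emotional users keep
talking about the event itself: a zero-inflated negative-binomial
regression (`glmmTMB`, constant inflation) of long-window
event-reference counts on corrected emotionality with log post volume
as exposure offset. The dispersion parameter is reported so that
near-Poisson data are recognizable (size $\to \infty$).

## Numerical and degenerate-input choices

* Missing daily means (no usable tweets) propagate as `NA` scores and
  drop out of the lag chain; no imputation anywhere.
* A constant score series, an all-zero count vector, a rank-deficient
  personality design, or an outcome with no variation raise immediate
  descriptive errors rather than returning numbers.
* All stochastic functions take an explicit seed and are
  bit-reproducible; generator configs refuse to be built without one.
* Bootstrap p-values use the add-one rule $(1 + \#)/(1 + B)$, so they
  are never exactly zero.

## Validation design and problem sizes

The test suite validates every stage against independent oracles:
hand-counted fractions; closed-form log-ratio identities; CLT interval
widths; OLS equivalence of the penalized fit; $\phi$ recovery at
$\phi \in \{0, 0.3, 0.6\}$ over 200 replicates of 56-day series;
coupled-vs-uncoupled discrimination over 50 simulator replicates per
arm at the default 500-agent/120-day size; mediation recovery at
$n = 5\,000$ against the product-of-coefficients closed form; null
coverage of mediation and sliding contrasts on zero-effect panels;
sequential-association recovery at 2 000 users x 30 tweets and null
coverage over 24 smaller replicates. These sizes are the package's
validation conditions, chosen to keep Monte-Carlo error comfortably
inside the asserted tolerances.

## Known limitations

* The tokenizer does not split contractions beyond apostrophe-joined
  units, does not handle emoji as affect carriers, and treats hashtag
  bodies as plain words.
* The demo lexicons are tiny synthetic stand-ins; nothing about their
  coverage generalizes to a real dictionary.
* The shock model is univariate AR(1); interactions between indicators
  are only probed pairwise at the tweet level.
* Mediation assumes linear, no-interaction structural models;
  violations bias ACME/ADE in the usual ways.
* The agent model is mean-field; a networked topology could produce
  memory patterns the global field cannot.
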