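Package: effervescence
Title: Collective Emotion Dynamics and Solidarity Indicators in Tweet Streams
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study collective emotional responses to a sudden
    public trauma in social-media text. Implements dictionary-based
    (LIWC-style) lexical scoring of tweets, weekday-baselined log-ratio
    daily indicator scores with per-day bootstrap uncertainty, an
    exogenous-shock autoregressive model whose memory coefficient
    quantifies collective (as opposed to individual) emotional dynamics,
    and an individual-level analysis of emotional synchronization:
    self-selection-corrected short-term emotionality, high/low
    synchronization groups, sliding-window group contrasts, causal
    mediation (ADE/ACME) with bootstrap confidence intervals, lagged
    tweet-pair mixed-effects logistic association, and a zero-inflated
    negative-binomial model of event-reference counts. Ships synthetic
    generators - an agent-based valence-arousal-field simulator of
    collective emotions and a user panel with known causal ground truth -
    so every stage of the pipeline can be validated against known effects.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    stringi,
    lme4,
    glmmTMB
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
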