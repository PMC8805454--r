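Package: newsaffect
Title: Circumplex Affect Dynamics of News Headlines and Mental-Health
    Search Activity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline relating the day-to-day affective dynamics of
    news-headline language to same-day mental-health search activity at the
    US-state level. Scores headline words against a valence/arousal/dominance
    lexicon (z-standardized 1-9 crowdsourced norms), pools tokens by state
    and day, and derives circumplex dynamics features: flux (SD of scalar
    affect scores), pulse (SD of word-vector magnitudes), and spin (SD of
    word-vector angular displacements) in the VA, VD and AD planes. Provides
    pandemic-phase descriptives (mean, variance, RMSSD, cross-state
    percentile ranks), denormalization of 0-100 search-interest values into
    estimated absolute counts via a daily comparator term of known volume
    tier, and negative binomial mixed-effects models of term-cluster counts
    on time and circumplex features with a state random intercept, reported
    with Wald intervals, Efron pseudo-r-squared and percent-change
    interpretations. A synthetic-data generator emulates every input
    (lexicon, headline corpora, populations, normalized search records with
    known ground truth) so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    glmmTMB,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    lme4,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
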