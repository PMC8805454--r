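---
title: "Circumplex affect dynamics of news headlines: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Circumplex affect dynamics of news headlines: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(newsaffect)
```

## The problem

During the first months of the COVID-19 pandemic, local news headlines
were a daily emotional stimulus for essentially the whole population, and
searches for terms like "anxiety" or "insomnia" are a widely used
population-level surrogate for mental-health burden. This package
implements a pipeline that asks whether the *dynamics* of headline
emotion — not just its average tone — are associated with same-day
mental-health search activity at the US-state level, and provides a
synthetic-data generator that emulates every input so the pipeline is
fully testable without the original scraped corpora or live
search-interest queries.

## Dictionary-based affect scoring

Words are scored against a valence/arousal/dominance (VAD) lexicon: a
table of lemmas rated 1–9 on each dimension (the crowdsourced English
norms of ~14k lemmas are the canonical example; the package reads any
CSV/TSV in that shape via a configurable column map, and
`generate_lexicon()` synthesizes one with the same scale properties —
valence mean 5.064, SD 1.275; arousal 4.211/0.986; dominance
5.185/0.938). Raw ratings are z-standardized against the loaded lexicon
itself (`standardize_lexicon()`), so every downstream score reads as SDs
above or below the average rated word; the raw means/SDs used are stored
with the lexicon for auditability.

Headline titles are lowercased, split on every non-alphabetic character
(so "covid-19" yields the token "covid"), stop words are removed, and
the surviving tokens are matched to lexicon lemmas by exact string — no
stemming or lemmatization, since headline scoring operates on surface
forms and the reference norms are lemmas that mostly coincide with them.
Out-of-vocabulary tokens are dropped silently; on real corpora only a
minority of tokens map (roughly a third), and `pool_daily()` reports the
exact mapping rate `n_mapped / n_raw` as a diagnostic. Tokens are pooled
per (state, day) with repeats kept: daily statistics are
**token-weighted**, because a word used ten times in a day's headlines
is ten exposures, not one.

## Circumplex dynamics: flux, pulse, spin

The circumplex model of affect places words as vectors in a 2D plane of
two affect dimensions (VA, VD or AD). From a day's pooled word vectors
three dynamics statistics are derived, each an SD over the day's words:

- **Flux** — SD of the scalar z-scores along one axis
  (`flux()`); magnitude-sensitive, direction-agnostic.
- **Pulse** — SD of the Euclidean magnitudes of the word
  vectors (`pulse()`); consistency of affective extremity. Invariant to
  common rotations.
- **Spin** — SD of the angular displacement of word vectors from the
  horizontal axis (`spin()`); consistency of affective tone, invariant
  to per-word positive rescaling.

All SDs in this package — lexicon standardization, flux, pulse, spin,
phase variance, the frequent-word threshold — use the sample (n − 1)
denominator. One convention has to hold globally for cross-feature
comparability; the sample form is the standard statistical default.

### The angle convention

The printed formula for a word's angle evaluates the cosine of the angle
between u = (a~x~, 0) and v = (a~x~, a~y~), normalized by the product of
their magnitudes. Because u·v = a~x~² is non-negative, this *folds every
quadrant into [0°, 90°]*: (−1, 1) and (1, 1) both sit at 45°. The
package implements this literal reading as the default (`mode =
"literal"`), and also the standard geometric alternative
|atan2(a~y~, a~x~)| ∈ [0°, 180°] (`mode = "signed"`), with the choice
recorded on the feature table and echoed into the pipeline manifest, so
the two conventions can be compared on the same corpus. Angular spread
is summarized by the ordinary linear SD of angles in degrees, not a
circular SD — spin is defined as a plain SD of angle values, and on the
folded [0°, 90°] range wrap-around cannot occur. Words exactly at the
plane's origin have no angle; they are excluded from spin but retained
for flux and pulse. Degenerate days — fewer than 2 mapped tokens — yield
missing dynamics (an SD of a singleton is undefined under the sample
convention), and days with no mapped token yield missing means too;
missing features exclude a row from modeling rather than being imputed.

## Phase descriptives

The collection period 2020-01-23..2020-10-22 divides into five windows:
Pre-pandemic (50 days, through 2020-03-12), Early Response (26 days,
through 2020-04-07), and Mid-pandemic (198 days) split into three 66-day
partitions for temporal parity. Per state, window and dimension the
package reports the mean, sample variance and RMSSD (root mean square of
successive differences) of the daily mean-affect series, plus cross-state
midrank percentile ranks of RMSSD (the table behind a choropleth).
RMSSD pairs only *calendar-adjacent* days that are both observed: a gap
contributes no pair, because a difference across a gap conflates
multi-day with daily change. High-frequency word tables
(`frequent_words()`) select types at or above 2 sample SDs over the mean
type count; an evenly used vocabulary (type-count SD 0) has no standout
words by construction.

## From normalized search interest to counts

Search-interest platforms report values normalized 0–100 within a query;
absolute counts are recovered by pairing each mental-health term with a
daily comparator term whose absolute volume is published in tiers
("50,000+", ...). The national estimate is
`MH_AdjTot = MH_NormTot × COMP_SV / COMP_NormTot`, with `COMP_SV` the
*tier floor* (the most conservative volume consistent with the published
tier), and the state share is
`MH_AdjState = floor(MH_AdjTot × MH_NormState/MH_NormTot ×
POP_State/POP_Tot)`. Days whose comparator normalizes to 0 are
unusable — the rescale is undefined — and are dropped with a message, not
imputed. The floor carries a tiny numerical guard (+1e-9 before
flooring) so products that are mathematically integral are not pushed
down a count by floating-point error; the guard is far below the
one-count resolution of the estimator. The 17 tracked terms pool into
All (17), Depression (7), Anxiety (6) and Nonspecific (4) clusters;
partial term coverage on a day is treated as upstream corruption and
errors, rather than silently biasing a sum.

## The mixed models

Each cluster's daily state count is modeled as negative binomial
(nbinom2: variance μ + μ²/θ) with a log link, fixed effects for time
(days since 2020-03-24, 213 daily points through 2020-10-22) and the
circumplex features — VA set: t, V, A, Spin~VA~, Pulse~VA~, Flux~V~,
Flux~A~; VAD set adds D and the VD/AD planes — and a Gaussian random
intercept per state, integrated by Laplace approximation (glmmTMB, the
standard estimator for this family; fits are deterministic given data).
Features enter unstandardized, so a coefficient is the log-change per
one unit of the feature's own scale (z-units; degrees for spin), read as
a percent change via `percent_change(beta) = (exp(beta) − 1) × 100`.
Inference is Wald: 95% CIs are β ± 1.96·se. Fit is summarized by Efron's
pseudo-r², computed from conditional fitted means (random effects
included), matching how the index is used for mixed count models. The
time sensitivity check refits with t entered as log(t + 1) — the +1
admits t = 0 — and compares pseudo-r² at 2 decimals; "logistic time" has
no standard formula in this context and the logarithmic transform is the
implemented reading. Marginal predictions (`predict_marginal()`) move
one feature (or a crossed pair) along a grid with the others at sample
means and the random effect at 0.

## The synthetic-data generator

`simulate_study()` emulates all four inputs from one master seed (each
module gets an independent substream, so regenerating one input does not
perturb the others):

- **Lexicon** — ratings drawn at the real norms' means/SDs, clipped to
  [1, 9].
- **Headlines** — per (state, day), target token affect vectors are
  drawn from a Gaussian whose center and spread come from a per-day
  regime (defaults: means wobbling around 0.25 z-units, spreads near 1,
  matching the mildly positive daily means and near-unit flux seen in
  pandemic-era corpora), snapped to the nearest lexicon word, and
  accepted by rejection sampling when realized mean and flux are within
  10% (relative) of target; tokens are woven into titles with
  out-of-vocabulary filler, stop words, numerals and punctuation so
  cleaning and mapping are exercised (mapping rates land near 0.6 —
  higher than real corpora, since fillers are the only unmapped mass).
- **Counts** — cluster-level ground truth drawn from the NB mixed model
  with a known coefficient vector (default: Spin~VA~ −0.02 per degree,
  Flux~A~ +0.22 per z-unit, signs as in the fitted study models, scaled
  to the features' units so linear predictors stay in a realistic
  range), θ = 5, random-intercept SD 0.3; split per-term by multinomial
  allocation so term-level ingestion and cluster pooling are both
  testable.
- **Normalization** — within each (date, term) query, state values are
  per-capita propensities and national values per-capita totals, scaled
  to a 0–100 maximum. In `lossless` mode values keep full precision and
  the comparator tier floor equals its true volume, making the count
  estimator exactly invertible (the round-trip oracle); the lossy mode
  rounds to integers and floors to published tiers, reproducing the real
  platform's information loss.

What the generator does *not* emulate: English syntax and n-gram
context, outlet-level curation artifacts, news-volume waves, spatial
correlation between neighboring states, and autocorrelated residuals in
search behavior. Passing tests therefore demonstrate that the pipeline's
computations are correct and that the estimator recovers known
structure — not that the substantive findings generalize to real
corpora.

## Problem sizes and numerical choices

The bundled analysis scripts run 10 states over the full 274-day
collection period with a 1000-lemma lexicon — large enough for stable
fits and phase windows with full coverage, small enough to run
comfortably on a laptop. The parameter-recovery study uses the modeling
scale of the original design (50 states × 200 days) over 20 replicates
and requires each slope coefficient's mean estimate to fall within 0.05
of truth with Wald CI coverage in [85%, 100%]; the intercept is reported
but assessed separately, since its per-replicate error absorbs the
realized mean of the 50 random intercepts. Optimizer non-convergence is
raised as an error (never silently reported), and a dispersion estimate
beyond 1e4 triggers a Poisson-limit warning.

## Worked example

```{r example, eval = FALSE}
study <- simulate_study(seed = 1, states = sprintf("S%02d", 1:10),
                        dates = seq(as.Date("2020-01-23"),
                                    as.Date("2020-10-22"), "day"))
pools <- pool_daily(study$headlines, study$lexicon)
features <- compute_daily_features(pools)
counts <- estimate_state_counts(study$trends, study$populations)
fit <- fit_nb_glmm(build_design(features, cluster_sums(counts),
                                cluster = "All", feature_set = "VA"))
fit$coef
predict_marginal(fit, "Flux_A", seq(0.4, 1.6, length.out = 9))
```

The same flow, staged with on-disk tables, lives in `analysis/01..05`
and as the one-call `run_pipeline()` orchestrator.

## Known limitations

- The literal angle fold discards quadrant information; signed mode is
  provided but the two are not reconciled into a single "correct" spin.
- Percent-change readings assume the feature scale is meaningful per
  unit; a one-degree change in spin is a much smaller perturbation than
  a one-z-unit change in flux.
- The count estimator inherits the comparator's tier-floor conservatism;
  estimated absolute counts are lower bounds in expectation.
- Type-I error and power of the Wald tests are inherited from the
  Laplace approximation; with 50 groups this is accurate, but with very
  few states the random-intercept SD (and hence CIs) can be poorly
  determined.
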