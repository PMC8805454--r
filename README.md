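# newsaffect

Circumplex affect dynamics of news headlines and same-day mental-health
search activity, as a tested R pipeline.

## What it does

News headlines are scored word-by-word against a valence / arousal /
dominance (VAD) lexicon (1–9 crowdsourced ratings, z-standardized), and
each US state's day of headline language becomes a cloud of word vectors
in circumplex affect space. Three dynamics statistics summarize each day
— all sample SDs over the day's mapped words:

- **Flux** = SD of the scalar z-scores on one axis (V, A or D):
  variability of affect magnitude along a dimension.
- **Pulse** = SD of word-vector Euclidean magnitudes in a 2D plane (VA,
  VD, AD): consistency of affective extremity.
- **Spin** = SD of word-vector angular displacements from the horizontal
  axis: consistency of affective tone.

On the outcome side, 0–100 normalized search-interest values for 17
mental-health terms are converted to estimated absolute daily counts via
a daily comparator term of published volume tier:

```
MH_AdjTot   = MH_NormTot × COMP_SV / COMP_NormTot
MH_AdjState = floor( MH_AdjTot × MH_NormState/MH_NormTot × POP_State/POP_Tot )
```

Counts pooled into All / Depression / Anxiety / Nonspecific clusters are
then modeled as negative binomial (nbinom2, variance μ + μ²/θ) mixed
models with a log link:

```
count ~ t + V + A + Spin_VA + Pulse_VA + Flux_V + Flux_A + (1 | state)      [VA]
count ~ t + V + A + D + Spin_{VA,VD,AD} + Pulse_{VA,VD,AD}
        + Flux_{V,A,D} + (1 | state)                                        [VAD]
```

with Wald 95% intervals, Efron pseudo-r², percent-change readings
`(exp(β) − 1) × 100`, and marginal/interaction prediction grids. Phase
descriptives (mean, variance, RMSSD and cross-state percentile ranks over
the five pandemic-phase windows: 50 / 26 / 3 × 66 days) and
high-frequency word tables cover the exploratory side.

A first-class synthetic-data generator (`simulate_study()`) emulates all
four inputs — lexicon, headline corpus, populations, normalized search
records with retained ground truth — so every stage is testable offline,
including exact round-trip recovery of counts under lossless
normalization and parameter recovery of the mixed model.

Intended for researchers in infodemiology, affective science and
computational social science who want the full path from raw headline
text to fitted count models in auditable, tested steps.

## Worked example

The staged analysis lives in `analysis/01_simulate.R` …
`analysis/05_models.R` (each a thin driver over the package functions,
writing its tables under `results/`). Running the five scripts on the
default synthetic study (10 states, 2020-01-23 → 2020-10-22, 1000-lemma
lexicon) prints, abridged:

```
pooled 2740 state-days; corpus mapping rate 59.60%
daily Flux_V median 0.96 | Pulse_VA median 0.64 | Spin_VA median 25.8 deg
audit vs ground truth on 36210 rows: max |error| = 0
All          VA   n= 2130  theta= 12.92  pseudo-r2=0.44

All-cluster VA model, key effects (percent change per unit):
     term        beta      ci_low     ci_high      p_value percent_change
1 Spin_VA -0.01907154 -0.02612321 -0.01201987 1.152296e-07      -1.889083
2  Flux_A  0.27893172  0.15354043  0.40432302 1.300619e-05      32.171710

linear vs log time, Efron pseudo-r2 (2 dp): linear=0.44, log=0.43
```

Reading: every token the cleaning stage kept either mapped to the
lexicon or was generator filler (59.6% mapped); the count estimator
inverted the lossless normalization exactly on all 36,210 term-days; and
the fitted model recovers the generating structure — spin's negative
effect (fewer searches when headline tone is more scattered, here −1.9%
per degree) and arousal-flux's positive effect (+32% per z-unit), with
linear and log time indistinguishable at 2 decimals of pseudo-r², the
same qualitative pattern the modeling was designed to detect.

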