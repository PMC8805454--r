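#!/usr/bin/env Rscript

# Stage 2 — sentiment scoring and circumplex features.
#
# Re-reads the stage-1 inputs from disk (so this stage runs on any
# corpus in the same dialect), cleans and pools headline tokens by
# (state, day), and derives daily mean V/A/D plus flux, pulse and spin in
# the VA, VD and AD planes (literal angle mode).

library(newsaffect)

data_dir <- file.path("results", "data")
lexicon <- standardize_lexicon(load_lexicon(
  file.path(data_dir, "lexicon_raw.csv"),
  col_map = c(word = "word", valence = "valence_raw",
              arousal = "arousal_raw", dominance = "dominance_raw")))
headlines <- read_headlines(file.path(data_dir, "headlines.csv"))

pools <- pool_daily(headlines, lexicon)
cat(sprintf("pooled %d state-days; corpus mapping rate %.2f%%\n",
            nrow(pools), 100 * attr(pools, "mapping_rate")))

features <- compute_daily_features(pools, angle_mode = "literal")
write_daily_features(features, file.path("results", "daily_features.csv"))

ok <- !is.na(features$Flux_V)
cat(sprintf("daily Flux_V median %.2f | Pulse_VA median %.2f | Spin_VA median %.1f deg\n",
            median(features$Flux_V[ok]), median(features$Pulse_VA[ok]),
            median(features$Spin_VA[ok])))
cat("wrote results/daily_features.csv\n")
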