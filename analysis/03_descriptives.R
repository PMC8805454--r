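#!/usr/bin/env Rscript

# Stage 3 — phase-based descriptives.
#
# Splits the collection period into the five pandemic-phase windows
# (50 / 26 / 3 x 66 days), computes per-state mean, variance and RMSSD of
# daily affect per window, cross-state percentile ranks of RMSSD (the
# choropleth table), and each state's high-frequency words with their
# (V, A) coordinates (the word-cloud table).

library(newsaffect)

data_dir <- file.path("results", "data")
lexicon <- standardize_lexicon(load_lexicon(
  file.path(data_dir, "lexicon_raw.csv"),
  col_map = c(word = "word", valence = "valence_raw",
              arousal = "arousal_raw", dominance = "dominance_raw")))
headlines <- read_headlines(file.path(data_dir, "headlines.csv"))
pools <- pool_daily(headlines, lexicon)
features <- compute_daily_features(pools)

stats <- phase_stats(features)
write.csv(stats, file.path("results", "phase_stats.csv"),
          row.names = FALSE, na = "")
pct <- percentile_rank_table(stats)
write.csv(pct, file.path("results", "phase_rmssd_percentiles.csv"),
          row.names = FALSE, na = "")

fw <- do.call(rbind, lapply(split(pools, pools$state), function(p) {
  out <- frequent_words(p, lexicon)
  if (nrow(out) > 0) out$state <- p$state[1]
  out
}))
write.csv(fw, file.path("results", "frequent_words.csv"),
          row.names = FALSE)

v_rmssd <- stats[stats$dimension == "V", ]
cat("phase-window mean RMSSD of daily valence:\n")
print(tapply(v_rmssd$rmssd, v_rmssd$window, mean, na.rm = TRUE))
cat("wrote phase_stats, phase_rmssd_percentiles, frequent_words\n")
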