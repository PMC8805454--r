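#!/usr/bin/env Rscript

# Stage 1 — generate the study inputs.
#
# No accessions exist for the original scraped headlines or the live
# search-interest pulls, so the analysis runs on the package's synthetic
# study: a 1000-lemma affect lexicon on the 1-9 scale, a headline corpus
# for 10 states over the 2020-01-23..2020-10-22 collection period whose
# daily affect follows the default regime, state populations, and
# normalized search-interest records drawn from a known negative binomial
# mixed model (ground truth retained for stage 4's audit).

library(newsaffect)

seed <- 20200324
out <- file.path("results", "data")
dir.create(out, showWarnings = FALSE, recursive = TRUE)

study <- simulate_study(
  seed = seed,
  states = sprintf("S%02d", 1:10),
  dates = seq(as.Date("2020-01-23"), as.Date("2020-10-22"), by = "day"),
  lexicon_size = 1000L
)

write.csv(study$lexicon_raw, file.path(out, "lexicon_raw.csv"),
          row.names = FALSE)
write_lexicon(study$lexicon, file.path(out, "lexicon_standardized.tsv"))
write.csv(study$headlines, file.path(out, "headlines.csv"),
          row.names = FALSE)
write.csv(study$populations, file.path(out, "populations.csv"),
          row.names = FALSE)
write.csv(study$trends, file.path(out, "trends.csv"), row.names = FALSE)
write.csv(study$truth$counts, file.path(out, "ground_truth_counts.csv"),
          row.names = FALSE)

cat("states:", length(unique(study$headlines$state)),
    "| headlines:", nrow(study$headlines),
    "| trends rows:", nrow(study$trends), "\n")
cat("wrote inputs under", out, "\n")
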