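#!/usr/bin/env Rscript

# Stage 4 — absolute search-count estimation.
#
# Denormalizes the 0-100 search-interest records into estimated absolute
# state-level counts via the daily comparator term (national rescale by
# the comparator's tier-floor-to-normalized ratio, then state
# apportionment by interest and population share, floored), pools terms
# into the four outcome clusters, and audits the estimates against the
# generator's ground truth.

library(newsaffect)

data_dir <- file.path("results", "data")
trends <- read_trends(file.path(data_dir, "trends.csv"))
populations <- read_populations(file.path(data_dir, "populations.csv"))

counts <- estimate_state_counts(trends, populations)
write.csv(counts, file.path("results", "estimated_counts.csv"),
          row.names = FALSE)
clusters <- cluster_sums(counts)
write.csv(clusters, file.path("results", "cluster_counts.csv"),
          row.names = FALSE)

truth <- read.csv(file.path(data_dir, "ground_truth_counts.csv"))
truth$date <- as.Date(truth$date)
m <- merge(counts, truth, by = c("state", "date", "term"),
           suffixes = c("_est", "_true"))
cat(sprintf("audit vs ground truth on %d rows: max |error| = %d\n",
            nrow(m), max(abs(m$count_est - m$count_true))))
for (cl in unique(clusters$cluster)) {
  x <- clusters$count[clusters$cluster == cl]
  cat(sprintf("%-12s mean %8.1f  var/mean %6.1f (overdispersed)\n",
              cl, mean(x), var(x) / mean(x)))
}
cat("wrote estimated_counts, cluster_counts\n")
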