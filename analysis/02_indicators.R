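#!/usr/bin/env Rscript
# Step 2: from raw samples to workload indicators.
#
# Reads the simulated session from results/session, computes the Index of
# Pupillary Activity per eye for every segment (two-level Symlet-16 detail
# -> modulus maxima -> universal threshold with factor 0.8 -> events per
# second), derives the four channels (left, right, mean, |diff|),
# z-standardizes each channel within participant, and aggregates per
# condition label.

library(pupilload)

samples <- read_samples("results/session/samples.csv")
segments <- read_segments("results/session/segments.csv")

cat("computing per-segment IPA for", nrow(segments), "segments...\n")
indicators <- compute_indicators(samples, segments)
indicators <- standardize_indicators(indicators)
aggregates <- aggregate_by_label(indicators)

dir.create("results/run", showWarnings = FALSE, recursive = TRUE)
write_indicators(indicators, "results/run/indicators.csv")
pupilload:::write_formatted(aggregates, "results/run/aggregates.csv",
                            list(value = 6L))

# quick look: grand-mean conventional IPA per condition
prof <- aggregate(value ~ label + channel,
                  data = aggregates[!aggregates$standardized, ], FUN = mean)
prof <- prof[prof$channel %in% c("mean", "diff"), ]
for (ch in c("mean", "diff")) {
  sub <- prof[prof$channel == ch, ]
  ord <- match(condition_labels(), sub$label)
  cat(sprintf("%-5s channel: %s\n", ch,
              paste(sprintf("%s=%.2f", sub$label[ord], sub$value[ord]),
                    collapse = " ")))
}
cat("wrote results/run/indicators.csv and aggregates.csv\n")
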