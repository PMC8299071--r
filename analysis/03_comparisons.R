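#!/usr/bin/env Rscript
# Step 3: the Bayesian comparison battery.
#
# Runs the study's eight pairwise contrasts (fixation task 2 vs 1
# undirected; level-vs-fixation and neighbouring-level contrasts directed)
# for the mean and diff channels, conventional and z-standardized: JZS
# paired-t Bayes factors with a Cauchy(0, 1) prior on the effect size,
# posterior means with central 95% credible intervals, and evidence
# classification.  Also checks the preconditions: per-level accuracy and
# the equality of fixation precision before vs after the test.

library(pupilload)

samples <- read_samples("results/session/samples.csv")
segments <- read_segments("results/session/segments.csv")
targets <- readr::read_csv("results/session/targets.csv",
                           show_col_types = FALSE)

res <- run_analysis(samples, segments, targets = targets,
                    out_dir = "results/run")

acc <- res$accuracy
cat("accuracy by level (possible items only):\n")
print(round(tapply(acc$accuracy, acc$label, mean), 2))

cat("\nfixation precision equality (undirected BF10, H0 = equal):\n")
pc <- res$precision_comparisons
for (i in seq_len(nrow(pc))) {
  cat(sprintf("  %s: BF10 = %.3f%s\n", pc$channel[i], pc$bf10[i],
              evidence_marker(pc$evidence[i])))
}

cm <- res$comparisons
key <- cm[cm$channel == "mean" & !cm$standardized &
            cm$pair_a %in% c("fix2", "a"), ]
cat("\nheadline mean-channel contrasts (conventional):\n")
for (i in seq_len(nrow(key))) {
  cat(sprintf("  %s - %s: ES %.2f [%.2f; %.2f], BF10 %.4g%s\n",
              key$pair_a[i], key$pair_b[i], key$es_mean[i], key$es_lo[i],
              key$es_hi[i], key$bf10[i], evidence_marker(key$evidence[i])))
}
cat("\nfull table in results/run/comparisons.csv\n")
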