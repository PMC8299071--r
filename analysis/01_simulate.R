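#!/usr/bin/env Rscript
# Step 1: simulate a binocular eye-tracking study.
#
# A "study" cohort: two 54 s fixation tasks flanking three blocks of 20
# spatial-reasoning items (six difficulty levels a-f, five possible and five
# impossible items each), recorded at 300 Hz.  Test levels carry a higher
# transient-dilation rate than the fixation tasks (designed standardized
# workload effect 0.8 on the mean channel) and a between-eye coupling that
# rises from the one-transformation-step levels (a, b) to the
# two-transformation-step levels (c-f).  Everything is reproducible from the
# master seed.

library(pupilload)

n_participants <- as.integer(Sys.getenv("PUPILLOAD_N", "10"))
seed <- as.integer(Sys.getenv("PUPILLOAD_SEED", "7"))
out <- "results/session"

design <- cohort_design(n_participants = n_participants, master_seed = seed)
cat(sprintf("simulating %d participants (master seed %d)...\n",
            n_participants, seed))
cohort <- generate_cohort(design)
paths <- write_session(cohort, out)

cat(sprintf("wrote %s: %d samples, %d segments, %d fixation-cross windows\n",
            out, nrow(cohort$samples), nrow(cohort$segments),
            nrow(cohort$targets)))
cat("ground truth: per-segment event counts and rates in",
    "truth_segments.csv;\nper-participant workload effects in",
    "truth_participants.csv\n")
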