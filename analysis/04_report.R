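#!/usr/bin/env Rscript
# Step 4: render the human-readable run report from the written artifacts
# (no recomputation): condition profiles for every channel plus the full
# comparison table with evidence markers (* moderate ... **** extreme for a
# difference; ' ... '''' for equality).

library(pupilload)

lines <- make_report("results/run")
cat(lines, sep = "\n")
cat("\nreport saved to results/run/report.txt\n")
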