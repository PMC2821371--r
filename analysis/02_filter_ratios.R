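#!/usr/bin/env Rscript
# Step 2 -- read the simulated arrays back from disk, apply the
# Present-in-at-least-half detection filter (9 of 18), and compute the
# per-probeset M:F ratio of means. Writes results/ratios.tsv.

library(zdosage)

SEED <- 1L
ds <- read_expression("results/sim/matrix.tsv",
                      "results/sim/calls.tsv",
                      "results/sim/sex.tsv")

fds <- detection_filter(ds, min_present_fraction = 0.5)
cat(sprintf("detection filter: %d of %d probesets retained (threshold %d Present calls)\n",
            attr(fds, "n_retained"), n_probesets(ds),
            attr(fds, "present_threshold")))

ratios <- sex_ratios(fds, floor_intensity = 1.0)
write_result_table(ratios, "results/ratios.tsv",
                   list(seed = SEED, floor_intensity = 1.0,
                        n_retained = attr(fds, "n_retained")))
cat(sprintf("M:F ratios span %.2f - %.2f (median %.2f)\n",
            min(ratios$mf_ratio), max(ratios$mf_ratio),
            median(ratios$mf_ratio)))
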