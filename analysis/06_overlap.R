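#!/usr/bin/env Rscript
# Step 6 -- overlap significance of the ratio-based compensation calls
# against the simulation ground truth, within the expressed-Z universe
# (10000 redraws of both sets). An external study's compensated list can be
# substituted for the truth column to reproduce a cross-study comparison.

library(zdosage)

SEED <- 1L
comp <- read.delim("results/compensation_calls.tsv", comment.char = "#")
truth <- read.delim("results/sim/truth.tsv", comment.char = "#")

universe <- comp$probeset_id
called_comp <- comp$probeset_id[comp$class == "compensated"]
true_comp <- intersect(truth$probeset_id[truth$true_class == "z_compensated"],
                       universe)

ov <- overlap_significance(called_comp, true_comp, universe,
                           n_sims = 10000, seed = SEED)
print(ov)
write_result_table(
  data.frame(n_universe = ov$n_universe, n_a = ov$n_a, n_b = ov$n_b,
             observed = ov$observed_overlap, expected = ov$expected_overlap,
             empirical_p = ov$empirical_p),
  "results/overlap_compensated_vs_truth.tsv",
  list(seed = SEED, n_sims = ov$n_sims))
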