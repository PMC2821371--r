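#!/usr/bin/env Rscript
# Step 1 -- simulate the study: 18 single-embryo arrays (9 male, 9 female)
# over a ZW genome with ~30% of Z probesets dosage-compensated, a
# compensation-enriched MHM-like window on Zp, and W-linked female-specific
# probesets. Writes the dataset and its ground truth under results/sim/.

library(zdosage)

SEED <- 1L
dir.create("results/sim", recursive = TRUE, showWarnings = FALSE)

cfg <- sim_config(seed = SEED)
sim <- simulate_dataset(cfg)

write_expression(sim$dataset,
                 "results/sim/matrix.tsv",
                 "results/sim/calls.tsv",
                 "results/sim/sex.tsv")
write_annotation(sim$annotation, "results/sim/annotation.tsv")
meta <- list(seed = SEED, config_hash = config_hash(cfg))
write_result_table(sim$truth, "results/sim/truth.tsv", meta)

ts <- truth_summary(sim$truth)
cat("simulated", n_probesets(sim$dataset), "probesets x",
    n_samples(sim$dataset), "samples\n")
print(ts$class_counts)
cat(sprintf("expected Z-wide mean log2(M:F) from the mixture: %.3f\n",
            ts$expected_z_mean_log2_mf))
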