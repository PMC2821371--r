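#!/usr/bin/env Rscript
# Step 4 -- classify sex-biased and compensated/non-compensated probesets,
# tally them by chromosome, and contrast Z against the autosomes with a
# Wilcoxon rank-sum test on log2(M:F). Writes bias, compensation and
# chromosome-summary tables under results/.

library(zdosage)

SEED <- 1L
ds <- read_expression("results/sim/matrix.tsv", "results/sim/calls.tsv",
                      "results/sim/sex.tsv")
ann <- read_annotation("results/sim/annotation.tsv")
fds <- detection_filter(ds)
ratios <- sex_ratios(fds)
sam_tab <- read.delim("results/sam_table.tsv", comment.char = "#")

## sex-bias funnel: FDR-significant, then ratio band 1.5-3.2 (M) / >1.5 (F)
bias <- classify_bias(sam_tab, ratios)
funnel <- attr(bias, "funnel")
cat(sprintf("male funnel:   %d significant -> %d ratio-biased\n",
            funnel$male["fdr_stage"], funnel$male["ratio_stage"]))
cat(sprintf("female funnel: %d significant -> %d ratio-biased\n",
            funnel$female["fdr_stage"], funnel$female["ratio_stage"]))
write_result_table(bias, "results/bias_calls.tsv", list(seed = SEED))

male_ids <- bias$probeset_id[bias$direction == "male"]
female_ids <- bias$probeset_id[bias$direction == "female"]
cat("male-biased by chromosome:\n")
print(chromosome_distribution(male_ids, ann))
cat("female-biased by chromosome:\n")
print(chromosome_distribution(female_ids, ann))

## compensation banding on the expressed Z subset
comp <- classify_compensation(ratios, annotation = ann, chromosome = "Z")
cat(sprintf("expressed Z probesets: %d; compensated %d, non-compensated %d, intermediate %d\n",
            nrow(comp), sum(comp$class == "compensated"),
            sum(comp$class == "non_compensated"),
            sum(comp$class == "intermediate")))
write_result_table(comp, "results/compensation_calls.tsv", list(seed = SEED))

## Z vs autosomes on log2(M:F)
chrom <- ann$chromosome[match(ratios$probeset_id, ann$probeset_id)]
z_vals <- ratios$log2_mf[chrom == "Z"]
aut_vals <- ratios$log2_mf[chrom %in% as.character(1:28)]
wrs <- rank_sum_compare(z_vals, aut_vals)
cat(sprintf("Z mean log2(M:F) = %.3f vs autosomes %.3f; Wilcoxon p = %.3g\n",
            mean(z_vals), mean(aut_vals), wrs$p_value))

cs <- chromosome_summary(ratios, fds, ann, comp)
write_result_table(cs$per_chromosome, "results/chromosome_summary.tsv",
                   list(seed = SEED, wilcoxon_p_z_vs_autosomes = wrs$p_value))
write_result_table(cs$strata, "results/strata_summary.tsv", list(seed = SEED))
cat("per-sex log2 expression by stratum:\n")
print(cs$strata)
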