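#!/usr/bin/env Rscript
# Step 7 -- term enrichment of the male-biased genes. Builds a synthetic
# GMT in which one term is loaded with non-compensated Z genes (emulating a
# sex-differentiation category) next to random terms, collapses probesets
# to unique genes by annotation quality, and runs the hypergeometric test
# with BH correction against the transcriptome background.

library(zdosage)

SEED <- 1L
ann <- read_annotation("results/sim/annotation.tsv")
bias <- read.delim("results/bias_calls.tsv", comment.char = "#")
truth <- read.delim("results/sim/truth.tsv", comment.char = "#")
ratios <- read.delim("results/ratios.tsv", comment.char = "#")

male_ids <- bias$probeset_id[bias$direction == "male"]
query_genes <- collapse_probesets_to_genes(male_ids, ann, seed = SEED)
background_genes <- collapse_probesets_to_genes(ratios$probeset_id, ann,
                                                seed = SEED)

set.seed(SEED)
noncomp_genes <- unique(ann$gene_id[match(
  truth$probeset_id[truth$true_class == "z_noncompensated"],
  ann$probeset_id)])
gmt_path <- "results/synthetic_terms.gmt"
lines <- c(
  paste(c("SEXDIFF_LIKE", "synthetic term loaded with non-compensated Z genes",
          sample(intersect(noncomp_genes, background_genes), 15),
          sample(background_genes, 5)), collapse = "\t"),
  vapply(1:3, function(i)
    paste(c(sprintf("RANDOM_%d", i), "random background term",
            sample(background_genes, 20)), collapse = "\t"), character(1)))
writeLines(lines, gmt_path)

terms <- read_gene_sets(gmt_path)
enr <- hypergeometric_enrichment(query_genes, terms, background_genes)
print(enr[, c("term_id", "k", "K", "n", "N", "raw_p", "adjusted_p")])
write_result_table(enr, "results/enrichment.tsv",
                   list(seed = SEED, background = "transcriptome",
                        n_background = length(background_genes)))
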