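# zdosage

Analysis pipeline for **sex-dimorphic gene expression and Z-chromosome
dosage compensation** in single-channel (MAS5-style) microarray data from
ZW systems such as birds, where males are ZZ and females ZW. Written for
transcriptomics researchers who need a tested, scriptable implementation of
the classic analysis chain:

1. **Detection filtering** — keep probesets called *Present* in at least
   half the arrays (`detection_filter()`).
2. **SAM differential testing** — the two-class unpaired Significance
   Analysis of Microarrays statistic
   `d = (x̄_M − x̄_F) / (s + s0)` with the pooled scatter
   `s = sqrt((1/n_M + 1/n_F) · (SS_M + SS_F)/(n_M + n_F − 2))`, a
   CV-minimizing fudge factor `s0`, a permutation null over distinct
   sex-label arrangements (exhaustive for 9 vs 9: C(18,9) = 48620),
   delta-threshold FDR and per-probeset q-values (`sam_test()`).
3. **Ratio classification** — M:F ratio of linear means per probeset
   (`sex_ratios()`); the two-stage bias funnel (FDR-significant, then
   1.5 < M:F < 3.2) via `classify_bias()`; compensated
   (M:F ∈ [0.8, 1.3]) vs non-compensated (M:F ≥ 1.5) banding via
   `classify_compensation()`; per-chromosome summaries and the
   Z-versus-autosome Wilcoxon rank-sum contrast.
4. **Positional profiles** — running averages of 30 consecutive log2
   ratios at the median window position, the |log2 M:F| *amplitude*
   profile, and a region contrast that quantifies the compensation valley
   at an MHM-like window (`running_average()`, `amplitude_profile()`,
   `region_contrast()`).
5. **List comparison & enrichment** — Monte-Carlo overlap significance
   with both sets redrawn from the declared universe
   (`overlap_significance()`), and hypergeometric term enrichment with
   Benjamini–Hochberg correction after quality-aware probeset→gene
   de-duplication (`hypergeometric_enrichment()`).

A first-class **synthetic-data generator** (`sim_config()`,
`simulate_dataset()`) emulates the dosage structure these analyses assume —
autosomal parity, a compensated/non-compensated Z mixture realized through
*reduced female expression*, spatial enrichment of compensated genes inside
a designated MHM window, W-linked female-specific probesets, log-normal
noise and a logistic Present-call model — with per-probeset ground truth,
so the whole pipeline is testable end to end without external data.

## Worked example

The `analysis/` directory holds the numbered workflow
(`01_simulate.R` … `07_enrichment.R`, run in order from the repository
root; outputs land under `results/`). Condensed, the core of it is:

```r
library(zdosage)

sim <- simulate_dataset(sim_config(seed = 1))   # 4730 probesets, 9 + 9 arrays
fds <- detection_filter(sim$dataset)            # 4701 retained (>= 9 Present)
ratios <- sex_ratios(fds)

sam <- sam_test(fds, sam_config(seed = 1))      # exhaustive 48620 permutations
sam
#> sam_result: 4701 probesets, 48620 permutations (exhaustive), s0 = 0.1514
#>   called at target FDR: 486 positive, 25 negative (delta = 1.097705)

bias <- classify_bias(sam, ratios)
attr(bias, "funnel")$male
#> fdr_stage ratio_stage
#>       486         485
```

486 probesets are significantly male-biased at 5% FDR, 485 of which also
pass the 1.5–3.2 ratio band — and all of them are Z-linked
(`chromosome_distribution()`), reflecting the generator's 490
non-compensated Z probesets. The per-stratum expression summary shows the
dosage mechanism: male Z expression matches autosomes while the female
non-compensated stratum is one log2 unit lower:

```
          stratum    n mean_log2_male mean_log2_female           gap
1       autosomes 3981       7.990244         7.990724 -0.0004800215
2               Z  695       8.040781         7.338982  0.7017987706
3     compensated  207       8.140672         8.117785  0.0228868583
4 non_compensated  485       7.998715         7.003750  0.9949650458
```

The expressed-Z mean log2(M:F) of 0.70 equals the truth mixture
`0.3·log2(1) + 0.7·log2(2) = 0.7`; the amplitude profile dips inside the
simulated MHM window (inside 0.562 vs outside 0.738, rank-sum p = 0.013 at
the default window size), and the ratio distribution shows the two modes of
the compensated/non-compensated mixture at log2 ≈ 0 and ≈ 1. The overlap of
the banding calls with the simulation truth is maximal (207 of 207
compensated calls are true, expected 62 by chance, empirical p = 1e-4 at
10000 redraws), and a synthetic term loaded with non-compensated Z genes is
the top enrichment hit (adjusted p ≈ 7e-11) while random terms are null.

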