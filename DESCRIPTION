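Package: zdosage
Title: Sex-Dimorphic Expression and Z-Chromosome Dosage Compensation Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A tested pipeline for analysing sex-dimorphic gene expression
    and Z-chromosome dosage compensation from detection-filtered microarray
    data: MAS5-style Present-call filtering, a from-scratch implementation
    of the two-class unpaired SAM permutation test with delta-threshold FDR
    and q-values, male:female ratio-of-means classification into
    compensated and non-compensated classes, positional running-average and
    amplitude profiles along a chromosome with region (MHM) valley
    assessment, Monte-Carlo gene-set overlap significance, and
    hypergeometric term enrichment with Benjamini-Hochberg correction.
    Includes a synthetic-data generator that emulates the dosage structure
    of the avian ZW system (non-compensated Z genes realised through
    reduced female expression, W-linked female-specific genes, spatial
    clustering of compensated genes) so that every stage is testable
    without external array data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
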