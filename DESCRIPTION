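Package: csfqtl
Title: Single-Cell cis-eQTL, Allele-Specific Expression and Factor Analyses
    for CSF Immune Cells
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Downstream statistical genetics for droplet single-cell RNA-seq
    cohorts of cerebrospinal fluid immune cells. Implements pseudobulk
    cis-eQTL mapping with a two-random-effect linear mixed model (kinship and
    per-donor read depth), gene-level permutation correction with Storey
    q-values and a conditional-FDR option, sum-of-single-effects Bayesian
    fine-mapping into credible sets, beta-binomial tests for allele-specific
    expression and two-isoform transcript usage, permutation-based regulon
    enrichment on factor loadings, and viral-prevalence regressions on
    cell-by-virus UMI matrices. A synthetic-data generator produces all
    required inputs with planted effects so every analysis can be exercised
    and calibrated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    yaml,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
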