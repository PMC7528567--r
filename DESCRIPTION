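Package: ewastrial
Title: Intervention EWAS, Region Calling, and Enrichment Analysis for
    Micronutrient-Trial Methylation Studies
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis toolkit for randomized micronutrient-intervention
    DNA-methylation studies on Illumina-style beta-value arrays. Provides
    per-CpG intervention EWAS with covariate adjustment and
    Benjamini-Hochberg FDR, two independent differentially-methylated-region
    callers (an autocorrelation-corrected Stouffer-Liptak scan with Sidak
    regional adjustment, and a Gaussian-kernel smoother with Satterthwaite
    calibration) plus a consensus check, candidate-locus robust regression
    with empirical Brown's combination, CpG-set enrichment with
    variance-matched controls and a sample-permutation null, cis-mQTL and
    genotype-by-intervention model comparison, post hoc sensitivity analyses
    (balanced resampling for sex imbalance, interaction and stratified
    tests, SNP-in-probe flags), array and pyrosequencing QC, and a
    synthetic-cohort generator that emulates the data structure of
    Gambian-like and Indian-like trial cohorts for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    MASS,
    limma,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    VariantAnnotation,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
biocViews: DNAMethylation, DifferentialMethylation, EpigenomeWideAssociation,
    MethylationArray, QualityControl, StatisticalMethod
RoxygenNote: 7.3.3
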