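Package: admixScan
Title: Simulation-Calibrated Selection Scans in Admixed Populations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Genome scans for recent positive selection in admixed
    populations, calibrated by coalescent simulation of the underlying
    demography. Implements windowed site-frequency-spectrum classification
    (an SFselect-style linear support-vector score), the integrated
    haplotype score (iHS) with extended haplotype homozygosity computed on
    physical positions, neutral-simulation critical values (99.99th
    percentile thresholds) for admixed and unadmixed population classes,
    simplified PCA-based local ancestry assignment on 20-SNP blocks with
    masking of one ancestry component, resampling tests for ancestry
    enrichment in selected windows, and detection of regions with
    unbalanced local ancestry. Synthetic data are generated under a
    three-population out-of-Africa demography with an optional
    West-Eurasian admixture pulse, using msprime through the system
    Python interpreter.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    Rcpp,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    Biostrings,
    VariantAnnotation
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
SystemRequirements: Python (>= 3.8) with msprime (>= 1.0) and tskit, for
    the simulation module only.
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'RcppExports.R'
    'accessors.R'
    'genome_io.R'
    'ancestry.R'
    'ihs.R'
    'demography.R'
    'simulate.R'
    'calibrate.R'
    'sfs.R'
    'pipeline.R'
    'reexports.R'
    'utils.R'
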