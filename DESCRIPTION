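Package: SnpHapScan
Title: Candidate-Gene SNP and Haplotype Association Scanning for
    Case-Control Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Multi-stage association analysis of tag SNPs grouped into
    candidate gene regions in unmatched case-control studies: genotype
    quality control (call rate, duplicate concordance, Hardy-Weinberg
    equilibrium in controls), single-SNP codominant and allele-dosage
    trend logistic models with within-gene false discovery rate control,
    gene-level minimum-p permutation (min-P) tests, haplotype frequency
    estimation from unphased genotypes by an expectation-maximization
    algorithm, haplotype odds ratios from posterior-dosage logistic
    models with rare-haplotype pooling, sliding-window haplotype scans
    (haplowalk), pairwise linkage disequilibrium, and diet-stratified
    effects with interaction likelihood-ratio tests. Includes a
    synthetic cohort generator emulating a multi-center case-control
    study with block-wise linkage disequilibrium, so the whole pipeline
    is testable end to end without subject-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
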