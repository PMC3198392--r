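---
title: "Multi-stage candidate-gene association scanning: models, choices and limits"
author: "SnpHapScan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-stage candidate-gene association scanning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(SnpHapScan)
```

This vignette is the package's own account of the statistics it
implements: what each stage assumes, where the numerical choices lie,
what the synthetic-cohort generator does and does not emulate, and
which design questions were genuinely open and how they were decided.

## The screening cascade

The package targets unmatched (frequency-matched) hospital-based
case-control studies in which a handful of candidate gene regions are
covered by tag SNPs at a minor-allele-frequency floor of about 5%, and
evidence is accumulated in stages so that multiple testing is handled
at each level rather than once at the end:

single SNPs → gene regions (min-P) → 3-SNP windows (haplowalk) →
analyst-named blocks → strata of a dietary covariate.

Every model in the cascade is an unconditional logistic regression;
the stages differ only in what enters the design matrix and in how the
family of tests is calibrated.

## Single-SNP models

Genotypes are coded as minor-allele counts. The codominant model uses
heterozygote and rare-homozygote indicators against the
common-homozygote reference; the trend model uses the 0/1/2 dosage.
The trend p-value is the two-sided Wald test on the dosage
coefficient — the Wald interval `exp(b ± 1.96 se)` is reported from
the same fit, so the test and interval are mutually consistent (a
score or LR trend test would not match the printed intervals).
Adjustment is for age (continuous), sex and center in the single-SNP
stage, and for age class (<50, 50–<60, 60–<70, 70+), sex and center in
the haplotype stage: the coarser age coding is conventional in the
haplotype-dosage models, where the dosage columns are themselves
estimated quantities and a saturated age term buys nothing.

Missing genotypes and covariates are handled by listwise deletion: at
the ~2% missingness these designs exhibit, the complete-case loss per
SNP is small, and no imputation model is assumed.

Aliased design columns are dropped with a warning (rank detection via
the weighted QR); complete separation is reported as non-convergence
with the affected estimates set to `NA` rather than as a huge odds
ratio. Where centers are known the adjustment stratum is center, not
country; `covariates=` makes this explicit everywhere rather than
hiding a switch.

## Within-gene FDR and the min-P test

Per-SNP trend p-values are Benjamini-Hochberg adjusted **within each
gene region** by default: each gene's tag set is the natural family in
a candidate-gene design, and the gene-level claim is then made by the
min-P test, which is FDR-adjusted **across genes**. A study-wide
switch (`withinGene = FALSE`) is provided.

The min-P statistic is the minimum trend p over a gene's SNPs. Its
null distribution cannot be read off a chi-square table because the
SNPs are correlated through LD; instead, case/control labels are
permuted while genotypes and covariates stay attached to subjects, and
the minimum is recomputed with the identical procedure. Permutation is
stratified by center, preserving each center's case count — this
respects the frequency-matched design, under which exchangeability
holds within, not across, matching strata. The empirical p-value is
`(count + 1) / (B + 1)`, which is never zero and is exact under
exchangeability. B defaults to 9,999 for reporting and 999 inside the
test-suite experiments; seeds are explicit arguments everywhere, and
the permutation stream is private (caller RNG state is restored).

Labels, not residuals, are permuted: with a binary outcome and modest
covariate effects, label permutation within matching strata is the
standard and simplest exchangeable scheme; permutation of
covariate-adjusted score residuals is deliberately out of scope.

## EM haplotype reconstruction

For a window of m ≤ 8 SNPs, each subject's unphased genotype is
compatible with `2^(h-1)` haplotype pairs (h = number of heterozygous
sites). The EM scheme is the classic one: the E-step distributes each
subject over its compatible pairs with posterior probability
proportional to `f(h1) f(h2)` (doubled for heterozygous pairs,
reflecting the two orderings), and the M-step sets each haplotype
frequency to its expected count over 2n chromosomes.

Numerical choices:

* **Initialization** is the linkage-equilibrium product of single-SNP
  allele frequencies — deterministic, so results are reproducible
  without a seed. The likelihood is concave in the cases that matter
  at these window widths; a brute-force maximization over the
  frequency simplex (grid + polish) is used as the oracle in the test
  suite and agrees to 1e-6 on two-SNP windows.
* **Convergence** when the log-likelihood improves by less than 1e-8
  (cap 500 iterations). The log-likelihood is asserted non-decreasing
  at every iteration; a decrease is a hard error, not a warning,
  because it can only mean an implementation bug.
* **Cleanup**: haplotypes ending below frequency 1e-6 are dropped and
  the remainder renormalized, except where a dropped haplotype is the
  only explanation of some observed genotype.
* Subjects with any missing genotype in the window are excluded.
  Marginalizing over the missing allele is possible in principle but
  adds an enumeration dimension for ≤3% of subjects; the exclusion
  policy is stated on the function and applied identically everywhere.

Pairwise LD r² is computed from the two-locus EM solution among
controls (`r² = D² / (pA qA pB qB)`, `D = f11 − pA pB`), controls being
the sample that approximates the source population.

## Haplotype odds ratios by posterior dosage

Phase posteriors are estimated once, on the pooled case + control
sample, *blind to phenotype*, and each subject's expected copy number
of each haplotype (a dosage in [0, 2]; rows sum to 2 exactly) enters
the logistic model. This two-stage expectation substitution is
deterministic and keeps frequency estimation separate from association
testing. An optional refinement mode re-weights the posteriors by the
fitted disease model and alternates with the GLM until coefficients
move less than 1e-6; it is off by default because the two-stage
estimate is the documented, reproducible behavior and the refinement
changes nothing when phase is nearly certain.

The most frequent haplotype is the reference; haplotypes below the 5%
pooling threshold are summed into one "Rare" column (if the reference
itself fell under the threshold the configuration is rejected — that
signals a threshold set too high for the window). The global test is
the Wald chi-square of all haplotype coefficients jointly. Reported
case/control haplotype frequency columns are posterior expected counts
split by group — the alternative (separate EMs per group) answers a
different question (group-specific frequency estimates) and would
decouple the frequencies from the model actually fitted.

## Haplowalk, blocks, strata

The haplowalk slides a 3-SNP window along each gene, records the
global Wald p per window, and BH-adjusts within gene (window families
are per-gene for the same reason SNP families are); windows with
adjusted p < 0.1 flag a region of interest. Block choice is *not*
automated: the scan output plus the control LD matrix are the
analyst's inputs, and blocks are named in the configuration. This
mirrors how such analyses are actually conducted and keeps an
irreducibly judgment-laden step out of the code path.

For stratified analyses the haplotype dictionary, reference and
pooling are frozen from the full-sample EM so that every stratum
reports the same rows, then the dosage GLM is refit per stratum
(strata with fewer than 25 cases or 25 controls are reported NA —
below that the Wald machinery is not trustworthy). The per-haplotype
interaction test is a likelihood-ratio test on the full sample
comparing models with and without that haplotype's dosage-by-stratum
products, stratum coded **categorically** (df = strata − 1): an
ordinal trend in the stratum would claim a dose-response the design
does not support, though the machinery accepts any coding via the
design matrix. Single-SNP stratified rows default to trend coding
with a dominant-coding switch.

Country heterogeneity uses the analogous LRT with genotype-by-country
products; countries contributing no contrast have their products
dropped by the aliasing rules with the df reduced accordingly.

## The synthetic cohort generator

The generator exists so that every stage is testable end to end. It
emulates:

* 777 cases / 1,035 controls across 7 centers in 4 countries with the
  genotyped-control center margins; age ~ N(59, 10.2) truncated to
  20–79; 62.6% male; BMI, smoking, hypertension and family-history
  margins from the genotyped controls.
* 13 gene regions, 163 tag SNPs. Two regions embed published block
  structure: a 6-SNP region whose middle 4 SNPs carry haplotypes
  G-C-G-G (43.8%), A-C-C-C (6.4%), G-C-C-G (21.0%), G-T-C-G (24.2%)
  plus rare remainder, and an 8-SNP region embedding a 5-SNP block at
  its published frequencies. The remaining 11 regions get synthetic
  pools: founder haplotypes with Dirichlet-like weights, alleles
  flipped deterministically until every SNP's pool-implied MAF is at
  least 5%. Gene sizes for the regions without published SNP counts
  were fixed once at realistic values (4–25 tags) summing to 163.
* All LD arises from the haplotype pools (random mating of pool
  draws); there is no recombination model, because the analysis only
  ever looks within gene blocks.
* Disease: `logit P = α + ln(1.37)·copies(A-C-C-C) +
  [ln(1.9) − ln(1.37)]·copies·1(low vegetable tertile) + small age/sex
  /vegetable terms`, with α calibrated numerically to a 6% population
  prevalence. Cases are collected by rejection; controls are selected
  from the non-case pool frequency-matched to the realized case
  distribution over age-class × sex × center cells, approximating the
  matched design. The "low tertile" of the generative interaction is
  defined by a fixed score cut (≤ 6 on the discrete intake score) so
  the generator does not depend on the analysis-side tertile
  derivation; the analysis recomputes tertiles from controls, and the
  two agree closely but not perfectly — which is faithful to how an
  interaction in nature would relate to an analyst's strata.
* 2% missingness, completely at random; one seed fixes the entire
  stream, and the generator restores the caller's RNG state.

What it does **not** emulate: genotyping batch effects, informative
missingness, within-country population substructure, correlated
lifestyle covariates, recall-biased diet measurement, or
hospital-control selection effects. Passing tests on this generator
therefore demonstrate statistical correctness of the machinery under
the stated model, not robustness to those artifacts. The intake score
itself is synthetic (a rounded gamma frequency score): the real
instrument is a food-frequency questionnaire whose weighting is not
reconstructable from summary tables.

## Experiment sizes in the test suite

Simulation experiments in the tests use sizes chosen to make their
statistical claims sharp while keeping the suite fast to run:

* min-P calibration: 500 single-SNP genes, B = 999, on a 100/100 null
  cohort — the uniformity of the empirical p and the type-I error
  bracket [0.03, 0.07] at α = 0.05 are sample-size-free claims, so
  the small cohort only makes the per-SNP asymptotics slightly
  coarser, which the Kolmogorov-Smirnov check would expose.
* Planted-OR recovery: 200 replicates at full study scale
  (777/1,035), since CI coverage of OR 1.37 at a 6.4% haplotype is
  precisely a study-scale property; the stratified low/high pattern
  uses 100 replicates.
* Other calibration checks (interaction LRT, country LRT, null
  windows) use 150–300 replicates at n = 300–400.

## Known limitations

* Windows are capped at 8 SNPs; no partition-ligation EM for longer
  ranges, no Bayesian phasing, no haplo-score-style score tests.
* No conditional logistic regression (the matching is frequency
  matching, handled by covariate adjustment and stratified
  permutation, not 1:1 matching) and no Firth correction — sparse
  strata are reported NA instead.
* The FDR families (within-gene) are a design decision with a
  study-wide switch; neither choice dominates in general.
* Duplicate-concordance QC requires the duplicate pair list; the
  generator does not fabricate duplicate genotyping runs.
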