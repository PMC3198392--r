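# SnpHapScan

Multi-stage candidate-gene association analysis for unmatched
case-control studies of tag SNPs grouped into gene regions — the kind of
design used in hospital-based molecular-epidemiology studies where a
modest number of genes (here, folate/one-carbon-metabolism and
glutathione-synthesis genes in a renal cell carcinoma study population)
are covered densely by tag SNPs and screened in stages, with diet
interaction as the final exploratory layer.

## What it computes

Given a genotype matrix *G* (subjects × SNPs, minor-allele counts
0/1/2 with missing calls), subject covariates, and a mapping of SNPs to
gene regions, the package runs the full screening cascade:

1. **Genotype QC** — per-SNP call rate, duplicate concordance,
   Hardy-Weinberg equilibrium in controls (1-df Pearson chi-square of
   observed genotype counts against *p², 2pq, q²*), control MAF; SNPs
   failing thresholds are flagged, not dropped.
2. **Descriptives** — case/control contingency tables with uncorrected
   Pearson chi-square tests, pooled-variance t-tests from summary
   statistics, and control-based tertiles of intake scores.
3. **Single-SNP models** — unconditional logistic regression,
   codominant (het/hom indicators) and additive trend (0/1/2 dosage)
   models adjusted for age, sex and center:
   `logit P(case) = β₀ + β·g + γ'z`, OR = exp(β) with Wald 95% CI;
   Benjamini-Hochberg FDR within each gene.
4. **Gene-level min-P permutation tests** — the gene statistic is
   min over its SNPs of the trend p; calibrated by shuffling
   case/control labels within study-center strata, which respects the
   LD correlation between SNPs; empirical p = (count + 1)/(B + 1).
5. **Haplotype engine** — maximum-likelihood haplotype frequencies
   from unphased genotypes via the classic EM scheme (phase-pair
   posteriors ∝ f(h₁)f(h₂), doubled for heterozygous pairs);
   haplotype odds ratios from logistic models on posterior-expected
   dosages with the most frequent haplotype as reference and
   haplotypes under 5% pooled as "rare"; pairwise LD r² from two-locus
   haplotype frequencies in controls.
6. **Haplowalk** — sliding 3-SNP-window haplotype scan per gene with
   window-level FDR < 0.1 flagging regions of interest; analyst-named
   block analysis; stratified effects by vegetable/alcohol tertile with
   per-haplotype interaction LRTs; country-heterogeneity LRTs.

A synthetic-cohort generator (`defaultStudyConfig()`,
`simulateCohort()`) emulates the study's structure — 777 cases / 1,035
controls across 7 centers in 4 countries, 13 gene regions totalling
163 tag SNPs with block-wise LD induced by haplotype pools, a 4-SNP
risk haplotype at 6.4% control frequency with per-copy OR 1.37
(amplified to ≈1.9 in the lowest vegetable tertile), 2% missing
genotype calls — so the whole pipeline is testable end to end without
subject-level data.

## Worked example

```r
library(SnpHapScan)

cfg <- defaultStudyConfig()           # the emulated study conditions
sim <- simulateCohort(cfg, seed = 1)  # SnpCohort + truth record
x   <- assignTertiles(sim$cohort)     # control-based intake tertiles

x
#> SnpCohort: 163 SNPs x 1812 subjects
#>   genes: 13  | cases: 777  controls: 1035
#>   overall call rate: 0.9803

block <- c("rs12483553", "rs2838950", "rs2838951", "rs17004785")
blockAnalysis(x, block)
#> Haplotype association, window 5' - rs12483553, rs2838950, rs2838951, rs17004785 - 3'
#>   reference: G-C-G-G | adjusted for: ageClass+sex+center
#>    G-C-G-G           42.4% /  43.1%  1.00 (ref)
#>    G-C-C-G           20.4% /  20.3%  1.02 (0.84-1.23) p=0.86
#>    G-T-C-G           24.2% /  25.6%  0.96 (0.81-1.15) p=0.691
#>    A-C-C-C            9.3% /   6.8%  1.39 (1.06-1.81) p=0.0168
#>    Rare               3.8% /   4.1%  0.95 (0.65-1.40) p=0.812
#>   global Wald chi2 = 7.086, df = 4, p = 0.131
```

The planted A-C-C-C haplotype (population frequency 6.4%, true
per-copy OR 1.37 rising to ≈1.9 under low vegetable intake) is
recovered at OR 1.39 (95% CI 1.06–1.81) in this replicate — its case
frequency is pushed up to 9.3% against 6.8% in controls — while the
other haplotypes sit at the null, as constructed. The gene-level
permutation test and the stratified analysis continue the cascade:

```r
minPTest(x, "SLC19A1", B = 999, seed = 2)
#> min-P test for SLC19A1 (6 SNPs): observed min p = 0.008125,
#>   empirical p = 0.053 (B = 999, seed = 2)

stratifiedBlocks(x, block, stratifyBy = "vegetableTertile")
#> ... A-C-C-C: low tertile OR 1.80 (1.16-2.79),
#>     medium 1.19 (0.73-1.94), high 1.31 (0.80-2.14);
#>     interaction LRT p = 0.61 (power-limited, as expected
#>     for a 6% haplotype at this sample size) ...
```

A YAML-configured end-to-end run (QC → descriptives → single-SNP →
min-P → haplowalk → blocks → stratified, with tab-separated reports
and a run manifest) is available as `runPipeline()` or from a shell via
the `inst/scripts/snphapscan` wrapper
(`snphapscan run-all --config cfg.yaml --seed 1`).

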