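# enhmeth

Integrative analysis of enhancer DNA methylation in paired tumor/non-tumor
cohorts.

## What problem this solves

Enhancers are distal cis-regulatory elements whose DNA methylation is
remodelled in cancer: tumor-specific enhancer *hypomethylation* can switch
on enhancer RNA (eRNA) transcription, up-regulate target oncogenes, and
mark patients with poorer outcome. Analysing this requires several
coordinated stages — region-level differential methylation from
capture-style coverage, single-base differential methylation at enhancers,
enrichment statistics over genomic annotations, methylation–expression
screening, histone-mark chromatin classification, and survival
stratification. `enhmeth` packages these stages as small, contract-tested
functions for computational biologists working with processed methylome,
expression, ChIP-signal and follow-up tables, plus a synthetic-cohort
generator with a recorded truth table so the entire pipeline can be
validated without any external data.

## The statistics at the core

* **Paired DMR calling.** Per region, a paired two-sided Wilcoxon
  signed-rank test of normalized (log2 CPM) tumor vs matched non-tumor
  coverage, Bonferroni-controlled over testable regions (default adjusted
  *p* < 0.1), with hypo/hyper classification by the sign of the mean
  paired difference.
* **Element enrichment.** For class *i*:
  score = (*Lm*ᵢ/*Lm*) / (*L*ᵢ/*L*), with *Lm*ᵢ the DMR length overlapping
  class *i*, *Lm* total DMR length, *L*ᵢ the class length and *L* the
  total annotated length, all on merged interval unions.
* **DME calling.** An enhancer is differentially methylated when ≥ 10
  shared, coverage-qualified CpGs have |mean(tumor β − reference β)| ≥ 0.1.
* **Inverse screening.** Candidate enhancer–gene pairs are kept at
  eRNA–mRNA Pearson *r* ≥ 0.3; paired DMEs are emitted when per-sample
  enhancer methylation correlates negatively with target mRNA (one-sided
  *p* < 0.05).
* **Chromatin.** Active enhancers: H3K27ac ≥ 2× background, H3K4me1/H3K4me3
  ≥ 2, H3K27me3 < 1.5× background. Signal change: loss < ½×, gain > 2×
  (pseudocount 1). Promoter vs enhancer: midpoint within ±2 kb of a TSS.
  Yates-corrected chi-square for the 2×2 change table. ROSE-style
  super-enhancers: 12.5-kb stitching, TSS exclusion, slope-1 cutoff on the
  scaled rank–signal curve.
* **Survival.** Kaplan–Meier curves and the Mantel–Cox log-rank test
  between strong/weak hypomethylation strata (median split of tumor minus
  non-tumor methylation), with the O/E hazard ratio
  (O₁/E₁)/(O₂/E₂).

## Worked example

Generate a 33-pair cohort with planted effects, call DMEs against the
pooled normal reference, screen for inverse methylation–expression
coupling, and stratify survival:

```r
library(enhmeth)

cfg <- effect_config(seed = 42L, n_pairs = 33L, n_genes = 20L,
                     n_enhancers = 80L, frac_dm_regions = 0.25)
cohort <- simulate_cohort(cfg)
enh <- cohort$annotation[cohort$annotation$element_class == "enhancer"]

dmes <- call_dmes(cohort$methylomes$tumor[1:3], cohort$methylomes$normal,
                  enh)
dme_direction_summary(dmes)
#>  n_hypo n_hyper
#>      18       1
head(dmes[, c("enhancer", "n_cpgs_used", "mean_delta", "direction")], 3)
#>   enhancer n_cpgs_used mean_delta direction
#> 1 enh_0014          19 -0.1829324      hypo
#> 2 enh_0019          15 -0.1861993      hypo
#> 3 enh_0021          16 -0.1531133      hypo
```

Of the 80 enhancers, 19 are called differentially methylated, 18 of them
hypomethylated with mean beta drops near the planted 0.15. Screening
against expression and ranking candidate targets:

```r
targets <- setNames(cohort$truth$target_gene, cohort$truth$region)
pairs <- pair_enhancers_to_genes(cohort$expression$erna,
                                 cohort$expression$mrna,
                                 data.frame(enhancer = names(targets),
                                            gene = unname(targets)))
hits <- screen_inverse_dmes(dmes, cohort$enh_meth,
                            cohort$expression$mrna, pairs)
head(rank_targets(hits), 3)
#>       gene n_dmes max_abs_r
#> 1 gene_015      2 0.8678313
#> 2 gene_011      2 0.8650118
#> 3 gene_006      2 0.8561085
```

18 DMEs show significant inverse methylation–expression coupling; the top
targets are supported by two enhancers each with eRNA–mRNA correlations
near the planted 0.86. Finally, outcome by hypomethylation stratum:

```r
sv <- cohort$survival_os
lr <- logrank_test(sv$time, sv$event, sv$stratum)
sprintf("log-rank chi-square = %.2f, p = %.2e, HR = %.2f",
        lr$statistic, lr$p_value, lr$hazard_ratio)
#> "log-rank chi-square = 4.95, p = 2.60e-02, HR = 2.41"
```

The strong-hypomethylation half of this small cohort has significantly
worse overall survival. The full pipeline, with per-stage outputs and a
checksummed manifest, runs as `run_pipeline(pipeline_config(...))` or from
the shell via `Rscript scripts/pipeline.R run config.yaml`.

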