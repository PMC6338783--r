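---
title: "Methods: integrative enhancer-methylome analysis with enhmeth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrative enhancer-methylome analysis with enhmeth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The scientific problem

Transcriptional enhancers are distal cis-regulatory elements whose DNA
methylation state is remodelled in many cancers. In paired tumor/non-tumor
designs, loss of enhancer methylation (hypomethylation) is frequently
coupled to increased enhancer RNA (eRNA) transcription and up-regulation of
target oncogenes, and the depth of tumor-specific hypomethylation at a
recurrent enhancer can stratify patient outcome. `enhmeth` implements the
computational backbone of such an analysis as small, testable stages:

1. paired differential-methylation calling over fixed regions from
   capture-style coverage (`call_dmrs`),
2. a length-based enrichment statistic of DMRs in annotated functional
   elements (`enrichment`),
3. single-base differentially methylated enhancer (DME) calling from
   per-CpG betas against a reference methylome (`call_dmes`),
4. enhancer--target pairing by eRNA--mRNA correlation and screening of DMEs
   for inverse methylation--expression coupling (`pair_enhancers_to_genes`,
   `screen_inverse_dmes`, `rank_targets`),
5. active-enhancer classification, signal-change classification,
   super-enhancer calling and a TF/BRD4 codepletion report from
   histone-mark signal (`classify_active_enhancer`, `call_super_enhancers`,
   `codepletion_and_expression`),
6. bench-assay quantification (`pyro_methylation_percent`,
   `ddct_fold_change`) and the shared statistical tests,
7. Kaplan--Meier survival stratification by relative enhancer
   hypomethylation (`stratify_by_hypomethylation`, `logrank_test`).

Every stage is exercisable on a bundled synthetic-cohort generator
(`simulate_cohort`) whose planted effects are recorded in a truth table, so
the whole pipeline is testable without any external download.

# Models and procedures

## Paired DMR calling from coverage signal

Capture-based methylation assays yield coverage-style signal per region
rather than single-base betas. Columns are depth-normalized to
counts-per-million and log2-transformed (`normalize_coverage`), then each
region is tested with a paired two-sided Wilcoxon signed-rank test of tumor
versus matched non-tumor values across patients. The signed-rank family was
chosen because it is rank-based and therefore robust to the heavy-tailed
coverage outliers typical of capture data. P-values are Bonferroni-adjusted
over the number of *testable* regions (regions whose paired differences are
all exactly zero are untestable and excluded from the family; the family
size is recorded in the output). The default cutoff is an adjusted p below
0.1, and calls are classified hypo- or hypermethylated by the sign of the
mean paired difference.

The signed-rank p-value uses exact enumeration of all 2^n sign assignments
for n <= 12 non-zero differences and a normal approximation with
continuity and tie corrections above that, which is where a 33-pair cohort
operates.

## Enrichment of DMRs in functional elements

For element class $i$, the enrichment score is

$$\mathrm{score}_i \;=\; \frac{Lm_i / Lm}{L_i / L},$$

where $Lm_i$ is the total length of DMRs overlapping class-$i$ elements,
$Lm$ the total DMR length, $L_i$ the total class-$i$ length and $L$ the
total length of all annotated elements combined. All lengths are computed
on merged interval unions so duplicated annotations cannot double count.
Each class is scored against the full DMR set independently: a DMR base
under two overlapping classes counts toward both, since the statistic is a
per-class length ratio, not a partition. Two exact identities pin the
implementation down and are enforced in tests: when classes partition the
annotation and all DMR bases lie inside it,
$\sum_i (L_i/L)\,\mathrm{score}_i = 1$; and the score is invariant to
splitting any interval into adjacent same-class pieces. Whether $L$
includes intergenic filler is configurable (`total_annotated`); the default
is the merged union of the annotation actually supplied.

## DME calling from per-CpG betas

An enhancer is a DME when, over CpGs covered by at least `min_coverage`
reads (default 5) in both the tumor and the reference profile, at least
`min_cpgs` (default 10) shared CpGs exist and the absolute mean of per-CpG
beta differences is at least `min_delta` (default 0.1). We read the
"average beta change over >= 10 CpGs" rule as a threshold on the *mean*
delta, not as requiring every individual CpG to change by 0.1: the per-site
reading is far stricter and would call almost nothing at realistic noise;
it remains available behind `per_site_rule = TRUE` for auditability.
Multi-sample tumor or reference inputs are pooled per CpG before the
comparison (betas averaged, coverages summed), matching the usual practice
of comparing a small tumor panel against a pooled normal reference.
Coordinates follow the BED convention throughout: a CpG at an interval's
start is inside it, one at its end is not.

## Enhancer--target screening

Candidate (enhancer, gene) pairs -- in the bundled pipeline, nearest-gene
candidates; in general any distance-windowed candidate list -- are kept
when the Pearson correlation of eRNA and mRNA across samples reaches
`r_min` (default 0.3). Paired DMEs are then screened for inverse coupling:
the Pearson correlation between per-sample mean enhancer methylation and
target mRNA over the pooled tumor + non-tumor samples must be negative
with a one-sided p below `alpha` (default 0.05). The inverse direction is
prespecified -- hypomethylation with target up-regulation and
hypermethylation with down-regulation both manifest as negative
methylation--expression correlation -- so a one-sided test is the natural
choice and makes the null emission rate equal `alpha` exactly, a property
the acceptance suite verifies. Genes are ranked by the number of distinct
supporting DMEs, then by the largest absolute eRNA--mRNA correlation, with
lexicographic tie-breaks for determinism.

## Chromatin state and super-enhancers

An active enhancer shows H3K27ac enrichment over local background of at
least 2-fold, an H3K4me1/H3K4me3 ratio (with pseudocount 1) of at least
2, and H3K27me3 below 1.5-fold background. These three thresholds are
calibrated on the generator and exposed as arguments; the *shape* of the
signature (acetylation high, me1/me3 ratio high, repressive mark low) is
the substantive claim, not the particular constants.

Cross-condition signal change uses the ratio (perturbed + 1)/(baseline +
1): strictly below 1/2 is loss, strictly above 2 is gain, values exactly at
a threshold are stable. The pseudocount of one signal unit stabilizes
ratios at near-zero background. Promoter/enhancer assignment is by region
midpoint within an inclusive 2-kb window of the nearest TSS, and the 2x2
promoter-vs-enhancer change table is tested with the Yates-corrected
chi-square statistic
$N(|ad-bc| - N/2)^2/(m_1 m_2 n_1 n_2)$, clamped to zero when
$|ad-bc| \le N/2$.

Super-enhancers are called in the ROSE style, implemented from its
published description: promoter-proximal peaks (within 2 kb of a TSS) are
removed, remaining peaks within 12.5 kb are stitched, background-subtracted
signal is summed per stitched region, and regions are ranked with rank and
signal rescaled to [0, 1]. Scanning from the low-signal end, the first
point where the discrete slope of the scaled curve exceeds 1 (the slope-1
tangent of the hockey stick) is the cutoff; regions past it are
super-enhancers. With an all-equal signal profile the scaled curve is the
diagonal and nothing is called. All constants are configurable.

The codepletion report flags regions where *both* the transcription factor
and BRD4 are classified "loss" between conditions, sub-groups them by
H3K27ac loss, attaches each region's nearest gene (midpoint-to-TSS,
lowest-coordinate tie-break) with its expression log2 fold change, and
compares the with-loss and without-loss groups with a two-sided Wilcoxon
rank-sum test. A separate summary, `frac_reduced`, reports the fraction of
regions with log2(perturbed/baseline) < 0 for both factors -- a laxer
"reduced co-occupancy" reading used for cohort-level summaries.

## Bench-assay quantification

Pyrosequencing percent methylation is the proportion $100\,M/(M+U)$ per
CpG; the raw $M/U$ ratio reading (which can exceed 100%) is available
behind `mode = "ratio"` purely for auditability. Non-CpG cytosine signal
above tolerance flags incomplete bisulfite conversion. Relative expression
uses the 2^-ddCt method against an internal-control gene and the mean dCt
of a designated reference group; folds are invariant under any common
additive Ct shift, a property tested with a thousand random shifts.
Technical replicates are transformed per replicate and then averaged.

## Survival stratification

Patients are ranked by relative methylation (tumor minus matched non-tumor,
most negative first); the lower half is the strong-hypomethylation stratum,
the median patient of an odd cohort goes to the weak stratum, and exact
ties follow stable input order. Curves are Kaplan--Meier product-limit
estimates and strata are compared with the Mantel--Cox log-rank test; the
hazard ratio is the observed/expected estimator
$(O_1/E_1)/(O_2/E_2)$ from the log-rank tabulation, matching a
KM/log-rank-only analysis (no Cox regression, which is out of scope).
The O/E estimator is known to attenuate large hazard ratios relative to
the true value, increasingly so under censoring; the simulation band used
in the acceptance suite (median estimate within [3.0, 6.0] at a planted
ratio of 4.404, n = 48) reflects that property rather than estimator
error. Overall and disease-free endpoints are handled as two event columns
over the same patients, computed independently.

# The synthetic-cohort generator

`effect_config()` fixes the study conditions: 33 tumor/non-tumor pairs; a
minority (default 10%) of enhancers differentially methylated, 95.5% of
them hypomethylated; non-tumor enhancer baseline beta 0.55 with planted
hypo tumors near 0.40 (delta 0.15) and promoters near 0.02; mean coverage
17.6 reads per CpG; methylation--eRNA coupling -0.8 and eRNA--mRNA
coupling +0.86; planted hazard ratios 4.404 (overall) and 3.809
(disease-free) for the strong- versus weak-hypomethylation stratum.

Per-CpG betas are drawn logit-normally around the element baseline (the
logit-scale SD is the configured beta-scale SD divided by the local
binomial variance factor, a delta-method calibration) and then observed
through binomial sampling of methylated reads at Poisson-distributed
coverage -- reproducing both biological and read-sampling variance, which
is exactly what the >= 10-CpG averaging rule must tolerate. Setting
`beta_noise_sd = 0` disables both noise sources, giving the noise-free
regime in which the DME caller must achieve precision and recall of
exactly 1. The planted shift is applied uniformly to every tumor so the
configured delta is the true mean effect.

Coverage-style region signal is Poisson around log-normal per-region
levels with per-sample depth factors in (0.7, 1.3); planted DMRs shift
tumor columns by 0.75 on the log2 scale (3 noise SDs at the default 0.25),
63% of them downward, mirroring the roughly two-thirds hypomethylated
split the analysis expects at cohort scale.

Expression is generated so the *population* correlation between enhancer
methylation and eRNA equals the configured coupling, and target mRNA is
driven by the eRNA of its primary enhancer (planted enhancers take
priority, so planted DME--target pairs are the coupled ones). The eRNA
models a sense-strand, unidirectional transcript; antisense signal is
treated as background and not represented.

Histone tracks give active enhancers ~6-fold H3K27ac and ~4-fold H3K4me1
over a log-normal local background with low H3K4me3 and H3K27me3, and
promoters high H3K4me3. In the perturbed (knockout) condition 84.2% of
factor binding sites lose >= 50% of both TF and BRD4 signal; 60% of those
additionally lose H3K27ac, which puts the overall fraction of enhancers
losing H3K27ac near 30%. Unaffected sites keep their occupancy centered on
no change. Two clusters of five adjacent enhancers are boosted to >= 10x
median signal as planted super-enhancers. Genes nearest to
K27ac-loss codepleted enhancers receive planted negative expression fold
changes (log2 FC around -1.2) against a null of mean zero.

Survival times are exponential with the baseline hazard (0.02/month)
multiplied by the configured ratio for the strong-hypomethylation half,
under independent uniform censoring on (0, 120) months.

**What the generator does not emulate.** Real MBDCap/WGBS data carry
fragment-level autocorrelation, CpG-density--dependent coverage, bisulfite
conversion error, copy-number and purity artefacts, and cell-type
heterogeneity; expression has library-size and batch structure; ChIP
signal has peak-shape and mappability structure. None of these are
modelled. Passing tests therefore demonstrate correctness of the
*algorithms and their contracts* under the stated statistical structure,
not robustness to every artefact of real cohorts.

# Numerical choices and edge cases

* Coordinates are 0-based half-open (BED) at every interface; browser-style
  1-based inclusive input is converted with an explicit `one_based` flag.
  Internally intervals are held as 1-based closed `GRanges`, and the
  read/write cycle round-trips BED coordinates bit-exactly.
* Nearest-gene ties break toward the lower TSS coordinate; stratification
  ties follow stable input order; ranked-target ties end lexicographically.
  Every tie rule is deterministic and order-independent.
* Regions with all-zero paired differences are untestable, skipped, and
  excluded from the Bonferroni family.
* An absent element class yields an undefined-score sentinel (`NA`), never
  zero; zero total DMR length is an error.
* Degenerate noise-free paired t-tests return an overflow-safe infinite
  statistic with p = 0; constant vectors are refused by the correlation
  test; a cohort with no events is refused by the log-rank test.
* Pipeline outputs are pure functions of (config, seed); the manifest
  records seed, thresholds, row counts and md5 checksums, and contains no
  timestamps, so identical runs are byte-identical.

# Problem sizes used in the checks

The bundled verification uses cohorts sized to exercise every code path at
desk scale: 100-region null cohorts across 200 seeds and 1000-region
cohorts with 50 planted shifts across 20 seeds for the DMR caller;
200-enhancer annotations across 20 seeds (plus one noise-free cohort) for
the DME caller; 50 planted and 500 null enhancer--gene pairs at 66 pooled
samples for the screen; 100 stitched regions with 10 planted
super-enhancers; 200 simulated 48-patient cohorts for the hazard-ratio
distribution; and an 808-sample panel for the eRNA--mRNA coupling. The
headline recomputation script scales the DME stage to 2980 enhancers with
894 planted effects to work at the cohort scale the analysis is designed
around.

# Known limitations

* Enhancer--target pairing is direct correlation over the provided
  expression matrices with a candidate window; full multi-tissue
  integrative target inference is deliberately out of scope, so distal or
  indirect targets beyond the candidate list are invisible.
* The DMR stage tests fixed, pre-defined regions; de novo boundary
  segmentation (HMM-style) is not attempted.
* Beta-binomial read-count modelling, smoothing-based DMR detection and
  non-CpG methylation are out of scope.
* The O/E hazard-ratio estimator attenuates strong effects; it is reported
  because it matches the KM/log-rank analysis style, not because it is the
  most efficient estimator.
* Distances are strand-agnostic throughout; no strand-aware "downstream"
  semantics are applied.
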