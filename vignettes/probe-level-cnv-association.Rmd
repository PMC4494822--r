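---
title: "Probe-level copy-number association scanning: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Probe-level copy-number association scanning: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnvdensity)
```

## The problem and the approach

Percent mammographic density (PD) — the proportion of the mammogram
occupied by dense stromal and epithelial tissue — is a strongly heritable
breast-cancer risk factor, and common SNPs explain only a small part of
that heritability. One candidate source for the remainder is germline copy
number variation (CNV). Most CNV association analyses first call discrete
CNVs per sample, build consensus regions across samples, and then test
those regions against the trait. That pipeline inherits the (notoriously
low) concordance of CNV calling algorithms and the ambiguity of defining
consensus regions.

`cnvdensity` implements the alternative *probe-level* strategy: skip
per-sample calling entirely and carry the association test down to the
raw probe intensities.

1. **Per-probe model.** For each array probe, regress the square root of
   PD on the probe's Log R Ratio (LRR) with age, inverse BMI and
   menopausal status as covariates. For family designs a Gaussian random
   intercept per family is added (maximum likelihood, via `lme4`); for
   unrelated samples an ordinary linear model is used. The probe's
   statistic is the Wald t for the LRR coefficient.
2. **Segmentation of the statistic track.** Circular binary segmentation
   (CBS) is applied to the absolute values |t| per chromosome. Segments
   with at least 3 probes and mean |t| strictly greater than 1 are
   candidate regions.
3. **Expansion.** Each candidate is padded by six times its probe count on
   each side (a 10-probe segment becomes a 130-probe region), clipped at
   chromosome ends, so the permutation machinery can re-find the segment
   wherever it lands under resampling.
4. **Permutation inference.** For each expanded region, the phenotype is
   permuted across samples (covariates travel with their sample), the
   probe models are refit inside the region, CBS is re-run on the
   permuted |t| track, and the best segment's mean |t| is recorded. The
   region's p-value is `(n_exceed + 1) / (B + 1)`, with floor 1/10,001 at
   the default B = 10,000. Discovery significance is p < 1/10,000;
   replication significance is 0.05.
5. **SNP conditioning.** Where a genotyped SNP inside the region is itself
   associated with PD, the analysis is repeated with the most significant
   SNP as an extra fixed covariate in every fit, observed and permuted
   alike. A region whose signal vanishes under adjustment is attributed to
   the SNP, not to copy number.
6. **Forced calling.** In predefined (catalogue-style) regions, each
   sample is assigned the most likely integer copy number 0-4 from a
   Gaussian LRR likelihood and a BAF cluster-mixture likelihood, and a
   deletion-carrier (copy number < 2) contrast is tested against PD with
   the same covariate model.

## Sample quality control

Before any modeling, LRR is median-normalized per genotyping plate
(subtract the plate's pooled median, so every plate's median is 0 — an
idempotent operation), and samples are excluded when any of four metrics
*strictly* exceeds its threshold:

| metric | definition here | threshold |
|---|---|---|
| `lrr_sd` | SD of non-missing autosomal LRR | 0.35 |
| `baf_drift` | fraction of BAF strictly inside (0.2, 0.25) or (0.75, 0.8) | 0.0015 |
| `wave_factor` | SD across 1,000-probe windows of the per-window median LRR | 0.05 |
| `n_cnv_intervals` | maximal runs of 3+ probes whose width-3 running-mean LRR deviates from 0 by more than 0.25 | 500 |

The thresholds are the standard array-QC cutoffs; the metric *formulas*
are this package's own deterministic, desk-scale definitions of the four
conventionally named quantities (production tools compute analogous
summaries from hidden-Markov segmentations). Metric-equal samples are
retained; all violated metrics are listed as exclusion reasons; samples
with fewer than 100 informative probes are excluded outright. Missing
intensities are omitted from every metric rather than imputed, and the
interval count is computed after normalization.

## The CBS implementation

CBS is re-implemented here (C++ core) rather than wrapped, because the
permutation stage needs tens of thousands of segmentations of short
tracks under tight control of tie-breaking and seeding:

* The split statistic for an interval arranged on a circle is the pooled
  two-sample mean-difference statistic between an arc and its complement,
  with the variance estimated once per interval. Arcs that wrap the
  interval end are complements of non-wrapping arcs, so scanning all
  ordered cut pairs covers every circular split and each maps back to at
  most two linear cut points.
* Ties break toward the leftmost start and then the shortest arc, making
  segmentation deterministic given the RNG seed.
* A candidate split is accepted when its within-interval permutation
  p-value is at most alpha = 0.01, estimated from 1,000 shuffles with
  early stopping as soon as rejection is certain. The procedure then
  recurses on the pieces. `min_width = 2` bounds the smallest arc.
* Multiplying a track by any positive constant leaves all change-points
  unchanged (the statistic is scale-equivariant); a constant track yields
  none.

The maximal-split search is verified against an exhaustive all-pairs
search on short random tracks in the test suite.

Two retention rules follow the method's definition — at least 3 probes
and mean |t| strictly above 1 — plus one guard of our own: a retained
segment must also exceed the chromosome-wide mean |t|. Under a null track
mean |t| is about 0.8, uncomfortably close to the threshold of 1, and the
guard prevents a long, flat, slightly-elevated chromosome from qualifying
as one giant segment. Adjacent qualifying segments separated by a short
gap are never merged.

## Permutation details and conventions

* The p-value convention `(n_exceed + 1)/(B + 1)` is the add-one
  convention whose floor reproduces 1/10,001 at B = 10,000; ties between
  a permuted and the observed statistic count as exceedances
  (conservative).
* When a permuted track yields no CBS segment of 3+ probes, the
  whole-region mean |t| is used as that permutation's statistic. This
  fallback is conservative: it can only enlarge permuted statistics
  relative to discarding the iteration.
* Permutation shuffles only the phenotype; covariates stay attached to
  their samples, so the permutation null preserves the covariate
  structure while breaking the phenotype-intensity link. Family
  structure is ignored during permutation (all samples exchangeable),
  matching the default analysis; the observed-statistic fit may still use
  the family random intercept. Two non-default variants are available
  behind flags of `permute_region()`: `permute = "residual"` shuffles the
  covariate-model residuals (preserving the phenotype-covariate
  association under the null), and `within_family = TRUE` restricts
  shuffles to within-family exchanges.
* One seed drives both the phenotype shuffles and the CBS split tests, so
  a region result is bit-reproducible given (inputs, B, seed).

## The synthetic cohort generator

Every quantitative claim in the package's tests is made on synthetic
cohorts with known truth, generated by `simulate_cohort()`:

* **Cohort structure.** Defaults emulate a multigenerational family study
  of density: 89 families of 3-10 women (about 580 samples), age ~
  Normal(57.2, 11.6), BMI ~ Normal(27.1, 5.7) truncated at 15,
  menopausal status = indicator(age > 51) with 5% label noise, 96-well
  plates with Normal(0, 0.05) plate shifts.
* **Intensities.** LRR = copy-number state mean + genomic wave + plate
  shift + Normal(0, 0.15) noise. State means default to
  {0: -3.5, 1: -0.45, 2: 0, 3: +0.4, 4: +0.68} — conventional SNP-array
  cluster positions (the method's sources do not state intensity
  physics, so these are calibration constants, configurable). The wave is
  a per-sample sinusoid in probe index (random phase, amplitude ~ 0.01)
  standing in for GC waves. BAF is drawn from the cluster pattern implied
  by the copy number (uniform at 0 copies; {0,1}, {0,1/2,1},
  {0,1/3,2/3,1}, {0,1/4,1/2,3/4,1} at 1-4 copies) with SD-0.02 cluster
  noise, using a per-probe population allele frequency.
* **Regions.** Embedded CNV regions carry configurable deletion /
  duplication carrier frequencies; deletion carriers split 1-copy :
  0-copy = 2 : 1 and duplications 3 : 4 = 2 : 1, the ratio catalogued for
  common deletion polymorphisms.
* **Phenotype.** sqrt(PD) = 4 + 0.01*age + 20/BMI - 0.3*menopausal +
  gamma*(copies - 2) + family intercept (SD 0.7) + residual (SD 1.3),
  then squared and clamped to [0, 100] (PD is a percentage). These
  constants put PD near mean 26, SD 16 on the sqrt scale's back
  transform, matching a family-study density distribution. Values of
  sqrt(PD) outside [0, 10] trigger a warning and clamping.
* **Seeding.** One master seed drives a derived per-stage seed sequence
  (probe map, family/copy-number assignment, intensities, phenotype), so
  stages are individually reproducible and identical configurations give
  bit-identical cohorts.

The generator intentionally does *not* emulate raw X/Y allele
intensities, genotype-clustering artifacts, GC-content-correlated waves
(only a smooth sinusoid), linkage disequilibrium between background SNPs,
or reader drift in the density measurement over time. Tests passing on
these cohorts therefore demonstrate the *procedure's* statistical
behavior (calibration, power, conditioning logic), not robustness to
every failure mode of real array data.

`simulate_linked_snp()` plants a SNP correlated with a region's carrier
status at a target r² by copy-then-perturb: the carrier indicator is
copied and a fraction 1 - sqrt(r²) of samples are re-drawn from the
marginal, giving expected correlation sqrt(r²); the realized r² is
recorded. `simulate_qc_failures()` constructs samples that violate each
QC metric in isolation; the interval-count violation needs at least
10 x ceil(count/2) probes (alternating ±0.35 blocks of five probes keep
the overall SD and wave factor below their thresholds while creating many
short mean-shift intervals).

## Forced calling model

For a fixed region there is no need for a hidden-Markov traversal: each
sample's copy number is the state maximizing the sum of an independent
Gaussian LRR log-likelihood (state means as above, SD 0.15) and a BAF
mixture log-likelihood (equal-weight Gaussian clusters at the state's
pattern, SD 0.02, with a 1% uniform admixture so off-cluster values stay
finite; 0 copies is uniform). The call score is the log-likelihood margin
over the runner-up state. The calling defaults deliberately match the
simulator's generative parameters, so recovery tests exercise a matched
model — a real cohort's intensities will not match them exactly, and the
parameters are exposed via `cn_model_params()`. The boundary between
hemizygous and homozygous deletion for low-probe regions is decided
entirely by these likelihood defaults.

## Problem sizes used in the shipped experiments

The test suite and `scripts/acceptance.R` run the full machinery at
deliberately desk-sized conditions: cohorts of roughly 150-200 women over
600-2,000 probes, 200 null windows at B = 500 (or 102 windows at B = 200
in the script) for type-I calibration, 50 (script: 20) recovery and
SNP-conditioning replicates at B = 99, and one strong-effect region
permuted at the full B = 10,000 to exhibit the 1/10,001 floor. The
"strong" recovery effect is gamma = 1.5 sqrt-PD units per copy against a
residual SD of 1.3. These sizes were chosen once as the smallest at which
the binomial/KS tolerances of the shipped checks are meaningful.

## Known limitations

* The family model is a single random intercept per family — no kinship
  matrix, no heritability decomposition.
* Probe p-values are Wald-based; the mixed-model degrees of freedom use
  the n - (fixed rank) convention rather than a Satterthwaite correction.
* The permutation machinery refits ordinary models fast (vectorized
  residualization); mixed-model permutation runs probe-by-probe and is
  correspondingly slow — feasible for single regions, not genome-wide.
* Whole-genome CBS cost grows quadratically in chromosome probe count;
  the implementation targets candidate-region workflows and desk-scale
  genomes, not 10^6-probe chromosomes in one pass.
* De novo per-sample CNV discovery, pedigree-aware joint calling and any
  FDR machinery beyond the two fixed significance rules are out of scope.
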