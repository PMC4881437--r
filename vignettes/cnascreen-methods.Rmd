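---
title: "Methods: copy-number screening for metastasis-associated genes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: copy-number screening for metastasis-associated genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Early-stage (stage II) colorectal tumours are mostly cured by surgery, yet
10–30% relapse with distant metastases. Somatic copy-number aberrations
(CNAs) measured by array CGH are a candidate substrate for predicting that
relapse, but tumour genomes carry large numbers of random "passenger"
aberrations, and most recurrent CNAs span hundreds of bystander genes.
`cnascreen` implements a funnel that narrows probe-level log2 ratios down to
a short list of expression-validated candidate genes:

1. **QC and segmentation** — noisy profiles are gated by the derivative
   log-ratio spread (DLRS < 0.5); each profile is segmented and thresholded
   into gain/loss calls.
2. **Recurrence (STAC-style permutation test)** — per chromosome arm and
   direction, the observed stacking frequency of calls across samples is
   calibrated against a null in which every sample's aberrant runs are
   relocated uniformly at random within the arm.
3. **Survival relevance (SPPS)** — samples carrying a recurrent region
   (In-Group) are compared with non-carriers (Out-Group) by log-rank on
   disease-free survival.
4. **Integration and cleansing** — the two maps are intersected; genes in
   the common regions are dropped when their CNA overlaps a catalog of
   copy-number variants common in healthy genomes (≥ 5% of the region).
5. **Expression validation** — in a batch-standardised expression
   meta-cohort, each candidate gets univariate Cox fits for overall and
   disease-free survival; a candidate passes only if a significant
   coefficient's sign is consistent with its CNA direction (loss → negative,
   gain → positive), with a stringent p < 0.005 tier, quartile-based
   co-deletion combination analysis, and clinicopathological associations.
6. **EMT scoring** — a per-sample epithelial–mesenchymal transition score in
   [−1, +1] from single-sample rank-enrichment (ssGSEA) of refined
   epithelial/mesenchymal signatures.

Because the original tumour profiles and the public expression series are
not shipped, a first-class synthetic-data module generates cohorts with
known ground truth, and the published 42-gene candidate table is packaged
as a fixture so the downstream filters can be replayed against real printed
numbers.

# Statistical components

## DLRS

For ordered probes within a chromosome, DLRS is
`IQR(diff(log2)) / (1.349 * sqrt(2))`. For i.i.d. Gaussian probe noise the
consecutive differences have standard deviation σ√2 and IQR/1.349 estimates
their SD, so the statistic estimates σ robustly; segment boundaries
contribute only a handful of outlying differences, which the IQR ignores.
The robust form is deliberate — users wanting the plain `sd/√2` variant can
compute it directly from the same differences.

## Segmentation

The proprietary segmentation algorithm used on the original arrays is not
available; calls here come from recursive binary segmentation minimising
within-segment squared error. A split is accepted when it reduces the SSE by
more than `penalty * sigma^2 * log(n)` (BIC-style; σ estimated as
`mad(diff(x))/√2`, penalty 6 by default). Segment means at or beyond ±0.25
become gain/loss calls (a single-copy change in a diploid is ≈ ±0.58,
attenuated by tumour-cell fraction), and probe-adjacent same-direction calls
merge. The segmenter is pluggable: pre-segmented SEG input (`read_seg()`)
bypasses it entirely, and all downstream statistics consume only the binary
calls, not segmenter internals. On noise-free piecewise-constant input the
σ estimate collapses to 0 and recovery is exact to probe resolution, which
is what the construction tests assert.

## STAC-style permutation calibration

Within each arm and direction, calls are binarised onto a fixed grid
(2 Mb bins by default, last bin short). The statistic per bin is the
stacking frequency f(b). The null preserves each sample's number of
maximal aberrant runs and their lengths, relocating each run independently
and uniformly within the arm (no wraparound; runs of one sample merging
after relocation count once). The p-value uses the arm-wide **maximum**
permuted frequency,

```
p(b) = (1 + #{permutations with max frequency ≥ f(b)}) / (1 + n_perm)
```

making the calibration family-wise across the arm and the p-values valid
(the +1 correction keeps p > 0). Bins with higher f never get a larger p
within an arm. Only the frequency statistic is calibrated; the original
method's footprint statistic is an extension point we did not need.
Regions are maximal bin runs with f ≥ 0.35 and p < 0.05 — the conventional
stringent settings, which are also the defaults throughout. Gains and
losses are tested separately: they are biologically distinct events and a
joint test would let a frequent loss mask a focal gain.

A consequence of the relocation null worth knowing: an aberration spanning
(nearly) the whole arm stacks under any relocation, so its p-value is 1 by
construction. The test has power only for aberrations that are focal
relative to their arm — the synthetic drivers are therefore planted at
roughly a quarter of their arms' lengths.

## Survival statistics

The log-rank test is computed directly from the pooled risk table
(O−E and hypergeometric variance at each distinct event time), so it can
serve as an independent leg of the cross-check against the Cox score test,
which must agree on tie-free two-group data. Cox fits are univariate
proportional-hazards fits via `survival::coxph` with **Efron** handling of
ties — more accurate than Breslow for the heavily tied quartile covariates.
"Mean survival" in SPPS output is the restricted mean survival time up to
the last observed time, the standard definition under censoring. The SPPS
In-Group is defined by same-direction calls covering ≥ 50% of the region
(`min_cover`); the original description ("samples with similar CNA
regions") does not pin this down, so it is an explicit, configurable
parameter.

## Meta-cohort standardisation

Datasets are restricted to shared genes and each gene is standardised to
mean 0, unit variance **within each dataset** before recombination. This
exact location/scale removal replaces empirical-Bayes batch adjustment: all
downstream statistics are rank- or regression-based, so what matters is
that no dataset contributes location or scale artefacts, which the
per-batch z-scoring removes by construction and testably so
(per batch per gene |mean| < 1e−8, |var − 1| < 1e−6).

## The screen and its sign rule

The Cox covariate is continuous standardised expression (one coefficient
per gene and endpoint, consistent with the published table); quartiles are
used only for Kaplan-Meier displays and the combination analysis. A
negative coefficient means higher expression protects, so for a loss-CNA
gene the metastasis-suppressor story requires a **negative** significant
coefficient, and for a gain-CNA gene a positive one. Membership of the
published 42-gene list joined several association types with "or"; the
implemented rule is explicit: primary screen pass (direction-consistent
Cox p < 0.05 on either endpoint) **or** a significant EMT-score Spearman
association. The published list itself is consumed as a fixture, not
re-derived — its exact membership rule is not fully recoverable from the
printed material.

Quartile boundaries are the 25th/50th/75th linear-interpolation quantiles;
boundary ties go to the lower quartile, deterministically. The combination
analysis compares samples with **every** listed gene in its own Q1 against
samples with every gene above Q1, excluding mixtures, by log-rank.

## EMT score

The published procedure initialises sample ordering with a Bayesian probit
meta-gene fit; that step only orders samples for extreme-tail selection, so
it is replaced here by a deterministic rank-enrichment prescore
(mesenchymal minus epithelial ssGSEA enrichment, rank-scaled to [0, 1]).
Signature refinement labels the extreme 25% tails and keeps genes that
(a) beat **all** 1000 label permutations in absolute between-tail mean
difference (empirical q = 0, per gene, following the described permutation
procedure) and (b) reach ROC AUC ≥ 0.85 for tail membership (≤ 0.15 for the
epithelial side). The ssGSEA statistic is the integral (sum over ranks) of
the weighted in-set ECDF minus the out-of-set ECDF, weight exponent 0.25;
the max-deviation KS form is deliberately not used, and exponent 0 gives a
purely rank-based statistic.

The final score min-max normalises each enrichment across the cohort to
[0, 1] and reports `norm(ES_mesenchymal) − norm(ES_epithelial)`, which is
bounded in [−1, +1] and exactly antisymmetric under swapping the two
signatures. The source description says "subtraction of the mesenchymal
from epithelial" while also defining +1 as fully mesenchymal; the sign
convention wins, so the score is M − E. "Normalised subtraction" is not
given as a formula anywhere; min-max is the simplest choice achieving the
stated bounds and is configurable in code.

# The synthetic cohort

`sim_config()` defaults are the study conditions the package is exercised
under:

| parameter | default | rationale |
|---|---|---|
| group sizes | 78 / 11 / 7 | disease-free / metastatic / local-recurrence structure of the emulated cohort |
| probes | 4000, uniform per arm | statistics depend on bins, not array layout |
| arm table | 14 arms, approx. hg19 | chromosomes 1, 7, 8, 13, 14, 17, 18, 20 — the recurrently altered ones in colorectal cancer |
| drivers | 8p loss, 18q loss, 20q gain | classic colorectal regions; focal (~25% of arm) so the relocation null has power |
| penetrance / background | 0.85 / 0.12 | recurrent colorectal CNAs reach 55–80% frequencies; background carriers keep the survival signal realistic in the disease-free group |
| probe noise SD | 0.15 | DLRS ≈ 0.15, comfortably under the 0.5 QC gate |
| segment amplitude | 0.6 | single-copy change attenuated by tumour-cell fraction |
| passenger rate | 3 per sample | 2–20 Mb random aberrations, arms weighted by length |
| DFS hazard | 1/9.5 per year, ×3 per driver | exponential proportional hazards — the simplest model satisfying the log-rank/Cox assumptions being tested |
| censoring | 30% random + 12 y administrative | realistic follow-up |
| expression | 6 tumour batches × 60 + 40 normals, 420 genes | scaled-down meta-cohort; 8 dosage-coupled genes per driver, 25-gene E and M blocks |
| dosage beta | 1.0 | expression shift per copy-state unit |
| EMT shift | 1.2, on a continuous latent axis | metastatic-like samples (30%) sit at the mesenchymal end; 30% reflects a meta-cohort that includes metastatic series |
| batch effects | shift SD 0.5, log-scale SD 0.2 | visible but removable by per-batch standardisation |

What the generator **does not** emulate: FFPE/wave/GC artefacts, probe-level
microarray chemistry, allele-specific copy number, platform probe-to-gene
mapping, or the microsatellite assay (MSI enters only as a label).
Consequently, passing tests demonstrate that the statistical machinery is
correct and well calibrated under its stated model — not that the pipeline
is robust to every artefact of archival clinical material.

Local-recurrence samples are generated and flagged but excluded from
analysis, mirroring the handling of such cases in the emulated study
design. With `hazard_ratio_driver = 1` the generator is an exact null for
the survival stages; with noise and passengers switched off every stage's
output equals the planted truth, which is how the construction tests work.

# Numerical choices and degenerate inputs

- Coordinates are 0-based half-open (BED convention) everywhere; IRanges is
  used internally for interval arithmetic with conversion at the boundary.
- The binary segmentation threshold floor (1e−10) prevents floating-point
  split storms on exactly constant segments; segmentation is idempotent on
  its own fitted means.
- Permutation p-values carry the +1 correction and are therefore never 0.
- A region carried by every sample (or none) cannot be tested by SPPS and
  is skipped with a warning rather than an error.
- Constant covariates, constant genes, empty gene-set intersections, a
  gene set covering all measured genes, and single-sample cohorts are all
  rejected with specific messages.
- The normal-CNV exclusion unions the catalog before measuring overlap (no
  double counting) and applies a strict ≥ 5% rule; the published table
  keeps one gene at 68.65% overlap despite the stated rule, so exceptions
  must go through an explicit whitelist, never silently. By default the
  exclusion applies to both directions although the source text literally
  mentions gains.
- One global seed fans out to per-stage seeds by fixed offsets (+11 gain
  STAC, +12 loss STAC, +13 EMT refinement, +1 expression, +2 CNV catalog),
  so stages can be re-run in isolation and byte-identical artifacts are
  reproducible; the pipeline manifest records parameters, the seed and md5
  hashes of every artifact.

# Problem sizes

The test suite and the acceptance script run the default 96-sample cohort
(4000 probes, 999 STAC permutations), 1000 null datasets for permutation
validity, 2000 replicates for log-rank size, Cox recovery at n = 500, and a
400-sample expression meta-cohort — sizes chosen so the full suite completes
in well under a minute on one core while keeping Monte-Carlo error well
below the tolerances asserted.

# Known limitations

- The within-arm relocation null has no power for aberrations spanning an
  arm; whole-arm events are real biology but need a different null.
- SPPS power at 89 samples is modest; when several independent drivers
  elevate hazard, each driver's Out-Group is contaminated by carriers of
  the others, and a true driver occasionally misses the 0.05 cut. The
  funnel is intersectional, so such a driver drops out entirely.
- Per-batch standardisation removes location/scale batch effects only;
  correlation-structure batch effects (which empirical-Bayes methods also
  do not fully remove) are out of scope.
- The EMT signature refinement assumes the curated starting sets are at
  least weakly informative; with pure-noise input it correctly returns an
  error or near-empty sets rather than inventing a signature.

```{r}
library(cnascreen)
res <- run_pipeline(pipeline_config())
funnel_report(res)
```
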