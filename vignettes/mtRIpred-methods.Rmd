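---
title: "Methods: scoring the proteome for mitochondrial poly(A) RNA interaction"
author: "mtRIpred"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scoring the proteome for mitochondrial poly(A) RNA interaction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtRIpred)
```

# Overview

`mtRIpred` ranks every gene of a proteome by the likelihood that its protein
product interacts with mitochondrial poly(A) RNA. The inputs are (i) label-free
quantification (LFQ) tables from RNA-crosslinking mass-spectrometry
experiments, (ii) per-gene annotation evidence (a mitochondrial-localization
likelihood score, an RNA-binding-domain flag, a co-expression score, a count
of protein-protein interactions with known mtRNA interactors, and four GO
flags), and (iii) a curated positive gene list. The output is a total order
over the gene universe with per-track contributions, plus evaluation
machinery (corrected FDR, ROC/AUC, ten-fold cross-validation).

This vignette explains the model, the parameters that matter, the numerical
choices, what the synthetic-data generator does and does not emulate, and the
known limitations. It states no result that the package's tests or the
acceptance script do not themselves compute.

# From LFQ intensities to the mtRNA-interaction track

LFQ intensities arrive on the linear scale, one column per sample, with
missing values where a protein was not quantified in a run. The processing is
deliberately simple and mirrors standard practice for this kind of screen:

1. **Log2 transform.** All downstream statistics are differences of log2
   intensities.
2. **Missing-value imputation.** Missing cells are set to the lowest log2
   intensity measured anywhere in the matrix (`log2TransformAndImpute()`,
   `floor = "global"`). The rationale is that a missing LFQ value most often
   means the protein sat below the detection limit, so the global detection
   floor is the least-assuming fill-in. Whether such a floor should be global
   or per-sample is genuinely open (sample-to-sample depth varies); we default
   to the global minimum as the simplest reading and expose
   `floor = "per_sample"` for data with strong per-run depth differences.
   Imputed cells are flagged, and a protein with no measured value in an
   approach counts as *not detected* there regardless of its imputed values.
3. **Replicate averaging.** Technical replicates are averaged within each
   biological replicate, then biological-replicate means are averaged
   (`averageReplicates()`, `method = "hierarchical"`). A flat mean over all
   samples is also available; the hierarchical default prevents a biological
   replicate that happens to have more technical replicates from dominating
   the estimate. With equal technical-replicate counts the two are identical.
4. **Fold-changes.** Per approach, the log2 fold-change is the crosslinked
   mean minus the control mean. For the EtBr-treatment approach (WCXL_EtBr)
   the "control" samples are the crosslinked, EtBr-treated ones, so the
   contrast isolates signal that disappears when mitochondrial transcription
   is suppressed.
5. **Enrichment calls.** Proteins detected in an approach with fold-change at
   or above `log2(3)` are called enriched (`classifyEnriched()`). The
   boundary is included by default — descriptions of this threshold vary
   between "above" and "at least" three-fold, and an inclusive boundary is
   the more conservative reading for a screen; it is configurable.
6. **The combined track.** The mtRNA-interaction evidence value of a gene is
   the mean of its MXL and WCXL fold-changes where both approaches detected
   it, the single available value where only one did, and missing where
   neither did (`combineApproaches()`). Using the single available value
   rather than discarding one-sided detections preserves the whole-cell
   approach's role of catching transiently or weakly interacting proteins the
   mitochondrial-isolation approach misses. WCXL_EtBr is computed and
   reported but never enters the combined track; it serves as a
   method-comparison contrast, not as integration evidence.

# The integration model

The integration is a binned naive-Bayes scheme. For each evidence track
$i$ the gene universe is partitioned into bins (plus a mandatory bin for
genes missing from the track), and each bin $b$ receives the weight

$$w_{i,b} = \log_2 \frac{\hat P(\text{bin } b \mid \text{mtRNA})}
                        {\hat P(\text{bin } b \mid \text{non-mtRNA})}
          = \log_2 \frac{\text{frac}^{+}_{i,b}}{\text{frac}^{-}_{i,b}},$$

where the fractions are the proportions of positive and negative training
genes falling in the bin. A gene's score is

$$\text{mtRNAscore}(g) = \log_2 O_{\text{prior}} + \sum_i w_{i,\,b_i(g)},
\qquad O_{\text{prior}} = \frac{n_\text{expected}}{n_\text{genes} - n_\text{expected}}.$$

Assumptions worth being explicit about:

* **Class-conditional independence.** Evidence tracks are treated as
  independent given the class. They are not (localization and co-expression
  correlate, for instance); the practical consequence is over-confident
  scores, not necessarily a worse ranking. The synthetic generator draws
  tracks independently by default, so tests verify correctness *under* the
  model's assumption rather than robustness to its violation.
* **Missingness is evidence.** A gene absent from a crosslinking experiment
  or an annotation resource lands in that track's missing bin, which is
  scored like any other bin. Training genes absent from a track therefore
  inform what absence means.
* **The prior only calibrates.** Since $\log_2 O_{\text{prior}}$ is a
  constant offset, the ranking is invariant to `nExpected`; only the absolute
  scores and the corrected FDR depend on it. This invariance is asserted
  exactly in the tests.

## Pseudo-counts

A bin containing no positive (or no negative) training genes would give an
infinite log ratio. The zero fraction is replaced by
$0.5 / |\text{negatives}|$ — note the *negative-set size in both cases*,
which is the literal form of the rule this pipeline implements; a symmetric
variant ($0.5$ over the own set's size) is available via
`pseudoDenominator = "own"`. With the default 24 positives and 248 negatives
the literal rule makes empty-positive bins slightly less damning than the
symmetric rule would (pseudo-fraction 0.002 instead of 0.021), i.e. it is
mildly conservative toward genes in bins never visited by positives. A bin
containing no training genes at all gets weight exactly 0.

## Binning

Exact bin borders are dataset-specific and belong to the run configuration,
not the method. Defaults (`quantileBinSpec()`): continuous tracks are cut at
interior quantiles into 5 approximately equally populated bins; duplicate
quantiles (zero-inflated tracks such as interaction counts) are collapsed, so
the effective bin count can be lower. Intervals are half-open $[lo, hi)$ with
open-ended outer bins, so every finite value maps to exactly one bin. Logical
tracks get the two flag bins. All resolved borders are written to the run
log, and callers can pass explicit `binSpec()` objects to reproduce a
previous run's borders exactly.

Five bins is a pragmatic default: with 24 positives, finer binning leaves
many bins without positive training genes and pushes the estimates onto the
pseudo-count floor, while coarser binning wastes dynamic range of the
strongly informative tracks.

## Ranking and ties

Genes are ordered by descending score; ties are broken by descending combined
fold-change (genes without one sort last), then lexicographically by gene
identifier, making the ranking a deterministic total order. Two numerical
details:

* Ranking uses the prior-free contribution sum, so tie groups are
  bit-identical across priors.
* Contribution sums are rounded to $10^{-9}$ log2 units before ranking and
  scoring. Differences below that are floating-point summation noise, not
  evidence; treating them as ties lets the fold-change tie-break apply
  deterministically and makes the written ranked table (10-decimal scores)
  round-trip exactly.

# Training sets

The positive set is curated externally (one identifier per line;
`loadPositiveSet()` deduplicates and validates against the universe). The
negative set is rule-built (`buildNegativeSet()`): category 1 is every gene
with the mitochondrion GO term and the TCA-cycle or OXPHOS GO term but
without the RNA-binding GO term — well-studied pathway members unlikely to
moonlight on mtRNA; category 2 is a uniform random sample, of the same size
as category 1, from genes with the RNA-binding GO term but without the
mitochondrion term. Equal sizes give both contaminant classes equal weight in
the likelihood estimates. The sample seed is recorded in the
`TrainingSets` object and every report. GO-DAG propagation is upstream; the
package consumes pre-computed flags. If a curated positive matches the
category-1 rule, the curation wins and the gene is dropped from the
negatives.

# Evaluation

**Cutoff metrics.** At a score cutoff, sensitivity and specificity are
computed on training genes only. The corrected FDR re-weights these rates by
the genome-wide prior odds:

$$\text{cFDR} = \frac{1-\text{spec}}{(1-\text{spec}) +
  \text{sens}\cdot O_{\text{prior}}}.$$

The $O_{\text{prior}}$ here is the *non-log* odds. This is a deliberate
disambiguation: the same symbol is used for the log2 form inside the score,
but only the odds form reproduces both published reference values of the
formula (69% at 300 expected genes and 39% at 1000, both recomputed by the
acceptance script); the log2 form would yield negative "rates". With no
selections (sensitivity 0, specificity 1) the cFDR is defined as 0.
`cutoffForCfdr()` picks the most inclusive rank cutoff whose cFDR stays at or
below a target (default 0.69).

**ROC/AUC.** `rocCurve()` sweeps score thresholds with tie groups handled
jointly and integrates by trapezoid, which equals the Mann-Whitney statistic
with half-credit ties. The tests verify this against an exhaustive
concordant-pair oracle and against `pROC`.

**Cross-validation.** Training genes are partitioned into $k = 10$ seeded
folds, stratified within the positive and within the negative set
(round-robin after a seeded shuffle, so fold sizes differ by at most one per
class; every gene is held out exactly once). Per fold, the bin tables are
re-estimated from the remaining nine-tenths and the full integration and
ranking re-run; the held-out genes' ranks are recorded and pooled into one
ROC. Pooling ranks (rather than averaging per-fold curves) is the natural
choice when each fold contributes only two or three held-out positives. Bin
*borders* are resolved once from the evidence values and kept fixed across
folds: they are part of the model specification and depend only on the
unlabeled value distribution, not on the training labels, so re-deriving them
per fold would change the hypothesis space rather than prevent leakage. The
no-leakage property — a held-out gene's evidence value cannot move its fold's
bin counts — is asserted in the tests.

# The synthetic-data generator

`simulateStudy()` draws a complete study under one seed:

* **Universe and truth.** `n_genes` genes (default 20129, scalable), of which
  `n_true` (default 300) are true mtRNA interactors — all mitochondrial — plus
  two contaminant classes: mitochondrial non-RNA genes (`frac_mito_extra`,
  default 8%) and cytosolic RNA binders (`frac_cyto_rna`, default 8%).
* **LFQ matrices.** Per-gene baseline log2 intensity
  $\mathcal N(25, 2^2)$ — the scale of typical log2 LFQ values; crosslinked
  samples of interactors shifted by `lfq_effect` (default 2.5 log2 units,
  comfortably above the log2(3) ≈ 1.58 enrichment threshold); the whole-cell
  approach applies the shift attenuated by `wcxl_attenuation` (0.6) and adds
  `wcxl_contaminant_shift` (1.5) to cytosolic RNA binders, encoding the
  observed contrast that mitochondrial crosslinking is the more specific
  method; Gaussian noise `lfq_noise_sd` (0.8) per sample; three biological ×
  two technical replicates per condition; per-cell missingness of 0.1 for
  interactors and 0.6 for background genes, then export on the linear scale.
* **Annotation tracks.** Localization score separated by `mitocarta_shift`
  (3) for mitochondrial genes with realistic partial coverage; a
  domain flag at true/false-positive rates 0.6/0.05 for RNA binders (note
  both true interactors *and* cytosolic RNA binders carry domains — the track
  distinguishes positives from only half the negative set, as a domain
  annotation really would); a co-expression score shifted by 1.5 for
  interactors; Poisson interaction counts with means 3 vs 0.3; GO flags equal
  to truth (optionally flipped with `go_noise`), with TCA/OXPHOS flags
  marking exactly `training_neg_size_per_category` (124) mitochondrial
  non-RNA genes so the negative-set rule reproduces the intended sizes.
* **Training sets.** 24 positives sampled from the true interactors;
  negatives built by the same `buildNegativeSet()` the real pipeline uses.

`nullSimConfig()` zeroes every effect and equalizes every class-conditional
rate, for chance-level controls.

**What passing tests do and do not show.** The generator matches the
integration's independence assumption and uses clean Gaussian/Poisson
families, missingness that is class-dependent but otherwise at random, and
noiseless gene identifiers. Real data violate all of these: correlated
evidence, intensity-dependent (not class-dependent) missingness, protein
groups mapping ambiguously to genes, and training sets with curation biases.
Tests on synthetic data therefore certify the *implementation* (the
estimator computes what the model says) and the model's behaviour under its
own assumptions — not performance on real screens.

# Problem sizes and reproducibility

The test suite exercises the full pipeline at 5000 genes with 300 true
interactors and ten-fold cross-validation, and the method-comparison
properties at 2000 genes — sizes at which every statistical band asserted in
the tests (cross-validated pooled AUC, integrated-versus-single-track AUC,
chance-level null behaviour) is stable under the fixed seeds while the whole
suite stays fast. Unit-level properties use instances of tens of genes where
oracle computations are exhaustive. All randomness flows through explicit
seeds (`withSeed()` restores the caller's RNG state), every random choice is
recorded in the outputs, and reruns of `runPipeline()` with one configuration
are byte-identical.

# Known limitations

* Bin borders for the published datasets are not shipped; reproducing a
  specific published ranking requires the original evidence values and
  borders, which the run log format can carry but the package cannot invent.
* The negative-set rule presumes trustworthy GO flags; annotation errors
  propagate directly into the likelihood estimates.
* The pseudo-count rule is asymmetric by design (literal form); with very
  small negative sets it can overstate the evidence of empty-negative bins.
* No dependence modelling between tracks and no continuous-density scoring:
  binning is the method. Strongly correlated tracks will double-count
  evidence.
* The volcano-plot style significance analysis of individual approaches is
  out of scope; enrichment calling is threshold-based.
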