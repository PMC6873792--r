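# mtRIpred

Ranking the human proteome for mitochondrial poly(A) RNA interaction from
crosslinking mass-spectrometry and public annotation evidence.

## The problem

Mitochondrial gene expression depends on a few hundred nuclear-encoded
proteins that bind mitochondrial mRNAs, tRNAs and rRNAs — processing and
modification enzymes, stability factors, ribosome-assembly factors. RNA
interactome capture (UV-crosslinking followed by oligo(dT) pulldown and
shotgun MS) finds whole-cell poly(A) RNA binders, but a mitochondrially
targeted variant has to contend with small signal, heavy contamination by
cytosolic RNA-binding proteins, and missing quantifications. No single
experiment settles the question, so the analysis integrates several weak,
complementary lines of evidence into one ranked list.

`mtRIpred` implements that analysis for people running such screens:

1. **LFQ enrichment** — label-free quantification tables (MaxQuant
   `proteinGroups`-style) are log2-transformed; missing values are imputed
   with the lowest measured log2 intensity; technical replicates are averaged
   within biological replicates and then across them; the log2 fold-change of
   crosslinked over control samples is computed per approach (mitochondrial
   crosslinking MXL, whole-cell crosslinking WCXL, and the EtBr-depletion
   control WCXL_EtBr); proteins with fold-change ≥ log2(3) are called
   enriched; MXL and WCXL fold-changes are combined into the
   mtRNA-interaction evidence track.
2. **Training sets** — a curated positive list of known mtRNA interactors,
   plus a rule-built negative set: mitochondrial TCA/OXPHOS genes without an
   RNA-binding GO term, and an equal-sized seeded sample of RNA-binding genes
   without a mitochondrial GO term.
3. **Bayesian integration** — every evidence track (combined fold-change,
   MitoCarta-style localization score, RNA-binding-domain flag,
   co-expression, protein-interaction counts) is discretized into bins
   (genes missing from a track form their own bin), each bin is weighted by
   the log2 ratio of positive to negative training-set fractions with a
   pseudo-count `0.5 / |negatives|` guarding empty bins, and each gene's
   score is

   ```
   mtRNAscore(g) = log2(O_prior) + Σ_i log2( P(data_i | mtRNA) / P(data_i | non-mtRNA) )
   ```

   with `O_prior = n_expected / (n_genes − n_expected)` (300 of 20129 by
   default). The prior shifts all scores equally and never changes the
   ranking. Score ties are broken by the combined fold-change, then by gene
   identifier.
4. **Evaluation** — training-set sensitivity/specificity at a score cutoff;
   the prior-corrected false discovery rate
   `cFDR = (1 − spec) / ((1 − spec) + sens · O_prior)`; ROC curves with
   trapezoidal AUC; and ten-fold cross-validation in which bin weights are
   re-fit on 9/10 of the training genes and every training gene's held-out
   rank is pooled into a ROC.
5. **Synthetic studies** — a seeded generator (`simulateStudy()`) produces a
   full study (ground truth, LFQ matrices for both approaches, all annotation
   tracks, training sets) with configurable effect sizes, noise and
   missingness, so the entire pipeline is testable without any downloads.

## Worked example

```r
library(mtRIpred)

study <- simulateStudy(simConfig(n_genes = 5000, n_true = 300, seed = 1))
res <- runPipeline(study$lfq, study$annotations,
                   positives(study$trainingSets),
                   nExpected = 300, k = 10)

res$ranking
#> MtRnaRanking: 5000 genes, 5 evidence tracks
#>   prior: 300 expected of 5000 genes (log2 odds -3.970)
#>   top genes:
#>        1 G0536           3.240
#>        2 G3379           3.240
#>        3 G4686           3.240
#>        4 G1749           3.240
#>        5 G4430           3.240

str(res$metrics)
#> List of 6
#>  $ cutoff_score: num -8.76
#>  $ n_selected  : int 563
#>  $ sensitivity : num 1
#>  $ specificity : num 0.859
#>  $ cFDR        : num 0.689
#>  $ cFDR_percent: num 69

cat(sprintf("cross-validated pooled AUC: %.3f\n", res$crossValidation$auc))
#> cross-validated pooled AUC: 0.988
```

The ranking object lists all 5000 genes ordered by mtRNA score (top ties
share one bin pattern and are ordered by fold-change, then identifier). The
metrics describe the most inclusive cutoff whose corrected FDR stays at or
below the 0.69 target: 563 genes are selected, recovering all 24 training
positives (sensitivity 1.000) while excluding 85.9% of the 248 training
negatives; the corrected FDR at that cutoff is 69%. The pooled
cross-validated AUC of 0.988 says held-out training genes are ranked almost
perfectly. With `outDir =` set, the ranked table, fold-changes, metrics,
cross-validation report and a run log (seeds, prior, bin borders) are written
as TSV/JSON.

A thin command-line wrapper with subcommands (`simulate`, `process-lfq`,
`build-training`, `integrate`, `evaluate`, `crossval`, `run-all`) is
installed at `inst/scripts/mtripred.R`.

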