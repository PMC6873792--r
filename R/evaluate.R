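#' @include bayes.R
NULL

#' Training-set sensitivity and specificity at a score cutoff
#'
#' Selects every gene whose mtRNA score reaches `cutoffScore` (inclusive) and
#' evaluates the selection on the training genes only: sensitivity is the
#' fraction of positive training genes selected, specificity the fraction of
#' negative training genes excluded.
#'
#' @param ranking An [MtRnaRanking-class] object.
#' @param sets A [TrainingSets-class] object.
#' @param cutoffScore Score threshold; genes with `score >= cutoffScore` are
#'   selected. A cutoff above the maximum score yields an empty selection
#'   (sensitivity 0), not an error.
#' @return A list with `cutoff_score`, `n_selected`, `sensitivity`,
#'   `specificity`.
#' @seealso [correctedFdr()], [rankMetricsTable()]
#' @export
confusionAtCutoff <- function(ranking, sets, cutoffScore) {
  stopifnot(is(ranking, "MtRnaRanking"), is(sets, "TrainingSets"),
            is.numeric(cutoffScore), length(cutoffScore) == 1L)
  s <- geneScores(ranking)
  selected <- names(s)[s >= cutoffScore]
  pos <- positives(sets)
  neg <- negatives(sets)
  list(cutoff_score = as.numeric(cutoffScore),
       n_selected = length(selected),
       sensitivity = length(intersect(selected, pos)) / length(pos),
       specificity = 1 - length(intersect(selected, neg)) / length(neg))
}

#' Corrected false discovery rate
#'
#' The training-set FDR does not reflect the genome-wide class balance: the
#' training sets contain roughly one positive per ten negatives, whereas only
#' a few hundred of ~20000 genes are expected to interact with mtRNA. The
#' corrected FDR re-weights the raw error rates by the prior odds:
#' \deqn{cFDR = \frac{1 - specificity}{(1 - specificity) + sensitivity \cdot
#'   O_{prior}}}
#' where \eqn{O_{prior}} is the *non-log* prior odds
#' `nExpected / (nGenes - nExpected)`. With no selections (sensitivity 0 and
#' specificity 1) the cFDR is defined as 0.
#'
#' @param sensitivity,specificity Training-set rates in `[0, 1]`
#'   (vectorized).
#' @param priorOdds Non-log prior odds, e.g. `computeOprior()$priorOdds`.
#' @return The corrected FDR in `[0, 1]`.
#' @examples
#' correctedFdr(0.958, 0.968, 300 / (20129 - 300))   # ~0.69
#' @export
correctedFdr <- function(sensitivity, specificity, priorOdds) {
  if (any(sensitivity < 0 | sensitivity > 1, na.rm = TRUE) ||
      any(specificity < 0 | specificity > 1, na.rm = TRUE)) {
    stop("sensitivity and specificity must lie in [0, 1]")
  }
  if (any(priorOdds <= 0)) stop("'priorOdds' must be positive")
  fpr <- 1 - specificity
  out <- fpr / (fpr + sensitivity * priorOdds)
  out[fpr == 0 & sensitivity == 0] <- 0
  out
}

#' @describeIn correctedFdr The cFDR as an integer percentage (round half
#'   up), the form in which cutoffs are reported.
#' @export
cfdrPercent <- function(sensitivity, specificity, priorOdds) {
  roundHalfUp(100 * correctedFdr(sensitivity, specificity, priorOdds))
}

#' ROC curve and AUC for a gene scoring
#'
#' Sweeps all score thresholds (tie groups handled jointly, so tied scores
#' contribute a diagonal segment) and returns the ROC points with the
#' trapezoidal area under the curve — equivalent to the Mann-Whitney
#' statistic with rank-averaged ties.
#'
#' @param scores Numeric scores (higher = more positive).
#' @param labels Logical vector, `TRUE` for positives, aligned with
#'   `scores`.
#' @return A list with `points` (`data.frame` of `fpr`, `tpr` from (0,0) to
#'   (1,1)) and `auc`.
#' @examples
#' rocCurve(c(3, 1, 2, 0), c(TRUE, TRUE, FALSE, FALSE))$auc
#' @export
rocCurve <- function(scores, labels) {
  stopifnot(is.numeric(scores), length(scores) == length(labels))
  labels <- as.logical(labels)
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]
  labels <- labels[keep]
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L) {
    stop("ROC needs at least one positive and one negative with a score")
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  l <- labels[ord]
  # collapse tie groups: one ROC point per distinct threshold
  grp_end <- which(!duplicated(s, fromLast = TRUE))
  tp <- cumsum(l)[grp_end]
  fp <- cumsum(!l)[grp_end]
  pts <- data.frame(fpr = c(0, fp / n_neg), tpr = c(0, tp / n_pos))
  auc <- sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) +
                                utils::tail(pts$tpr, -1)) / 2)
  list(points = pts, auc = auc)
}

#' Ten-fold cross-validated evaluation of the integration
#'
#' Partitions the training genes into `k` seeded folds, stratified within the
#' positive set and within the negative set so fold sizes differ by at most
#' one per class, and every training gene is held out exactly once. For each
#' fold the bin tables are re-estimated from the remaining 9/10 of the
#' training genes (bin borders stay fixed — they are part of the model
#' specification, derived from the evidence values, not from the labels) and
#' the full integration and ranking is re-run. The rank of each held-out gene
#' in its fold's ranking is recorded, and a pooled ROC over the held-out
#' ranks measures how well the integrated score separates known
#' mtRNA-interacting genes from negatives it has not seen.
#'
#' @inheritParams integrateEvidence
#' @param k Number of folds (default 10).
#' @param seed Integer seed for the fold partition.
#' @return A list with `heldOut` (`data.frame` of `gene_id`, `label`,
#'   `fold`, `rank`), `roc` (pooled ROC, see [rocCurve()]), `auc`, `folds`
#'   (named fold assignment) and `binSpecs` (the resolved specifications).
#' @export
crossValidate <- function(evidence, sets, prior, k = 10L, seed = 1L,
                          universe = NULL, binSpecs = NULL, tieBreak = NULL,
                          nBins = 5L,
                          pseudoDenominator = c("negatives", "own")) {
  stopifnot(is(sets, "TrainingSets"))
  k <- assertCount(k, "k", min = 2L)
  pseudoDenominator <- match.arg(pseudoDenominator)
  pos <- positives(sets)
  neg <- negatives(sets)
  if (length(pos) < k || length(neg) < k) {
    stop("need at least k genes in each training class (k = ", k, ")")
  }
  if (is.null(universe)) {
    universe <- sort(unique(unlist(lapply(evidence, names))))
  }
  binSpecs <- resolveBinSpecs(evidence, binSpecs, nBins = nBins)

  folds <- withSeed(seed, {
    f_pos <- stats::setNames(rep_len(seq_len(k), length(pos)), sample(pos))
    f_neg <- stats::setNames(rep_len(seq_len(k), length(neg)), sample(neg))
    c(f_pos, f_neg)
  })

  held <- vector("list", k)
  for (f in seq_len(k)) {
    out_genes <- names(folds)[folds == f]
    sets_f <- TrainingSets(
      setdiff(pos, out_genes),
      setdiff(negatives(sets, "mito_nonrna"), out_genes),
      setdiff(negatives(sets, "rna_nonmito"), out_genes),
      seed = sets@seed)
    res_f <- integrateEvidence(evidence, sets_f, prior, universe = universe,
                               binSpecs = binSpecs, tieBreak = tieBreak,
                               pseudoDenominator = pseudoDenominator)
    rk <- rankedTable(res_f)
    idx <- match(out_genes, rk$gene_id)
    held[[f]] <- data.frame(gene_id = out_genes,
                            label = out_genes %in% pos,
                            fold = f,
                            rank = rk$rank[idx],
                            stringsAsFactors = FALSE)
  }
  held <- do.call(rbind, held)
  roc <- rocCurve(-held$rank, held$label)
  list(heldOut = held, roc = roc, auc = roc$auc, folds = folds,
       binSpecs = binSpecs)
}

#' Metrics as a function of list length
#'
#' Evaluates sensitivity, specificity and corrected FDR at every rank cutoff
#' of a ranked gene list, so a cutoff can be chosen by its cFDR (or by list
#' length) after the fact. Row `rank = 0` is the empty selection.
#'
#' @param ranking An [MtRnaRanking-class] object.
#' @param sets A [TrainingSets-class] object.
#' @param prior A prior from [computeOprior()].
#' @return `data.frame` with columns `rank`, `cutoff_score`, `n_selected`,
#'   `sensitivity`, `specificity`, `cFDR`.
#' @export
rankMetricsTable <- function(ranking, sets, prior) {
  stopifnot(is(ranking, "MtRnaRanking"), is(sets, "TrainingSets"))
  rk <- rankedTable(ranking)
  n_pos <- length(positives(sets))
  n_neg <- length(negatives(sets))
  sens <- c(0, cumsum(rk$in_positive_set) / n_pos)
  spec <- c(1, 1 - cumsum(rk$in_negative_set) / n_neg)
  data.frame(rank = c(0L, rk$rank),
             cutoff_score = c(Inf, rk$mtRNA_score),
             n_selected = c(0L, rk$rank),
             sensitivity = sens,
             specificity = spec,
             cFDR = correctedFdr(sens, spec, prior$priorOdds))
}

#' Choose the score cutoff for a target corrected FDR
#'
#' Returns the most inclusive cutoff — the largest selection — whose cFDR
#' does not exceed `target`, mirroring how the prediction list is cut at a
#' chosen cFDR. The returned `cutoff_score` is the score of the last
#' selected gene.
#'
#' @inheritParams rankMetricsTable
#' @param target Maximum acceptable cFDR (default 0.69).
#' @return One row of [rankMetricsTable()] as a list.
#' @export
cutoffForCfdr <- function(ranking, sets, prior, target = 0.69) {
  assertProb(target, "target")
  tab <- rankMetricsTable(ranking, sets, prior)
  ok <- which(tab$cFDR <= target)
  row <- tab[max(ok), , drop = FALSE]
  as.list(row)
}
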