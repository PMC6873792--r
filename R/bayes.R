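#' @include AllClasses.R
NULL

#' Quantile-based bin specification for a continuous evidence track
#'
#' Computes interior quantile borders over the genes with a value, giving
#' `nBins` approximately equally populated bins (plus the mandatory missing
#' bin). Duplicate quantiles — common for zero-inflated tracks such as
#' interaction counts — are collapsed, so the effective number of bins can be
#' smaller.
#'
#' @param datasetName Name of the evidence track.
#' @param values Numeric vector of per-gene values (`NA` = missing).
#' @param nBins Target number of value bins (default 5).
#' @return A [BinSpec-class] of kind `"continuous"`.
#' @export
quantileBinSpec <- function(datasetName, values, nBins = 5L) {
  nBins <- assertCount(nBins, "nBins", min = 2L)
  v <- values[!is.na(values)]
  if (!length(v)) stop("no observed values to derive borders from")
  probs <- seq(0, 1, length.out = nBins + 1L)[-c(1L, nBins + 1L)]
  borders <- unique(as.numeric(stats::quantile(v, probs, names = FALSE,
                                               type = 7)))
  if (!length(borders)) borders <- unique(v)[1L]
  binSpec(datasetName, "continuous", borders = borders)
}

#' Assign every gene of the universe to a bin
#'
#' Maps per-gene evidence values onto the bins of a [BinSpec-class]. Genes of
#' the universe without a value (absent from `values` or `NA`) go to the
#' `"missing"` bin. Continuous bins are half-open `[lo, hi)` with open-ended
#' outer bins, so every finite value is covered.
#'
#' @param values Named vector of evidence values (numeric for
#'   continuous/discrete tracks, logical for flags). Names are gene
#'   identifiers; genes may be a subset of the universe.
#' @param spec A [BinSpec-class].
#' @param universe Character vector of all gene identifiers; defaults to
#'   `names(values)`.
#' @return A factor of bin labels, named by gene, whose levels always include
#'   `"missing"`.
#' @examples
#' sp <- binSpec("track", "continuous", borders = c(0, 2))
#' assignBins(c(A = 1, B = 3, C = NA), sp)
#' @export
assignBins <- function(values, spec, universe = names(values)) {
  stopifnot(is(spec, "BinSpec"))
  methods::validObject(spec)
  if (is.null(names(values))) stop("'values' must be named by gene identifier")
  if (is.null(universe)) stop("a gene universe is required")
  extra <- setdiff(names(values), universe)
  if (length(extra)) {
    stop("value(s) for gene(s) outside the universe: ",
         paste(utils::head(extra, 5), collapse = ", "))
  }
  v <- values[match(universe, names(values))]
  bins <- switch(spec@kind,
    continuous = {
      vv <- as.numeric(v)
      as.character(cut(vv, breaks = c(-Inf, spec@borders, Inf),
                       right = FALSE, dig.lab = 6))
    },
    flag = c("no", "yes")[as.logical(v) + 1L],
    discrete = as.character(v))
  bins[is.na(v)] <- "missing"
  lev <- switch(spec@kind,
    continuous = levels(cut(numeric(0), breaks = c(-Inf, spec@borders, Inf),
                            right = FALSE, dig.lab = 6)),
    flag = c("no", "yes"),
    discrete = sort(unique(bins[bins != "missing"])))
  stats::setNames(factor(bins, levels = c(lev, "missing")), universe)
}

#' Score bins by training-set log2 likelihood ratios
#'
#' For each bin, counts positive and negative training genes, converts the
#' counts to within-set fractions, and takes the log2 ratio of the fractions
#' as the bin's evidence weight. A fraction of zero is replaced by the
#' pseudo-fraction `0.5 / |negatives|` so every ratio is finite; by default
#' the negative-set size is the denominator for both sides
#' (`pseudoDenominator = "negatives"`), with `"own"` using each set's own
#' size instead.
#'
#' @param assignments Factor of bin labels named by gene, from
#'   [assignBins()].
#' @param sets A [TrainingSets-class] object.
#' @param pseudoDenominator `"negatives"` (default) or `"own"`.
#' @return `data.frame` with one row per bin: `bin`, `n_pos`, `n_neg`,
#'   `frac_pos`, `frac_neg`, `log2_ratio`.
#' @export
scoreBins <- function(assignments, sets,
                      pseudoDenominator = c("negatives", "own")) {
  stopifnot(is(sets, "TrainingSets"), is.factor(assignments))
  pseudoDenominator <- match.arg(pseudoDenominator)
  pos <- positives(sets)
  neg <- negatives(sets)
  if (!length(pos) || !length(neg)) stop("empty training set")
  genes <- names(assignments)
  missing_train <- setdiff(c(pos, neg), genes)
  if (length(missing_train)) {
    stop("training gene(s) not in the binned universe: ",
         paste(utils::head(missing_train, 5), collapse = ", "))
  }
  n_pos <- table(assignments[pos])
  n_neg <- table(assignments[neg])
  frac_pos <- as.numeric(n_pos) / length(pos)
  frac_neg <- as.numeric(n_neg) / length(neg)
  pseudo_pos <- if (pseudoDenominator == "negatives") {
    0.5 / length(neg)
  } else {
    0.5 / length(pos)
  }
  pseudo_neg <- 0.5 / length(neg)
  frac_pos[frac_pos == 0] <- pseudo_pos
  frac_neg[frac_neg == 0] <- pseudo_neg
  data.frame(bin = levels(assignments),
             n_pos = as.integer(n_pos),
             n_neg = as.integer(n_neg),
             frac_pos = frac_pos,
             frac_neg = frac_neg,
             log2_ratio = log2(frac_pos / frac_neg),
             stringsAsFactors = FALSE)
}

#' Prior odds of mtRNA interaction
#'
#' Encodes the genome-wide expectation that `nExpected` of the `nGenes`
#' protein-coding genes encode a mitochondrial RNA interacting protein. The
#' log2 of the prior odds enters every mtRNA score as a constant offset (so
#' it never changes the ranking); the raw odds enter the corrected FDR.
#'
#' @param nExpected Expected number of mtRNA-interacting genes (default 300).
#' @param nGenes Number of protein-coding genes in the reference proteome
#'   (default 20129).
#' @return A list with `nExpected`, `nGenes`, `priorOdds`
#'   (`nExpected / (nGenes - nExpected)`) and `opriorLog2`
#'   (`log2(priorOdds)`).
#' @examples
#' computeOprior(300, 20129)
#' @export
computeOprior <- function(nExpected = 300L, nGenes = 20129L) {
  nExpected <- assertCount(nExpected, "nExpected")
  nGenes <- assertCount(nGenes, "nGenes")
  if (nExpected >= nGenes) stop("'nExpected' must be smaller than 'nGenes'")
  odds <- nExpected / (nGenes - nExpected)
  list(nExpected = nExpected, nGenes = nGenes,
       priorOdds = odds, opriorLog2 = log2(odds))
}

# Resolve bin specifications for a list of evidence tracks: numeric tracks
# get quantile bins, logical tracks the flag bins.
resolveBinSpecs <- function(evidence, binSpecs = NULL, nBins = 5L) {
  stopifnot(is.list(evidence), !is.null(names(evidence)))
  out <- list()
  for (nm in names(evidence)) {
    sp <- binSpecs[[nm]]
    if (is.null(sp)) {
      sp <- if (is.logical(evidence[[nm]])) {
        binSpec(nm, "flag")
      } else {
        quantileBinSpec(nm, evidence[[nm]], nBins = nBins)
      }
    }
    stopifnot(is(sp, "BinSpec"))
    out[[nm]] <- sp
  }
  out
}

#' Rank genes by score with fold-change tie-breaking
#'
#' Primary sort is descending score; genes with equal scores are ordered by
#' descending combined log2 fold-change (missing fold-changes sort last);
#' remaining ties are broken lexicographically by gene identifier so the
#' ranking is a deterministic total order.
#'
#' @param scores Named numeric vector of per-gene scores.
#' @param tieBreak Optional named numeric vector of combined log2
#'   fold-changes used to break score ties.
#' @return Integer ranks (1 = best), named by gene.
#' @export
rankGenes <- function(scores, tieBreak = NULL) {
  stopifnot(is.numeric(scores), !is.null(names(scores)))
  ids <- names(scores)
  tb <- rep(-Inf, length(ids))
  if (!is.null(tieBreak)) {
    v <- as.numeric(tieBreak[ids])
    tb[!is.na(v)] <- v[!is.na(v)]
  }
  ord <- order(-scores, -tb, ids, method = "radix")
  ranks <- integer(length(ids))
  ranks[ord] <- seq_along(ids)
  stats::setNames(ranks, ids)
}

#' Integrate binned evidence tracks into per-gene mtRNA scores
#'
#' The core naive-Bayes integration: each evidence track is discretized
#' (see [assignBins()]), each bin is weighted by its training-set log2
#' likelihood ratio (see [scoreBins()]), and every gene's mtRNA score is the
#' log2 prior odds plus the sum of its bins' weights across tracks. Genes
#' absent from a track fall in that track's missing bin, which is scored like
#' any other bin — absence from a crosslinking experiment is itself evidence.
#' The full universe is then ranked (see [rankGenes()]).
#'
#' @param evidence Named list of per-gene evidence vectors (named numeric, or
#'   named logical for flag tracks); each may cover a subset of the universe.
#' @param sets A [TrainingSets-class] object.
#' @param prior A prior from [computeOprior()].
#' @param universe Character vector of all gene identifiers. Defaults to the
#'   union of gene names across tracks.
#' @param binSpecs Optional named list of [BinSpec-class] objects; tracks
#'   without one get quantile bins (numeric) or flag bins (logical).
#' @param tieBreak Optional named numeric vector (typically
#'   `combined_log2_fc`) for rank tie-breaking.
#' @param nBins Bin count for automatically derived quantile bins.
#' @param pseudoDenominator Pseudo-count rule, see [scoreBins()].
#' @return An [MtRnaRanking-class] object.
#' @examples
#' ev <- list(flagTrack = c(g1 = TRUE, g2 = FALSE, g3 = TRUE, g4 = FALSE))
#' sets <- TrainingSets("g1", "g2", "g4")
#' pr <- computeOprior(2, 10)
#' integrateEvidence(ev, sets, pr, universe = paste0("g", 1:6))
#' @export
integrateEvidence <- function(evidence, sets, prior,
                              universe = NULL, binSpecs = NULL,
                              tieBreak = NULL, nBins = 5L,
                              pseudoDenominator = c("negatives", "own")) {
  stopifnot(is.list(evidence), length(evidence) >= 1L,
            !is.null(names(evidence)), is(sets, "TrainingSets"))
  pseudoDenominator <- match.arg(pseudoDenominator)
  if (is.null(universe)) {
    universe <- sort(unique(unlist(lapply(evidence, names))))
  }
  for (nm in names(evidence)) {
    bad <- setdiff(names(evidence[[nm]]), universe)
    if (length(bad)) {
      stop("track '", nm, "' covers gene(s) outside the universe: ",
           paste(utils::head(bad, 5), collapse = ", "))
    }
  }
  validateTrainingSets(sets, universe)
  specs <- resolveBinSpecs(evidence, binSpecs, nBins = nBins)

  contrib <- matrix(0, nrow = length(universe), ncol = length(evidence),
                    dimnames = list(universe, names(evidence)))
  bin_tables <- list()
  for (nm in names(evidence)) {
    asg <- assignBins(evidence[[nm]], specs[[nm]], universe)
    tab <- scoreBins(asg, sets, pseudoDenominator = pseudoDenominator)
    bin_tables[[nm]] <- tab
    contrib[, nm] <- tab$log2_ratio[match(as.character(asg), tab$bin)]
  }
  # Score differences below 1e-9 log2 units are floating-point noise from the
  # summation, not evidence: round so such genes form a genuine tie group and
  # the fold-change tie-break applies deterministically. Ranking uses the
  # prior-free sums — the prior is a constant offset, so the order is the
  # same for every prior, bit for bit.
  sums <- round(rowSums(contrib), 9)
  scores <- prior$opriorLog2 + sums
  names(scores) <- names(sums) <- universe
  ranks <- rankGenes(sums, tieBreak)

  tb <- rep(NA_real_, length(universe))
  if (!is.null(tieBreak)) tb <- as.numeric(tieBreak[universe])
  ord <- order(ranks)
  ranking <- S4Vectors::DataFrame(
    gene_id = universe[ord],
    mtRNA_score = unname(scores[ord]),
    tie_break_fc = tb[ord],
    rank = unname(ranks[ord]),
    in_positive_set = universe[ord] %in% positives(sets),
    in_negative_set = universe[ord] %in% negatives(sets))
  .MtRnaRanking(ranking = ranking,
                contributions = contrib[ord, , drop = FALSE],
                binScoreTables = bin_tables,
                prior = prior)
}
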