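#' @include AllGenerics.R
NULL

.APPROACHES <- c("MXL", "WCXL", "WCXL_EtBr")
.CONDITIONS <- c("crosslinked", "control")

# ---------------------------------------------------------------------------
# LfqExperiment
# ---------------------------------------------------------------------------

#' Container for label-free quantification intensities
#'
#' `LfqExperiment` extends [SummarizedExperiment::SummarizedExperiment] with a
#' fixed sample-annotation contract: each column (sample) carries an
#' `approach` (`"MXL"`, `"WCXL"` or `"WCXL_EtBr"`), a `condition`
#' (`"crosslinked"` or `"control"`), and 1-based `biological_rep` /
#' `technical_rep` indices. Rows are gene-level protein identifiers. The
#' `"intensities"` assay holds linear, strictly positive LFQ values with `NA`
#' for missing quantifications; after [log2TransformAndImpute()] it holds
#' log2 values, a logical `"imputed"` assay marks filled-in cells, and
#' `metadata(x)$log2` is `TRUE`.
#'
#' For the `WCXL_EtBr` approach the samples labelled `condition = "control"`
#' are the crosslinked, ethidium-bromide-treated samples: fold-changes for
#' that approach compare crosslinking against crosslinking under mtRNA
#' depletion.
#'
#' @param intensities Numeric matrix, proteins x samples, linear scale,
#'   strictly positive where present, `NA` for missing. Row names are gene
#'   identifiers, column names are sample identifiers.
#' @param samples `data.frame` with columns `sample_id`, `approach`,
#'   `condition`, `biological_rep`, `technical_rep`; one row per column of
#'   `intensities`.
#' @return An `LfqExperiment` object.
#' @examples
#' m <- matrix(c(8, 4, NA, 16), nrow = 2,
#'             dimnames = list(c("A", "B"), c("s1", "s2")))
#' sm <- data.frame(sample_id = c("s1", "s2"), approach = "MXL",
#'                  condition = c("crosslinked", "control"),
#'                  biological_rep = 1L, technical_rep = 1L)
#' lfq <- LfqExperiment(m, sm)
#' lfq
#' @aliases LfqExperiment
#' @export LfqExperiment
#' @exportClass LfqExperiment
.LfqExperiment <- setClass("LfqExperiment",
                           contains = "SummarizedExperiment")

setValidity("LfqExperiment", function(object) {
  msg <- character()
  cd <- SummarizedExperiment::colData(object)
  needed <- c("sample_id", "approach", "condition",
              "biological_rep", "technical_rep")
  missing_cols <- setdiff(needed, colnames(cd))
  if (length(missing_cols)) {
    return(paste("colData lacks column(s):",
                 paste(missing_cols, collapse = ", ")))
  }
  if (!"intensities" %in% SummarizedExperiment::assayNames(object)) {
    return("assay 'intensities' is required")
  }
  if (is.null(rownames(object))) {
    msg <- c(msg, "row (protein/gene) names are required")
  }
  if (!all(cd$approach %in% .APPROACHES)) {
    msg <- c(msg, paste("approach must be one of:",
                        paste(.APPROACHES, collapse = ", ")))
  }
  if (!all(cd$condition %in% .CONDITIONS)) {
    msg <- c(msg, paste("condition must be one of:",
                        paste(.CONDITIONS, collapse = ", ")))
  }
  key <- paste(cd$approach, cd$condition, cd$biological_rep, cd$technical_rep)
  if (anyDuplicated(key)) {
    msg <- c(msg, "(approach, condition, biological_rep, technical_rep) must be unique")
  }
  if (any(cd$biological_rep < 1) || any(cd$technical_rep < 1)) {
    msg <- c(msg, "replicate indices must be >= 1")
  }
  m <- SummarizedExperiment::assay(object, "intensities")
  if (!isTRUE(S4Vectors::metadata(object)$log2)) {
    if (any(m[!is.na(m)] <= 0)) {
      msg <- c(msg, "linear intensities must be strictly positive where present")
    }
  }
  if (length(msg)) msg else TRUE
})

LfqExperiment <- function(intensities, samples) {
  intensities <- as.matrix(intensities)
  samples <- as.data.frame(samples)
  if (is.null(rownames(intensities))) {
    stop("'intensities' must have row names (gene identifiers)")
  }
  if (!"sample_id" %in% colnames(samples)) {
    stop("'samples' must have a 'sample_id' column")
  }
  if (is.null(colnames(intensities))) {
    stop("'intensities' must have column names (sample identifiers)")
  }
  if (!setequal(colnames(intensities), samples$sample_id) ||
      anyDuplicated(samples$sample_id)) {
    stop("columns of 'intensities' and 'samples$sample_id' must match one-to-one")
  }
  samples <- samples[match(colnames(intensities), samples$sample_id), ,
                     drop = FALSE]
  rownames(samples) <- samples$sample_id
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(intensities = intensities),
    colData = S4Vectors::DataFrame(samples))
  S4Vectors::metadata(se)$log2 <- FALSE
  .LfqExperiment(se)
}

#' @describeIn LfqExperiment Whether intensities are on the log2 scale.
#' @param x,object An `LfqExperiment`.
#' @export
isLog2 <- function(x) isTRUE(S4Vectors::metadata(x)$log2)

#' @describeIn LfqExperiment Logical matrix marking imputed cells (all-`FALSE`
#'   before imputation).
#' @export
imputedMask <- function(x) {
  if ("imputed" %in% SummarizedExperiment::assayNames(x)) {
    SummarizedExperiment::assay(x, "imputed")
  } else {
    m <- SummarizedExperiment::assay(x, "intensities")
    array(FALSE, dim = dim(m), dimnames = dimnames(m))
  }
}

setMethod("show", "LfqExperiment", function(object) {
  cd <- SummarizedExperiment::colData(object)
  cat("LfqExperiment:", nrow(object), "proteins x", ncol(object), "samples\n")
  cat("  scale:", if (isLog2(object)) "log2 (imputed)" else "linear", "\n")
  tab <- table(cd$approach, cd$condition)
  for (a in rownames(tab)) {
    cat(sprintf("  %-10s crosslinked: %d, control: %d\n", a,
                tab[a, "crosslinked"], tab[a, "control"]))
  }
  invisible(NULL)
})

# ---------------------------------------------------------------------------
# TrainingSets
# ---------------------------------------------------------------------------

#' Positive and negative training gene sets
#'
#' Holds the curated positive set of known mtRNA-interacting genes and the
#' rule-built negative set used to estimate per-bin likelihood ratios. The
#' negative set consists of two equally sized categories: mitochondrial
#' TCA/OXPHOS genes without an RNA-binding GO annotation
#' (`negMitoNonRna`), and a seeded random sample of RNA-binding genes without
#' a mitochondrial GO annotation (`negRnaNonMito`). Validity requires all
#' three lists to be non-empty, duplicate-free and mutually disjoint.
#'
#' @param positives,negMitoNonRna,negRnaNonMito Character vectors of gene
#'   identifiers.
#' @param seed Integer seed recorded for the random sampling of
#'   `negRnaNonMito` (may be `NA` if the set was not sampled).
#' @return A `TrainingSets` object.
#' @seealso [buildNegativeSet()], [buildTrainingSets()],
#'   [validateTrainingSets()]
#' @examples
#' ts <- TrainingSets(positives = c("g1", "g2"),
#'                    negMitoNonRna = c("g3", "g4"),
#'                    negRnaNonMito = c("g5", "g6"), seed = 7L)
#' ts
#' negatives(ts)
#' @aliases TrainingSets
#' @export TrainingSets
#' @exportClass TrainingSets
.TrainingSets <- setClass("TrainingSets",
  representation(positives = "character",
                 negMitoNonRna = "character",
                 negRnaNonMito = "character",
                 seed = "integer"))

setValidity("TrainingSets", function(object) {
  msg <- character()
  p <- object@positives
  n1 <- object@negMitoNonRna
  n2 <- object@negRnaNonMito
  if (!length(p)) msg <- c(msg, "positive set is empty")
  if (!length(n1) && !length(n2)) msg <- c(msg, "negative set is empty")
  if (anyDuplicated(p) || anyDuplicated(n1) || anyDuplicated(n2)) {
    msg <- c(msg, "duplicate gene identifiers within a set")
  }
  if (length(intersect(p, c(n1, n2)))) {
    msg <- c(msg, paste("positives overlap negatives:",
                        paste(utils::head(intersect(p, c(n1, n2)), 5),
                              collapse = ", ")))
  }
  if (length(intersect(n1, n2))) {
    msg <- c(msg, "negative categories overlap")
  }
  if (length(msg)) msg else TRUE
})

TrainingSets <- function(positives, negMitoNonRna, negRnaNonMito,
                         seed = NA_integer_) {
  .TrainingSets(positives = as.character(positives),
                negMitoNonRna = as.character(negMitoNonRna),
                negRnaNonMito = as.character(negRnaNonMito),
                seed = as.integer(seed))
}

#' @rdname positives
setMethod("positives", "TrainingSets", function(x, ...) x@positives)

#' @rdname positives
#' @param category `"all"` for the combined negative set, or one of
#'   `"mito_nonrna"`, `"rna_nonmito"` for a single category.
setMethod("negatives", "TrainingSets",
          function(x, category = c("all", "mito_nonrna", "rna_nonmito"), ...) {
  category <- match.arg(category)
  switch(category,
         all = c(x@negMitoNonRna, x@negRnaNonMito),
         mito_nonrna = x@negMitoNonRna,
         rna_nonmito = x@negRnaNonMito)
})

setMethod("show", "TrainingSets", function(object) {
  cat("TrainingSets\n")
  cat("  positives:              ", length(object@positives), "genes\n")
  cat("  negatives (mito, non-RNA):", length(object@negMitoNonRna), "genes\n")
  cat("  negatives (RNA, non-mito):", length(object@negRnaNonMito), "genes\n")
  cat("  sampling seed:           ",
      if (is.na(object@seed)) "none" else object@seed, "\n")
  invisible(NULL)
})

# ---------------------------------------------------------------------------
# BinSpec
# ---------------------------------------------------------------------------

#' Bin specification for one evidence track
#'
#' Describes how a per-gene evidence track is discretized before likelihood
#' scoring. Continuous tracks are cut at `borders` into half-open intervals
#' `[lo, hi)` with open-ended outer bins; `flag` tracks have the two logical
#' bins; `discrete` tracks use each observed value as its own bin. Every
#' specification implicitly includes a `"missing"` bin that collects genes
#' absent from the track — absence is treated as evidence like any other bin.
#'
#' @param datasetName Name of the evidence track.
#' @param kind One of `"continuous"`, `"discrete"`, `"flag"`.
#' @param borders For `"continuous"`: strictly increasing numeric cut points.
#' @return A `BinSpec` object.
#' @seealso [quantileBinSpec()], [assignBins()]
#' @examples
#' binSpec("mitocarta_score", "continuous", borders = c(-1, 0, 1))
#' @aliases BinSpec
#' @export binSpec
#' @exportClass BinSpec
.BinSpec <- setClass("BinSpec",
  representation(datasetName = "character",
                 kind = "character",
                 borders = "numeric"))

setValidity("BinSpec", function(object) {
  msg <- character()
  if (length(object@datasetName) != 1L || !nzchar(object@datasetName)) {
    msg <- c(msg, "datasetName must be a single non-empty string")
  }
  if (length(object@kind) != 1L ||
      !object@kind %in% c("continuous", "discrete", "flag")) {
    msg <- c(msg, "kind must be 'continuous', 'discrete' or 'flag'")
  }
  if (identical(object@kind, "continuous")) {
    b <- object@borders
    if (!length(b) || anyNA(b) || any(!is.finite(b))) {
      msg <- c(msg, "continuous bins need at least one finite border")
    } else if (is.unsorted(b, strictly = TRUE)) {
      msg <- c(msg, "borders must be strictly increasing")
    }
  } else if (length(object@borders)) {
    msg <- c(msg, "borders are only meaningful for continuous bins")
  }
  if (length(msg)) msg else TRUE
})

binSpec <- function(datasetName, kind = c("continuous", "discrete", "flag"),
                    borders = numeric(0)) {
  kind <- match.arg(kind)
  .BinSpec(datasetName = as.character(datasetName), kind = kind,
           borders = as.numeric(borders))
}

setMethod("show", "BinSpec", function(object) {
  cat("BinSpec '", object@datasetName, "' (", object@kind, ")\n", sep = "")
  if (identical(object@kind, "continuous")) {
    cat("  borders:", paste(signif(object@borders, 6), collapse = ", "), "\n")
  }
  cat("  includes a 'missing' bin\n")
  invisible(NULL)
})

# ---------------------------------------------------------------------------
# MtRnaRanking
# ---------------------------------------------------------------------------

#' Ranked result of the Bayesian evidence integration
#'
#' One row per gene of the universe, sorted by rank. The mtRNA score of a
#' gene is the log2 prior odds plus the sum of its per-track log2
#' likelihood-ratio contributions; ranks are a total order (score, then
#' combined fold-change, then gene identifier). Validity enforces that ranks
#' are a permutation of `1..n`, that scores are non-increasing with rank and
#' that every score equals the prior plus the row sum of the contribution
#' matrix.
#'
#' Create objects with [integrateEvidence()]; inspect them with
#' [rankedTable()], [geneScores()], [contributions()], [binScores()] and
#' [priorSpec()].
#'
#' @seealso [integrateEvidence()], [confusionAtCutoff()], [rocCurve()]
#' @aliases MtRnaRanking
#' @exportClass MtRnaRanking
.MtRnaRanking <- setClass("MtRnaRanking",
  representation(ranking = "DFrame",
                 contributions = "matrix",
                 binScoreTables = "list",
                 prior = "list"))

setValidity("MtRnaRanking", function(object) {
  msg <- character()
  rk <- object@ranking
  needed <- c("gene_id", "mtRNA_score", "tie_break_fc", "rank",
              "in_positive_set", "in_negative_set")
  missing_cols <- setdiff(needed, colnames(rk))
  if (length(missing_cols)) {
    return(paste("ranking lacks column(s):",
                 paste(missing_cols, collapse = ", ")))
  }
  n <- nrow(rk)
  if (!identical(sort(as.integer(rk$rank)), seq_len(n))) {
    msg <- c(msg, "ranks must be a permutation of 1..n")
  }
  s <- rk$mtRNA_score[order(rk$rank)]
  if (n > 1L && any(diff(s) > 1e-12)) {
    msg <- c(msg, "scores must be non-increasing with rank")
  }
  if (nrow(object@contributions) != n) {
    msg <- c(msg, "contribution matrix must have one row per gene")
  } else {
    expect <- object@prior$opriorLog2 + rowSums(object@contributions)
    if (max(abs(expect - rk$mtRNA_score)) > 1e-8) {
      msg <- c(msg, "mtRNA_score must equal prior + sum of contributions")
    }
  }
  if (!all(c("priorOdds", "opriorLog2") %in% names(object@prior))) {
    msg <- c(msg, "prior must carry priorOdds and opriorLog2")
  }
  if (length(msg)) msg else TRUE
})

#' @rdname rankedTable
setMethod("rankedTable", "MtRnaRanking", function(x, ...) {
  df <- as.data.frame(x@ranking)
  contrib <- as.data.frame(x@contributions)
  colnames(contrib) <- paste0("contribution_", colnames(contrib))
  rownames(df) <- NULL
  cbind(df[c("rank", "gene_id", "mtRNA_score")], contrib,
        df[c("tie_break_fc", "in_positive_set", "in_negative_set")])
})

#' @rdname rankedTable
setMethod("geneScores", "MtRnaRanking", function(x, ...) {
  stats::setNames(x@ranking$mtRNA_score, x@ranking$gene_id)
})

#' @rdname rankedTable
setMethod("contributions", "MtRnaRanking", function(x, ...) x@contributions)

#' @rdname rankedTable
setMethod("binScores", "MtRnaRanking", function(x, ...) x@binScoreTables)

#' @rdname rankedTable
setMethod("priorSpec", "MtRnaRanking", function(x, ...) x@prior)

setMethod("show", "MtRnaRanking", function(object) {
  n <- nrow(object@ranking)
  cat("MtRnaRanking:", n, "genes,",
      ncol(object@contributions), "evidence tracks\n")
  cat(sprintf("  prior: %d expected of %d genes (log2 odds %.3f)\n",
              object@prior$nExpected, object@prior$nGenes,
              object@prior$opriorLog2))
  cat("  top genes:\n")
  top <- utils::head(as.data.frame(object@ranking), 5)
  for (i in seq_len(nrow(top))) {
    cat(sprintf("    %4d %-12s %8.3f\n", top$rank[i], top$gene_id[i],
                top$mtRNA_score[i]))
  }
  invisible(NULL)
})
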