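#' @include utils.R
NULL

#' Positive training genes
#'
#' Accessors for the gene identifiers held in a [TrainingSets-class] object.
#' `positives()` returns the curated positive set; `negatives()` returns the
#' negative set, either combined or restricted to one of its two construction
#' categories (mitochondrial TCA/OXPHOS proteins without an RNA-binding
#' annotation, and RNA-binding proteins without a mitochondrial annotation).
#'
#' @param x A `TrainingSets` object.
#' @param ... Further arguments passed to methods.
#' @return A character vector of gene identifiers.
#' @examples
#' ts <- TrainingSets(positives = c("g1", "g2"),
#'                    negMitoNonRna = c("g3", "g4"),
#'                    negRnaNonMito = c("g5", "g6"), seed = 1L)
#' positives(ts)
#' negatives(ts, category = "rna_nonmito")
#' @export
setGeneric("positives", function(x, ...) standardGeneric("positives"))

#' @rdname positives
#' @export
setGeneric("negatives", function(x, ...) standardGeneric("negatives"))

#' Accessors for integration results
#'
#' `rankedTable()` returns the full ranked gene table of an
#' [MtRnaRanking-class] as a plain `data.frame`; `geneScores()` returns the
#' per-gene mtRNA scores as a named numeric vector (in rank order);
#' `contributions()` returns the per-gene, per-dataset log2 likelihood-ratio
#' contributions; `binScores()` returns the per-dataset bin score tables; and
#' `priorSpec()` returns the prior used in the integration.
#'
#' @param x An `MtRnaRanking` object.
#' @param ... Further arguments passed to methods.
#' @export
setGeneric("rankedTable", function(x, ...) standardGeneric("rankedTable"))

#' @rdname rankedTable
#' @export
setGeneric("geneScores", function(x, ...) standardGeneric("geneScores"))

#' @rdname rankedTable
#' @export
setGeneric("contributions", function(x, ...) standardGeneric("contributions"))

#' @rdname rankedTable
#' @export
setGeneric("binScores", function(x, ...) standardGeneric("binScores"))

#' @rdname rankedTable
#' @export
setGeneric("priorSpec", function(x, ...) standardGeneric("priorSpec"))
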