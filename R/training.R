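#' @include AllClasses.R
NULL

#' Build the negative training set from GO-flag logic
#'
#' Publications establishing that a protein is *not* mitochondrial or does
#' *not* bind RNA are rare, so the negative set is built from Gene Ontology
#' logic over the annotation table. Category 1 takes every gene that is
#' mitochondrial and belongs to the TCA cycle or OXPHOS — well-studied
#' pathways unlikely to moonlight on mtRNA — but carries no RNA-binding GO
#' term. Category 2 is a seeded uniform random sample, of the same size as
#' category 1 so both contaminant classes contribute equally, drawn from
#' RNA-binding genes without a mitochondrial GO term.
#'
#' @param annotations Annotation `data.frame` with `gene_id` and logical
#'   columns `is_mito_go`, `is_rna_go`, `is_tca_go`, `is_oxphos_go`.
#' @param seed Integer seed for the category-2 sample.
#' @return A list with character vectors `negMitoNonRna` and `negRnaNonMito`.
#' @seealso [buildTrainingSets()]
#' @export
buildNegativeSet <- function(annotations, seed) {
  needed <- c("gene_id", "is_mito_go", "is_rna_go", "is_tca_go", "is_oxphos_go")
  stopifnot(all(needed %in% colnames(annotations)))
  seed <- assertCount(seed, "seed", min = 0L)
  a <- annotations
  cat1 <- a$gene_id[a$is_mito_go & (a$is_tca_go | a$is_oxphos_go) & !a$is_rna_go]
  pool <- a$gene_id[a$is_rna_go & !a$is_mito_go]
  if (!length(cat1)) {
    stop("no genes match the mitochondrial TCA/OXPHOS non-RNA definition")
  }
  if (length(pool) < length(cat1)) {
    stop("RNA-binding non-mitochondrial pool (", length(pool),
         ") is smaller than category 1 (", length(cat1), ")")
  }
  cat2 <- withSeed(seed, sample(pool, length(cat1)))
  list(negMitoNonRna = cat1, negRnaNonMito = cat2)
}

#' Load the curated positive gene list
#'
#' Reads one gene identifier per line, preserving order. Duplicates are
#' dropped with a warning; an empty file is an error. If a gene universe is
#' supplied, identifiers outside it are an error.
#'
#' @param path Path to a plain-text file, one identifier per line.
#' @param universe Optional character vector of valid gene identifiers.
#' @return Character vector of unique gene identifiers.
#' @export
loadPositiveSet <- function(path, universe = NULL) {
  ids <- trimws(readLines(path, warn = FALSE))
  ids <- ids[nzchar(ids)]
  if (!length(ids)) stop("positive-set file '", path, "' is empty")
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    warning("dropping duplicated positive-set identifier(s): ",
            paste(dup, collapse = ", "))
    ids <- ids[!duplicated(ids)]
  }
  if (!is.null(universe)) {
    bad <- setdiff(ids, universe)
    if (length(bad)) {
      stop("positive-set gene(s) absent from the gene universe: ",
           paste(bad, collapse = ", "))
    }
  }
  ids
}

#' Assemble and validate training sets
#'
#' Combines a curated positive list with the GO-rule negative set built by
#' [buildNegativeSet()] into a validated [TrainingSets-class] object.
#'
#' @param positives Character vector of positive gene identifiers, or a path
#'   to a file readable by [loadPositiveSet()].
#' @param annotations Annotation table, see [buildNegativeSet()].
#' @param seed Integer seed for negative-set sampling.
#' @return A `TrainingSets` object.
#' @export
buildTrainingSets <- function(positives, annotations, seed) {
  if (length(positives) == 1L && file.exists(positives)) {
    positives <- loadPositiveSet(positives, universe = annotations$gene_id)
  }
  neg <- buildNegativeSet(annotations, seed)
  # A curated positive can in principle carry the GO flags of category 1;
  # drop it from the negatives rather than fail, the curation wins.
  neg$negMitoNonRna <- setdiff(neg$negMitoNonRna, positives)
  neg$negRnaNonMito <- setdiff(neg$negRnaNonMito, positives)
  sets <- TrainingSets(positives, neg$negMitoNonRna, neg$negRnaNonMito,
                       seed = seed)
  validateTrainingSets(sets, universe = annotations$gene_id)
  sets
}

#' Validate training sets against a gene universe
#'
#' Asserts that the positive set and both negative categories are non-empty,
#' mutually disjoint and contained in the gene universe, and reports their
#' sizes.
#'
#' @param sets A [TrainingSets-class] object.
#' @param universe Character vector of all gene identifiers.
#' @return Invisibly, a named list of set sizes.
#' @export
validateTrainingSets <- function(sets, universe) {
  stopifnot(is(sets, "TrainingSets"))
  methods::validObject(sets)  # disjointness, duplicates, non-emptiness
  if (!length(sets@negMitoNonRna) || !length(sets@negRnaNonMito)) {
    stop("both negative categories must be non-empty")
  }
  all_ids <- c(positives(sets), negatives(sets))
  bad <- setdiff(all_ids, universe)
  if (length(bad)) {
    stop("training gene(s) absent from the gene universe: ",
         paste(utils::head(bad, 10), collapse = ", "))
  }
  invisible(list(n_positives = length(positives(sets)),
                 n_neg_mito_nonrna = length(sets@negMitoNonRna),
                 n_neg_rna_nonmito = length(sets@negRnaNonMito),
                 n_negatives = length(negatives(sets))))
}

#' Write and read training sets as JSON
#'
#' Serializes a [TrainingSets-class] object (gene lists plus the sampling
#' seed) to a JSON file and back.
#'
#' @param sets A `TrainingSets` object.
#' @param path Output/input file path.
#' @return `writeTrainingSets()` returns `path` invisibly;
#'   `readTrainingSets()` returns a `TrainingSets` object.
#' @export
writeTrainingSets <- function(sets, path) {
  stopifnot(is(sets, "TrainingSets"))
  jsonlite::write_json(
    list(positives = positives(sets),
         negatives_mito_nonrna = sets@negMitoNonRna,
         negatives_rna_nonmito = sets@negRnaNonMito,
         seed = sets@seed),
    path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname writeTrainingSets
#' @export
readTrainingSets <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  TrainingSets(x$positives, x$negatives_mito_nonrna, x$negatives_rna_nonmito,
               seed = if (is.null(x$seed)) NA_integer_ else x$seed)
}
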