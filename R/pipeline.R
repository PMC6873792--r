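#' @include evaluate.R simulate.R io.R
NULL

# Assemble the named evidence list the integration consumes from a
# fold-change table and an annotation table.
assembleEvidence <- function(fcTable, annotations) {
  universe <- annotations$gene_id
  combined <- combineApproaches(fcTable)
  combined <- combined[!is.na(combined)]
  named <- function(col) stats::setNames(annotations[[col]], universe)
  drop_na <- function(v) v[!is.na(v)]
  list(
    mtrna_interaction = combined,
    mitochondrial_localization = drop_na(named("mitocarta_score")),
    rna_binding_domain = named("rna_domain"),
    coexpression = drop_na(named("coexpression_score")),
    ppi = drop_na(named("ppi_count")))
}

#' Run the full analysis pipeline
#'
#' Orchestrates the stages end to end: log2 transform and imputation of the
#' LFQ intensities, replicate averaging and per-approach fold-changes,
#' enrichment calling and category fractions, training-set construction,
#' Bayesian evidence integration and ranking, cutoff metrics at a target
#' corrected FDR, and (optionally) ten-fold cross-validation. If `outDir` is
#' given, all report files are written there along with a run log that
#' records seeds, the prior, resolved bin borders and every parameter, so the
#' run can be re-created exactly.
#'
#' @param lfq An [LfqExperiment-class] (linear scale) or a length-2 character
#'   vector `c(lfqPath, samplesPath)` readable by [readLfqTable()].
#' @param annotations Annotation `data.frame` (see [readAnnotations()]) or a
#'   file path. Its `gene_id` column defines the gene universe.
#' @param positives Character vector of positive training genes, or a path to
#'   a one-id-per-line file.
#' @param seed Seed for the negative-set sampling and fold partition.
#' @param fcThreshold Enrichment threshold on the log2 fold-change (default
#'   `log2(3)`).
#' @param nExpected Expected number of mtRNA-interacting genes for the prior
#'   (default 300).
#' @param nGenes Number of genes behind the prior; defaults to the universe
#'   size.
#' @param cfdrTarget Corrected-FDR level at which the predicted set is cut
#'   (default 0.69).
#' @param nBins Bins per continuous evidence track (default 5).
#' @param k Cross-validation folds (default 10).
#' @param crossval Run the ten-fold cross-validation (default `TRUE`).
#' @param outDir Optional output directory for report files.
#' @return A list with `foldChanges`, `enriched` (per-approach id lists),
#'   `categoryFractions` (per approach), `trainingSets`, `ranking`
#'   ([MtRnaRanking-class]), `prior`, `cutoff` (chosen rank/score/metrics),
#'   `metrics` (sensitivity, specificity, cFDR at the cutoff), `report`
#'   (annotation breakdown of the selected set) and, if requested,
#'   `crossValidation`.
#' @examples
#' study <- simulateStudy(simConfig(n_genes = 600, n_true = 60, seed = 3,
#'                                  training_pos_size = 10,
#'                                  training_neg_size_per_category = 15))
#' res <- runPipeline(study$lfq, study$annotations,
#'                    positives(study$trainingSets),
#'                    nExpected = 60, k = 5)
#' res$metrics
#' @export
runPipeline <- function(lfq, annotations, positives, seed = 1L,
                        fcThreshold = log2(3), nExpected = 300L,
                        nGenes = NULL, cfdrTarget = 0.69, nBins = 5L,
                        k = 10L, crossval = TRUE, outDir = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  lfq <- stage("read-lfq", {
    if (is.character(lfq)) {
      stopifnot(length(lfq) == 2L)
      readLfqTable(lfq[[1L]], lfq[[2L]])
    } else {
      stopifnot(is(lfq, "LfqExperiment"))
      lfq
    }
  })
  annotations <- stage("read-annotations", {
    if (is.character(annotations)) readAnnotations(annotations) else annotations
  })
  universe <- annotations$gene_id
  bad <- setdiff(rownames(lfq), universe)
  if (length(bad)) {
    stop("LFQ protein(s) absent from the annotation universe: ",
         paste(utils::head(bad, 5), collapse = ", "))
  }

  fct <- stage("process-lfq", {
    foldChangeTable(log2TransformAndImpute(lfq))
  })
  approaches <- intersect(.APPROACHES,
                          sub("^log2_fc_", "",
                              grep("^log2_fc_", colnames(fct), value = TRUE)))
  enriched <- lapply(stats::setNames(nm = approaches), function(a) {
    classifyEnriched(fct, a, threshold = fcThreshold)
  })
  fractions <- lapply(enriched, categoryFractions, annotations = annotations)

  sets <- stage("build-training", buildTrainingSets(positives, annotations,
                                                    seed = seed))

  prior <- computeOprior(nExpected,
                         if (is.null(nGenes)) length(universe) else nGenes)
  evidence <- assembleEvidence(fct, annotations)
  tie_break <- combineApproaches(fct)
  ranking <- stage("integrate", {
    integrateEvidence(evidence, sets, prior, universe = universe,
                      tieBreak = tie_break, nBins = nBins)
  })

  cutoff <- stage("evaluate", cutoffForCfdr(ranking, sets, prior, cfdrTarget))
  metrics <- confusionAtCutoff(ranking, sets, cutoff$cutoff_score)
  metrics$cFDR <- correctedFdr(metrics$sensitivity, metrics$specificity,
                               prior$priorOdds)
  metrics$cFDR_percent <- roundHalfUp(100 * metrics$cFDR)
  report <- reportIdentifiedSet(ranking, annotations, cutoff$cutoff_score)

  cv <- NULL
  if (isTRUE(crossval)) {
    cv <- stage("crossval", {
      crossValidate(evidence, sets, prior, k = k, seed = seed,
                    universe = universe, tieBreak = tie_break, nBins = nBins)
    })
  }

  result <- list(foldChanges = fct, enriched = enriched,
                 categoryFractions = fractions, trainingSets = sets,
                 ranking = ranking, prior = prior, cutoff = cutoff,
                 metrics = metrics, report = report, crossValidation = cv)

  if (!is.null(outDir)) {
    stage("write-reports", {
      dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
      writeFoldChangeTable(fct, file.path(outDir, "fold_changes.tsv"))
      writeRankedTable(ranking, file.path(outDir, "ranked_genes.tsv"))
      writeTrainingSets(sets, file.path(outDir, "training_sets.json"))
      jsonlite::write_json(
        list(cutoff = cutoff, metrics = metrics,
             category_fractions = fractions, identified_set = report,
             cv_auc = if (!is.null(cv)) cv$auc else NULL),
        file.path(outDir, "metrics.json"),
        auto_unbox = TRUE, pretty = TRUE, digits = NA, force = TRUE)
      if (!is.null(cv)) {
        utils::write.table(cv$heldOut,
                           file.path(outDir, "crossval_heldout_ranks.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        utils::write.table(cv$roc$points, file.path(outDir, "roc_points.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      }
      borders <- lapply(binScores(ranking), function(t) t$bin)
      writeRunLog(list(seed = seed, prior = prior,
                       parameters = list(fcThreshold = fcThreshold,
                                         cfdrTarget = cfdrTarget,
                                         nBins = nBins, k = k),
                       bins = borders),
                  file.path(outDir, "run_log.json"))
    })
  }
  result
}

#' Annotation breakdown of the predicted set
#'
#' Partitions the genes selected at a score cutoff into the four annotation
#' quadrants — mitochondrial with an RNA-binding GO term, mitochondrial only,
#' RNA-binding only, neither — mirroring how a predicted mtRNA interactome is
#' summarized. The four counts always sum to the selection size.
#'
#' @param ranking An [MtRnaRanking-class].
#' @param annotations Annotation `data.frame` covering the universe.
#' @param cutoffScore Score threshold (inclusive).
#' @param mitoColumn,rnaColumn Annotation columns, as in
#'   [categoryFractions()].
#' @return Named list of counts: `n_selected`, `mito_rna`, `mito_only`,
#'   `rna_only`, `neither`.
#' @export
reportIdentifiedSet <- function(ranking, annotations, cutoffScore,
                                mitoColumn = "is_mitocarta",
                                rnaColumn = "is_rna_go") {
  stopifnot(is(ranking, "MtRnaRanking"))
  s <- geneScores(ranking)
  selected <- names(s)[s >= cutoffScore]
  idx <- match(selected, annotations$gene_id)
  if (anyNA(idx)) {
    stop("selected gene(s) absent from annotation table: ",
         paste(utils::head(selected[is.na(idx)], 5), collapse = ", "))
  }
  mito <- annotations[[mitoColumn]][idx]
  rna <- annotations[[rnaColumn]][idx]
  list(n_selected = length(selected),
       mito_rna = sum(mito & rna),
       mito_only = sum(mito & !rna),
       rna_only = sum(!mito & rna),
       neither = sum(!mito & !rna))
}
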