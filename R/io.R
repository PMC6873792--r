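#' @include AllClasses.R
NULL

# TSV dialect used throughout: UTF-8, tab-separated, header row, '.' decimal
# separator, "NA" for missing, scores written with 6 decimals.

#' Read an LFQ table and its sample sheet
#'
#' Reads a tab-separated LFQ intensity table (first column gene/protein
#' identifier, remaining columns samples, empty or `NA` cells for missing
#' quantifications) together with a sample sheet mapping each sample column
#' to approach, condition and replicate indices.
#'
#' @param lfqPath Path to the intensity TSV.
#' @param samplesPath Path to the sample-sheet TSV with columns `sample_id`,
#'   `approach`, `condition`, `biological_rep`, `technical_rep`.
#' @return An [LfqExperiment-class] on the linear scale.
#' @export
readLfqTable <- function(lfqPath, samplesPath) {
  tab <- utils::read.delim(lfqPath, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop("LFQ table needs an id column and >= 1 sample")
  ids <- as.character(tab[[1L]])
  if (anyDuplicated(ids)) stop("duplicated gene identifiers in LFQ table")
  m <- as.matrix(tab[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  samples <- utils::read.delim(samplesPath, stringsAsFactors = FALSE)
  LfqExperiment(m, samples)
}

#' Write an LFQ matrix and sample sheet
#'
#' Inverse of [readLfqTable()]; exports the linear intensities and the sample
#' annotations of an [LfqExperiment-class] to two TSV files.
#'
#' @param x An `LfqExperiment`.
#' @param lfqPath,samplesPath Output paths.
#' @return Invisibly, `c(lfqPath, samplesPath)`.
#' @export
writeLfqTable <- function(x, lfqPath, samplesPath) {
  stopifnot(is(x, "LfqExperiment"))
  m <- SummarizedExperiment::assay(x, "intensities")
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, lfqPath, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  cd <- as.data.frame(SummarizedExperiment::colData(x))
  utils::write.table(cd, samplesPath, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(c(lfqPath, samplesPath))
}

#' Read / write the annotation table
#'
#' The annotation TSV has one row per gene: `gene_id`, logical GO flags
#' (`is_mito_go`, `is_rna_go`, `is_tca_go`, `is_oxphos_go`), `is_mitocarta`,
#' `mitocarta_score`, `rna_domain`, `coexpression_score`, `ppi_count`.
#'
#' @param path File path.
#' @return `readAnnotations()` returns the annotation `data.frame`.
#' @export
readAnnotations <- function(path) {
  a <- utils::read.delim(path, stringsAsFactors = FALSE)
  flags <- intersect(c("is_mito_go", "is_rna_go", "is_tca_go",
                       "is_oxphos_go", "is_mitocarta", "rna_domain"),
                     colnames(a))
  for (f in flags) a[[f]] <- as.logical(a[[f]])
  if (anyDuplicated(a$gene_id)) stop("duplicated gene_id in annotation table")
  a
}

#' @rdname readAnnotations
#' @param annotations Annotation `data.frame`.
#' @export
writeAnnotations <- function(annotations, path) {
  utils::write.table(annotations, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Write the per-gene fold-change table
#'
#' @param fcTable Table from [foldChangeTable()].
#' @param path Output TSV path.
#' @export
writeFoldChangeTable <- function(fcTable, path) {
  out <- fcTable
  num <- vapply(out, is.double, logical(1))
  out[num] <- lapply(out[num], function(v) {
    s <- formatC(v, digits = 6, format = "f")
    s[is.na(v)] <- "NA"
    s
  })
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Write the ranked integration result
#'
#' Exports [rankedTable()] as TSV. Scores and contributions are written with
#' 10 decimals so that re-ranking the read-back table reproduces the stored
#' ranks (6 decimals can collapse genuinely distinct scores into spurious
#' ties).
#'
#' @param ranking An [MtRnaRanking-class].
#' @param path Output TSV path.
#' @export
writeRankedTable <- function(ranking, path) {
  rk <- rankedTable(ranking)
  num <- vapply(rk, is.double, logical(1))
  rk[num] <- lapply(rk[num], function(v) {
    out <- formatC(v, digits = 10, format = "f")
    out[is.na(v)] <- "NA"
    out
  })
  utils::write.table(rk, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Write the run log
#'
#' Records everything needed to re-create a run: package version, seeds,
#' prior, resolved bin borders and all stage parameters, as pretty JSON.
#'
#' @param log Named list of run metadata.
#' @param path Output JSON path.
#' @export
writeRunLog <- function(log, path) {
  log$package <- as.character(utils::packageVersion("mtRIpred"))
  log$r_version <- R.version.string
  log$timestamp <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  jsonlite::write_json(log, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, force = TRUE)
  invisible(path)
}

#' Export a synthetic study to pipeline input files
#'
#' Writes the LFQ matrix, sample sheet, annotation table, positive gene list
#' and ground truth of a [simulateStudy()] result into a directory, in
#' exactly the TSV formats the pipeline readers consume.
#'
#' @param study A list from [simulateStudy()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named character vector of the written paths.
#' @export
writeStudy <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(lfq = file.path(dir, "lfq_intensities.tsv"),
             samples = file.path(dir, "sample_sheet.tsv"),
             annotations = file.path(dir, "annotations.tsv"),
             positives = file.path(dir, "positive_set.txt"),
             truth = file.path(dir, "ground_truth.tsv"))
  writeLfqTable(study$lfq, paths["lfq"], paths["samples"])
  writeAnnotations(study$annotations, paths["annotations"])
  writeLines(positives(study$trainingSets), paths["positives"])
  utils::write.table(study$truth, paths["truth"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}
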