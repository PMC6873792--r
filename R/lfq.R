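#' @include AllClasses.R
NULL

#' Log2-transform LFQ intensities and impute missing values
#'
#' Transforms linear LFQ intensities to the log2 scale and replaces missing
#' values with the lowest log2 intensity actually measured — the conventional
#' low-abundance floor for label-free data, where a missing quantification
#' most often means the protein was below the detection limit. By default the
#' floor is the global minimum over the whole matrix; `floor = "per_sample"`
#' uses each sample's own minimum instead.
#'
#' @param x An [LfqExperiment-class] on the linear scale.
#' @param floor `"global"` (default) or `"per_sample"`.
#' @return An `LfqExperiment` on the log2 scale with an added logical
#'   `"imputed"` assay flagging filled-in cells and
#'   `metadata(x)$imputeFloor` recording the floor value(s).
#' @examples
#' m <- matrix(c(8, 4, NA, 16), nrow = 2,
#'             dimnames = list(c("A", "B"), c("s1", "s2")))
#' sm <- data.frame(sample_id = c("s1", "s2"), approach = "MXL",
#'                  condition = c("crosslinked", "control"),
#'                  biological_rep = 1L, technical_rep = 1L)
#' lfq <- log2TransformAndImpute(LfqExperiment(m, sm))
#' SummarizedExperiment::assay(lfq, "intensities")
#' @export
log2TransformAndImpute <- function(x, floor = c("global", "per_sample")) {
  stopifnot(is(x, "LfqExperiment"))
  floor <- match.arg(floor)
  if (isLog2(x)) stop("intensities are already log2-transformed")
  m <- SummarizedExperiment::assay(x, "intensities")
  present <- !is.na(m)
  if (!any(present)) stop("nothing to impute from: no measured intensities")
  if (any(m[present] <= 0)) {
    stop("non-positive intensities present; linear LFQ values must be > 0")
  }
  lm <- log2(m)
  lm[!present] <- NA_real_
  if (floor == "global") {
    fl <- min(lm, na.rm = TRUE)
    lm[!present] <- fl
  } else {
    fl <- apply(lm, 2L, min, na.rm = TRUE)
    fl[!is.finite(fl)] <- min(lm, na.rm = TRUE)  # column with nothing measured
    idx <- which(!present, arr.ind = TRUE)
    lm[idx] <- fl[idx[, 2L]]
  }
  out <- x
  SummarizedExperiment::assay(out, "intensities") <- lm
  SummarizedExperiment::assays(out)$imputed <- !present
  S4Vectors::metadata(out)$log2 <- TRUE
  S4Vectors::metadata(out)$imputeFloor <- fl
  out
}

#' Average technical and biological replicates
#'
#' Reduces the log2 LFQ matrix to one mean value per protein for a given
#' approach/condition pair. The default averages hierarchically — technical
#' replicates within each biological replicate first, then across biological
#' replicates — so that unequal technical-replicate counts do not weight one
#' biological replicate more than another. `method = "flat"` takes a plain
#' mean over all matching samples.
#'
#' @param x An [LfqExperiment-class] on the log2 scale.
#' @param approach One of `"MXL"`, `"WCXL"`, `"WCXL_EtBr"`.
#' @param condition `"crosslinked"` or `"control"`.
#' @param method `"hierarchical"` (default) or `"flat"`.
#' @return Named numeric vector, one mean log2 intensity per protein.
#' @export
averageReplicates <- function(x, approach, condition,
                              method = c("hierarchical", "flat")) {
  stopifnot(is(x, "LfqExperiment"))
  method <- match.arg(method)
  if (!isLog2(x)) stop("call log2TransformAndImpute() first")
  cd <- SummarizedExperiment::colData(x)
  sel <- cd$approach == approach & cd$condition == condition
  if (!any(sel)) {
    stop("no samples for approach '", approach, "', condition '", condition, "'")
  }
  m <- SummarizedExperiment::assay(x, "intensities")[, sel, drop = FALSE]
  if (method == "flat" || ncol(m) == 1L) {
    return(rowMeans(m))
  }
  bio <- cd$biological_rep[sel]
  groups <- split(seq_len(ncol(m)), bio)
  per_bio <- matrix(0, nrow = nrow(m), ncol = length(groups),
                    dimnames = list(rownames(m), names(groups)))
  for (g in seq_along(groups)) {
    per_bio[, g] <- rowMeans(m[, groups[[g]], drop = FALSE])
  }
  rowMeans(per_bio)
}

#' Log2 fold-change of crosslinked over control
#'
#' The difference of mean log2 LFQ intensities, crosslinked minus control.
#' For the `WCXL_EtBr` approach the "control" means are those of the
#' crosslinked, EtBr-treated samples.
#'
#' @param xlMean,controlMean Finite numeric vectors (typically named by gene)
#'   of mean log2 intensities.
#' @return `xlMean - controlMean`.
#' @examples
#' computeFoldChange(10, 8)
#' @export
computeFoldChange <- function(xlMean, controlMean) {
  if (anyNA(xlMean) || anyNA(controlMean) ||
      any(!is.finite(xlMean)) || any(!is.finite(controlMean))) {
    stop("means must be finite; impute before computing fold-changes")
  }
  xlMean - controlMean
}

#' Per-approach fold-change table with combined evidence value
#'
#' Runs replicate averaging and fold-change computation for every approach
#' present in the experiment and assembles the per-gene table consumed by
#' enrichment calling and the Bayesian integration. A protein counts as
#' *detected* in an approach if it has at least one measured (non-imputed)
#' intensity among that approach's samples; fold-changes of undetected
#' proteins are reported as `NA`. The combined mtRNA-interaction evidence
#' value (`combined_log2_fc`) averages the MXL and WCXL fold-changes where
#' both are detected and passes through the single available value otherwise;
#' WCXL_EtBr is reported but never enters the combined track.
#'
#' @param x An [LfqExperiment-class] on the log2 scale (imputed).
#' @param averaging Replicate-averaging method, see [averageReplicates()].
#' @return `data.frame` with `gene_id`, per-approach `log2_fc_<approach>` and
#'   `detected_<approach>` columns, and `combined_log2_fc`.
#' @export
foldChangeTable <- function(x, averaging = c("hierarchical", "flat")) {
  stopifnot(is(x, "LfqExperiment"))
  averaging <- match.arg(averaging)
  if (!isLog2(x)) stop("call log2TransformAndImpute() first")
  cd <- SummarizedExperiment::colData(x)
  approaches <- intersect(.APPROACHES, unique(cd$approach))
  imp <- imputedMask(x)
  out <- data.frame(gene_id = rownames(x), stringsAsFactors = FALSE)
  for (a in approaches) {
    xl <- averageReplicates(x, a, "crosslinked", method = averaging)
    ct <- averageReplicates(x, a, "control", method = averaging)
    fc <- computeFoldChange(xl, ct)
    det <- rowSums(!imp[, cd$approach == a, drop = FALSE]) > 0
    fc[!det] <- NA_real_
    out[[paste0("log2_fc_", a)]] <- fc
    out[[paste0("detected_", a)]] <- det
  }
  out$combined_log2_fc <- combineApproaches(out)
  out
}

#' Combine MXL and WCXL fold-changes into the mtRNA-interaction track
#'
#' Mean of the mitochondrial-crosslinking (MXL) and whole-cell-crosslinking
#' (WCXL) log2 fold-changes where a protein is detected in both approaches;
#' the single available value where only one approach detected it; `NA` where
#' neither did (such genes land in the missing bin of the integration).
#'
#' @param fcTable A fold-change table as produced by [foldChangeTable()],
#'   with `log2_fc_MXL` and/or `log2_fc_WCXL` columns.
#' @return Numeric vector of combined log2 fold-changes, named by gene.
#' @export
combineApproaches <- function(fcTable) {
  cols <- intersect(c("log2_fc_MXL", "log2_fc_WCXL"), colnames(fcTable))
  if (!length(cols)) {
    return(stats::setNames(rep(NA_real_, nrow(fcTable)), fcTable$gene_id))
  }
  m <- as.matrix(fcTable[, cols, drop = FALSE])
  combined <- rowMeans(m, na.rm = TRUE)
  combined[!rowSums(!is.na(m))] <- NA_real_
  stats::setNames(combined, fcTable$gene_id)
}

#' Call enriched proteins in one approach
#'
#' Proteins detected in the approach whose log2 fold-change reaches the
#' enrichment threshold, by default a three-fold change (`log2(3)`),
#' boundary included.
#'
#' @param fcTable A fold-change table from [foldChangeTable()].
#' @param approach Approach whose fold-changes to threshold.
#' @param threshold Log2 fold-change threshold; default `log2(3)`.
#' @param inclusive Include proteins exactly at the threshold (default
#'   `TRUE`).
#' @return Character vector of enriched gene identifiers.
#' @export
classifyEnriched <- function(fcTable, approach, threshold = log2(3),
                             inclusive = TRUE) {
  assertFlag(inclusive, "inclusive")
  col <- paste0("log2_fc_", approach)
  if (!col %in% colnames(fcTable)) {
    stop("unknown approach '", approach, "': no column '", col, "'")
  }
  fc <- fcTable[[col]]
  hit <- !is.na(fc) & (if (inclusive) fc >= threshold else fc > threshold)
  fcTable$gene_id[hit]
}

#' Annotation-category composition of an enriched protein set
#'
#' Counts how many enriched proteins are annotated mitochondrial, carry the
#' RNA-binding GO term, or both, and reports integer-rounded percentages —
#' the method-comparison statistic for crosslinking approaches: a more
#' mitochondrially targeted approach yields a higher mitochondrial fraction
#' among its enriched proteins.
#'
#' @param enriched Character vector of enriched gene identifiers.
#' @param annotations Annotation `data.frame` with a `gene_id` column and the
#'   logical columns named by `mitoColumn` / `rnaColumn`.
#' @param mitoColumn Column flagging mitochondrial annotation (default
#'   `"is_mitocarta"`, the curated localization inventory).
#' @param rnaColumn Column flagging the RNA-binding GO term (default
#'   `"is_rna_go"`).
#' @return A list with `n_enriched`, `n_mito`, `n_rna_go`,
#'   `n_mito_and_rna_go` and the corresponding integer percentages
#'   `pct_mito`, `pct_rna_go`, `pct_mito_and_rna_go` (round half up).
#' @export
categoryFractions <- function(enriched, annotations,
                              mitoColumn = "is_mitocarta",
                              rnaColumn = "is_rna_go") {
  stopifnot(is.character(enriched),
            all(c("gene_id", mitoColumn, rnaColumn) %in% colnames(annotations)))
  idx <- match(enriched, annotations$gene_id)
  if (anyNA(idx)) {
    bad <- enriched[is.na(idx)]
    stop("enriched gene(s) absent from annotation table: ",
         paste(utils::head(bad, 10), collapse = ", "),
         if (length(bad) > 10) sprintf(" (and %d more)", length(bad) - 10))
  }
  mito <- annotations[[mitoColumn]][idx]
  rna <- annotations[[rnaColumn]][idx]
  n <- length(enriched)
  counts <- list(n_enriched = n,
                 n_mito = sum(mito),
                 n_rna_go = sum(rna),
                 n_mito_and_rna_go = sum(mito & rna))
  pct <- function(k) if (n == 0L) NA_real_ else roundHalfUp(100 * k / n)
  c(counts, list(pct_mito = pct(counts$n_mito),
                 pct_rna_go = pct(counts$n_rna_go),
                 pct_mito_and_rna_go = pct(counts$n_mito_and_rna_go)))
}

#' Sensitivity against a reference gene set
#'
#' The fraction of a reference set (e.g. the mitochondrial proteins that
#' carry an RNA-binding GO term) recovered by a hit list, reported to three
#' decimals.
#'
#' @param nHitsInReference Number of hits that belong to the reference set.
#' @param nReference Size of the reference set (> 0).
#' @return Sensitivity, rounded to 3 decimals.
#' @examples
#' overlapSensitivity(53, 180)
#' @export
overlapSensitivity <- function(nHitsInReference, nReference) {
  if (!is.numeric(nReference) || length(nReference) != 1L || nReference <= 0) {
    stop("'nReference' must be a single positive number")
  }
  if (!is.numeric(nHitsInReference) || length(nHitsInReference) != 1L ||
      nHitsInReference < 0 || nHitsInReference > nReference) {
    stop("'nHitsInReference' must lie in [0, nReference]")
  }
  roundHalfUp(nHitsInReference / nReference, 3)
}
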