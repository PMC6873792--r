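#' @include training.R
NULL

#' Configuration of the synthetic study generator
#'
#' Bundles and validates all parameters of the synthetic-data module. The
#' defaults emulate the study conditions of a mitochondrial poly(A) RNA
#' interactome capture experiment: a reference proteome of 20129 gene-level
#' entries of which ~300 are expected to interact with mtRNA, three
#' biological replicates with two technical replicates per condition, a
#' crosslinking enrichment of 2.5 log2 units for true interactors with
#' replicate noise of 0.8 log2 units, heavy missingness for unenriched
#' background proteins, a 24-gene positive training set and two 124-gene
#' negative categories.
#'
#' @param n_genes Size of the gene universe (default 20129; down-scalable).
#' @param n_true Number of true mtRNA-interacting genes (default 300).
#' @param seed Master seed for all generator randomness.
#' @param lfq_effect Log2 intensity shift of true interactors in crosslinked
#'   samples (default 2.5).
#' @param lfq_noise_sd Per-sample Gaussian noise, log2 units (default 0.8).
#' @param missing_rate_background,missing_rate_detected Per-cell missingness
#'   probability for background genes (default 0.6) and for true interactors
#'   (default 0.1).
#' @param n_bioreps,n_techreps Replicates per condition (defaults 3 and 2).
#' @param wcxl_attenuation Multiplier on `lfq_effect` in the whole-cell
#'   approach, encoding its lower specificity (default 0.6).
#' @param wcxl_contaminant_shift Log2 shift of cytosolic RNA binders in
#'   crosslinked WCXL samples — the contaminant class whole-cell crosslinking
#'   co-purifies (default 1.5).
#' @param mito_flag_tpr,mito_flag_fpr Rates for the mitochondrial annotation
#'   flag given the true localization (defaults 0.95 / 0.02).
#' @param rna_domain_tpr,rna_domain_fpr Rates for the RNA-binding-domain flag
#'   given true RNA binding (defaults 0.6 / 0.05).
#' @param coexpr_shift Mean shift of the co-expression score for true
#'   interactors (default 1.5; unit-variance Gaussian track).
#' @param ppi_lambda_pos,ppi_lambda_neg Poisson means of the
#'   interaction-partner count for interactors and others (defaults 3 / 0.3).
#' @param mitocarta_shift Mean separation of the localization likelihood
#'   score between mitochondrial and other genes (default 3).
#' @param mitocarta_coverage_bg Fraction of non-flagged genes that still
#'   carry a localization score (default 0.1); flagged genes always do.
#' @param frac_mito_extra Fraction of the universe that is mitochondrial but
#'   does not interact with mtRNA (default 0.08).
#' @param frac_cyto_rna Fraction that binds RNA but is not mitochondrial
#'   (default 0.08).
#' @param go_noise Probability of flipping each derived GO flag (default 0).
#' @param baseline_mean,baseline_sd Per-gene baseline log2 LFQ intensity
#'   distribution (defaults 25 / 2).
#' @param training_pos_size Positive training-set size (default 24).
#' @param training_neg_size_per_category Genes flagged TCA/OXPHOS, i.e. the
#'   size of negative category 1 and hence of each category (default 124).
#' @return A validated list of class `SimulationConfig`.
#' @export
simConfig <- function(n_genes = 20129L, n_true = 300L, seed = 1L,
                      lfq_effect = 2.5, lfq_noise_sd = 0.8,
                      missing_rate_background = 0.6,
                      missing_rate_detected = 0.1,
                      n_bioreps = 3L, n_techreps = 2L,
                      wcxl_attenuation = 0.6, wcxl_contaminant_shift = 1.5,
                      mito_flag_tpr = 0.95, mito_flag_fpr = 0.02,
                      rna_domain_tpr = 0.6, rna_domain_fpr = 0.05,
                      coexpr_shift = 1.5,
                      ppi_lambda_pos = 3, ppi_lambda_neg = 0.3,
                      mitocarta_shift = 3, mitocarta_coverage_bg = 0.1,
                      frac_mito_extra = 0.08, frac_cyto_rna = 0.08,
                      go_noise = 0,
                      baseline_mean = 25, baseline_sd = 2,
                      training_pos_size = 24L,
                      training_neg_size_per_category = 124L) {
  cfg <- list(
    n_genes = assertCount(n_genes, "n_genes", min = 10L),
    n_true = assertCount(n_true, "n_true"),
    seed = assertCount(seed, "seed", min = 0L),
    lfq_effect = as.numeric(lfq_effect),
    lfq_noise_sd = as.numeric(lfq_noise_sd),
    missing_rate_background = assertProb(missing_rate_background,
                                         "missing_rate_background"),
    missing_rate_detected = assertProb(missing_rate_detected,
                                       "missing_rate_detected"),
    n_bioreps = assertCount(n_bioreps, "n_bioreps"),
    n_techreps = assertCount(n_techreps, "n_techreps"),
    wcxl_attenuation = as.numeric(wcxl_attenuation),
    wcxl_contaminant_shift = as.numeric(wcxl_contaminant_shift),
    mito_flag_tpr = assertProb(mito_flag_tpr, "mito_flag_tpr"),
    mito_flag_fpr = assertProb(mito_flag_fpr, "mito_flag_fpr"),
    rna_domain_tpr = assertProb(rna_domain_tpr, "rna_domain_tpr"),
    rna_domain_fpr = assertProb(rna_domain_fpr, "rna_domain_fpr"),
    coexpr_shift = as.numeric(coexpr_shift),
    ppi_lambda_pos = as.numeric(ppi_lambda_pos),
    ppi_lambda_neg = as.numeric(ppi_lambda_neg),
    mitocarta_shift = as.numeric(mitocarta_shift),
    mitocarta_coverage_bg = assertProb(mitocarta_coverage_bg,
                                       "mitocarta_coverage_bg"),
    frac_mito_extra = assertProb(frac_mito_extra, "frac_mito_extra"),
    frac_cyto_rna = assertProb(frac_cyto_rna, "frac_cyto_rna"),
    go_noise = assertProb(go_noise, "go_noise"),
    baseline_mean = as.numeric(baseline_mean),
    baseline_sd = as.numeric(baseline_sd),
    training_pos_size = assertCount(training_pos_size, "training_pos_size"),
    training_neg_size_per_category =
      assertCount(training_neg_size_per_category,
                  "training_neg_size_per_category"))
  if (cfg$n_true >= cfg$n_genes) stop("'n_true' must be smaller than 'n_genes'")
  if (cfg$lfq_noise_sd < 0 || cfg$baseline_sd < 0) {
    stop("standard deviations must be non-negative")
  }
  if (cfg$ppi_lambda_pos < 0 || cfg$ppi_lambda_neg < 0) {
    stop("Poisson means must be non-negative")
  }
  class(cfg) <- "SimulationConfig"
  cfg
}

#' Null configuration with every signal removed
#'
#' A convenience wrapper around [simConfig()] that zeroes all effects and
#' shifts and equalizes all class-conditional rates, so that no evidence
#' track carries information about the true interactors. Used to check that
#' the pipeline's AUC degrades to chance.
#'
#' @param ... Overrides passed to [simConfig()] (e.g. `n_genes`, `seed`).
#' @return A `SimulationConfig`.
#' @export
nullSimConfig <- function(...) {
  simConfig(lfq_effect = 0, wcxl_contaminant_shift = 0,
            coexpr_shift = 0, mitocarta_shift = 0,
            ppi_lambda_pos = 0.3, ppi_lambda_neg = 0.3,
            mito_flag_tpr = 0.1, mito_flag_fpr = 0.1,
            rna_domain_tpr = 0.1, rna_domain_fpr = 0.1,
            missing_rate_detected = 0.6, missing_rate_background = 0.6,
            mitocarta_coverage_bg = 0.1,
            ...)
}

#' Generate the gene universe and ground truth
#'
#' Assigns, under the configuration seed, `n_true` genes as true mtRNA
#' interactors (all mitochondrial), a surplus of mitochondrial genes that do
#' not interact with mtRNA, and a class of cytosolic RNA binders — the two
#' contaminant classes the negative training set encodes.
#'
#' @param config A [simConfig()] object.
#' @return `data.frame` with `gene_id`, `is_mtRNA_interactor`,
#'   `is_mitochondrial`, `is_cytosolic_rna_binder`.
#' @export
generateUniverse <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  n <- config$n_genes
  ids <- sprintf("G%0*d", nchar(n), seq_len(n))
  n_mito_extra <- round(config$frac_mito_extra * n)
  n_cyto <- round(config$frac_cyto_rna * n)
  if (config$n_true + n_mito_extra + n_cyto > n) {
    stop("signal classes exceed the universe; lower n_true or the fractions")
  }
  roles <- withSeed(config$seed, sample(n, config$n_true + n_mito_extra + n_cyto))
  interactor <- roles[seq_len(config$n_true)]
  mito_extra <- roles[config$n_true + seq_len(n_mito_extra)]
  cyto <- roles[config$n_true + n_mito_extra + seq_len(n_cyto)]
  data.frame(
    gene_id = ids,
    is_mtRNA_interactor = seq_len(n) %in% interactor,
    is_mitochondrial = seq_len(n) %in% c(interactor, mito_extra),
    is_cytosolic_rna_binder = seq_len(n) %in% cyto,
    stringsAsFactors = FALSE)
}

#' Generate synthetic LFQ intensity matrices
#'
#' Draws a per-gene baseline log2 intensity, shifts crosslinked samples of
#' true interactors by `lfq_effect` (full effect in the mitochondrial
#' crosslinking approach, attenuated in the whole-cell approach, where
#' cytosolic RNA binders additionally receive a contaminant shift), adds
#' Gaussian replicate noise, applies class-dependent missingness, and exports
#' on the linear scale as one [LfqExperiment-class] covering both approaches.
#'
#' @param truth Ground truth from [generateUniverse()].
#' @param config A [simConfig()] object.
#' @return An `LfqExperiment` (linear scale) with MXL and WCXL samples.
#' @export
generateLfq <- function(truth, config) {
  stopifnot(inherits(config, "SimulationConfig"))
  n <- nrow(truth)
  sm <- expand.grid(technical_rep = seq_len(config$n_techreps),
                    biological_rep = seq_len(config$n_bioreps),
                    condition = .CONDITIONS,
                    approach = c("MXL", "WCXL"),
                    stringsAsFactors = FALSE)
  sm$sample_id <- sprintf("%s_%s_b%d_t%d", sm$approach,
                          ifelse(sm$condition == "crosslinked", "xl", "ctl"),
                          sm$biological_rep, sm$technical_rep)
  sm <- sm[, c("sample_id", "approach", "condition",
               "biological_rep", "technical_rep")]

  withSeed(config$seed + 1L, {
    baseline <- stats::rnorm(n, config$baseline_mean, config$baseline_sd)
    m <- matrix(NA_real_, nrow = n, ncol = nrow(sm),
                dimnames = list(truth$gene_id, sm$sample_id))
    for (j in seq_len(nrow(sm))) {
      shift <- numeric(n)
      if (sm$condition[j] == "crosslinked") {
        if (sm$approach[j] == "MXL") {
          shift[truth$is_mtRNA_interactor] <- config$lfq_effect
        } else {
          shift[truth$is_mtRNA_interactor] <-
            config$lfq_effect * config$wcxl_attenuation
          shift[truth$is_cytosolic_rna_binder] <-
            shift[truth$is_cytosolic_rna_binder] + config$wcxl_contaminant_shift
        }
      }
      m[, j] <- baseline + shift + stats::rnorm(n, 0, config$lfq_noise_sd)
    }
    miss_p <- ifelse(truth$is_mtRNA_interactor,
                     config$missing_rate_detected,
                     config$missing_rate_background)
    miss <- matrix(stats::runif(length(m)) < miss_p, nrow = n)
    m[miss] <- NA_real_
    LfqExperiment(2^m, sm)
  })
}

#' Generate synthetic annotation and evidence tracks
#'
#' Produces the per-gene annotation table the integration consumes:
#' a mitochondrial-localization likelihood score (higher-location Gaussian
#' for mitochondrial genes, with configurable background coverage and a
#' membership flag drawn at class-conditional rates), an RNA-binding-domain
#' flag, a co-expression score shifted for true interactors, a Poisson count
#' of interaction partners among known mtRNA interactors, and the four GO
#' flags derived from truth (TCA/OXPHOS flags mark
#' `training_neg_size_per_category` mitochondrial non-RNA genes, the pool the
#' negative set is built from).
#'
#' @param truth Ground truth from [generateUniverse()].
#' @param config A [simConfig()] object.
#' @return Annotation `data.frame` (one row per gene).
#' @export
generateAnnotations <- function(truth, config) {
  stopifnot(inherits(config, "SimulationConfig"))
  n <- nrow(truth)
  rna_true <- truth$is_mtRNA_interactor | truth$is_cytosolic_rna_binder
  withSeed(config$seed + 2L, {
    flip <- function(x) {
      if (config$go_noise > 0) {
        xor(x, stats::runif(n) < config$go_noise)
      } else {
        x
      }
    }
    is_mito_go <- flip(truth$is_mitochondrial)
    is_rna_go <- flip(rna_true)

    pool <- which(truth$is_mitochondrial & !rna_true)
    if (length(pool) < config$training_neg_size_per_category) {
      stop("not enough mitochondrial non-RNA genes to flag TCA/OXPHOS")
    }
    flagged <- sample(pool, config$training_neg_size_per_category)
    half <- length(flagged) %/% 2L
    is_tca_go <- seq_len(n) %in% flagged[seq_len(half)]
    is_oxphos_go <- seq_len(n) %in% setdiff(flagged, flagged[seq_len(half)])

    is_mitocarta <- ifelse(truth$is_mitochondrial,
                           stats::runif(n) < config$mito_flag_tpr,
                           stats::runif(n) < config$mito_flag_fpr)
    has_score <- is_mitocarta | stats::runif(n) < config$mitocarta_coverage_bg
    mitocarta_score <- stats::rnorm(
      n, mean = ifelse(truth$is_mitochondrial, config$mitocarta_shift, 0))
    mitocarta_score[!has_score] <- NA_real_

    rna_domain <- ifelse(rna_true,
                         stats::runif(n) < config$rna_domain_tpr,
                         stats::runif(n) < config$rna_domain_fpr)
    coexpression_score <- stats::rnorm(
      n, mean = ifelse(truth$is_mtRNA_interactor, config$coexpr_shift, 0))
    ppi_count <- stats::rpois(
      n, lambda = ifelse(truth$is_mtRNA_interactor,
                         config$ppi_lambda_pos, config$ppi_lambda_neg))

    data.frame(gene_id = truth$gene_id,
               is_mito_go = is_mito_go,
               is_rna_go = is_rna_go,
               is_tca_go = is_tca_go,
               is_oxphos_go = is_oxphos_go,
               is_mitocarta = is_mitocarta,
               mitocarta_score = mitocarta_score,
               rna_domain = rna_domain,
               coexpression_score = coexpression_score,
               ppi_count = ppi_count,
               stringsAsFactors = FALSE)
  })
}

#' Generate training sets for a synthetic study
#'
#' Samples the positive set from the true interactors and builds the negative
#' set with the same GO-rule machinery the real pipeline uses
#' ([buildNegativeSet()]), so the synthetic training sets have the structure
#' of the curated ones.
#'
#' @param truth Ground truth from [generateUniverse()].
#' @param annotations Annotation table from [generateAnnotations()].
#' @param config A [simConfig()] object.
#' @return A [TrainingSets-class] object.
#' @export
generateTrainingSets <- function(truth, annotations, config) {
  stopifnot(inherits(config, "SimulationConfig"))
  interactors <- truth$gene_id[truth$is_mtRNA_interactor]
  if (length(interactors) < config$training_pos_size) {
    stop("fewer true interactors than the requested positive-set size")
  }
  pos <- withSeed(config$seed + 3L,
                  sample(interactors, config$training_pos_size))
  buildTrainingSets(pos, annotations, seed = config$seed + 4L)
}

#' Generate a complete synthetic study
#'
#' Runs [generateUniverse()], [generateLfq()], [generateAnnotations()] and
#' [generateTrainingSets()] under one configuration, returning every input
#' the analysis pipeline needs. Fully deterministic given the configuration
#' (which includes the seed).
#'
#' @param config A [simConfig()] object.
#' @return A list with `truth`, `lfq` ([LfqExperiment-class]),
#'   `annotations`, `trainingSets` and `config`.
#' @examples
#' study <- simulateStudy(simConfig(n_genes = 500, n_true = 40,
#'                                  training_pos_size = 8,
#'                                  training_neg_size_per_category = 10))
#' study$trainingSets
#' @export
simulateStudy <- function(config = simConfig()) {
  stopifnot(inherits(config, "SimulationConfig"))
  truth <- generateUniverse(config)
  lfq <- generateLfq(truth, config)
  annotations <- generateAnnotations(truth, config)
  sets <- generateTrainingSets(truth, annotations, config)
  list(truth = truth, lfq = lfq, annotations = annotations,
       trainingSets = sets, config = config)
}
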