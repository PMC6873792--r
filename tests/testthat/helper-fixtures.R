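# Small in-code fixtures shared across test files.

# An LfqExperiment built from an explicit matrix; one approach, first half of
# the columns crosslinked, second half control, all biological replicates.
makeLfq <- function(m, approach = "MXL") {
  n <- ncol(m)
  n_xl <- ceiling(n / 2)
  sm <- data.frame(
    sample_id = colnames(m),
    approach = approach,
    condition = rep(c("crosslinked", "control"), c(n_xl, n - n_xl)),
    biological_rep = c(seq_len(n_xl), seq_len(n - n_xl)),
    technical_rep = 1L,
    stringsAsFactors = FALSE)
  LfqExperiment(m, sm)
}

# Annotation table with explicit class memberships by gene index.
makeAnnotations <- function(ids, mito = integer(), rna = integer(),
                            tca = integer(), oxphos = integer()) {
  n <- length(ids)
  data.frame(gene_id = ids,
             is_mito_go = seq_len(n) %in% mito,
             is_rna_go = seq_len(n) %in% rna,
             is_tca_go = seq_len(n) %in% tca,
             is_oxphos_go = seq_len(n) %in% oxphos,
             is_mitocarta = seq_len(n) %in% mito,
             mitocarta_score = NA_real_,
             rna_domain = seq_len(n) %in% rna,
             coexpression_score = NA_real_,
             ppi_count = 0L,
             stringsAsFactors = FALSE)
}

# A deterministic MtRnaRanking from one discrete track: genes in `high` get
# value 1, all others 0, so the high group scores above the rest.
makeRanking <- function(universe, sets, high, prior = computeOprior(30, 300)) {
  vals <- stats::setNames(as.numeric(universe %in% high), universe)
  integrateEvidence(list(track = vals), sets, prior, universe = universe,
                    binSpecs = list(track = binSpec("track", "discrete")))
}
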