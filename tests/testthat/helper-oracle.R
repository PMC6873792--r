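# Independent oracles, written with plain loops and no calls into the
# package's integration path.

# Brute-force naive-Bayes log2 posterior odds for discrete/flag evidence.
# Bins are the raw values themselves ("missing" for absent/NA); fractions of
# zero are replaced by 0.5 / |negatives| on both sides.
oracleNaiveBayesScores <- function(evidence, pos, neg, priorOdds, universe) {
  bin_of <- function(track, g) {
    v <- if (g %in% names(track)) track[[g]] else NA
    if (is.na(v)) "missing" else as.character(v)
  }
  scores <- numeric(length(universe))
  names(scores) <- universe
  for (g in universe) {
    lo <- log2(priorOdds)
    for (nm in names(evidence)) {
      track <- evidence[[nm]]
      gb <- bin_of(track, g)
      n_pos <- 0L
      for (p in pos) if (bin_of(track, p) == gb) n_pos <- n_pos + 1L
      n_neg <- 0L
      for (q in neg) if (bin_of(track, q) == gb) n_neg <- n_neg + 1L
      f_pos <- n_pos / length(pos)
      f_neg <- n_neg / length(neg)
      if (f_pos == 0) f_pos <- 0.5 / length(neg)
      if (f_neg == 0) f_neg <- 0.5 / length(neg)
      lo <- lo + log2(f_pos / f_neg)
    }
    scores[[g]] <- lo
  }
  scores
}

# Exhaustive concordant-pair AUC (Mann-Whitney with half-credit ties).
oracleAuc <- function(scores, labels) {
  ps <- scores[labels]
  ns <- scores[!labels]
  tot <- 0
  for (p in ps) {
    for (q in ns) {
      tot <- tot + (p > q) + 0.5 * (p == q)
    }
  }
  tot / (length(ps) * length(ns))
}

# Random small discrete-evidence instance for oracle comparisons.
randomToyInstance <- function(n_genes = 40L, n_tracks = 3L, n_bins = 3L,
                              miss_rate = 0.2) {
  universe <- sprintf("g%02d", seq_len(n_genes))
  evidence <- list()
  for (i in seq_len(n_tracks)) {
    vals <- sample(seq_len(n_bins), n_genes, replace = TRUE)
    names(vals) <- universe
    vals <- vals[runif(n_genes) >= miss_rate]
    evidence[[paste0("track", i)]] <- vals
  }
  labs <- sample(universe, 14L)
  list(universe = universe, evidence = evidence,
       pos = labs[1:6], neg = labs[7:14])
}
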