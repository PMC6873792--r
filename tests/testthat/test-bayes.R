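test_that("bin assignment covers the universe with half-open intervals", {
  sp <- binSpec("t", "continuous", borders = c(0, 2))
  asg <- assignBins(c(A = 1, B = 3, C = NA, D = -5, E = 2), sp,
                    universe = c("A", "B", "C", "D", "E", "F"))
  expect_equal(as.character(asg[c("A", "B", "C", "D", "E", "F")]),
               c("[0,2)", "[2, Inf)", "missing", "[-Inf,0)", "[2, Inf)",
                 "missing"))
  expect_true("missing" %in% levels(asg))

  # flag track: two bins plus missing
  fl <- assignBins(c(A = TRUE, B = FALSE), binSpec("f", "flag"),
                   universe = c("A", "B", "C"))
  expect_equal(as.character(fl), c("yes", "no", "missing"))

  # all genes missing
  allm <- assignBins(c(A = NA_real_), sp, universe = c("A", "B"))
  expect_true(all(allm == "missing"))

  expect_error(assignBins(c(Z = 1), sp, universe = c("A")), "outside")
  expect_error(binSpec("t", "continuous", borders = c(2, 0)), "increasing")
})

test_that("bin scores are training-set log2 likelihood ratios with pseudo-counts", {
  pos <- paste0("p", 1:10)
  neg <- paste0("n", 1:10)
  universe <- c(pos, neg, "x1", "x2")
  sets <- TrainingSets(pos, neg[1:5], neg[6:10])
  vals <- stats::setNames(rep(0, length(universe)), universe)
  vals[c(pos[1:4], neg[1])] <- 1           # bin "1": 4 pos, 1 neg
  asg <- assignBins(vals, binSpec("t", "discrete"), universe)
  tab <- scoreBins(asg, sets)
  expect_equal(tab$log2_ratio[tab$bin == "1"], log2((4 / 10) / (1 / 10)))

  # zero positives in a bin: pseudo-fraction 0.5/|neg| on the positive side
  vals2 <- stats::setNames(rep(0, length(universe)), universe)
  vals2[neg[1:2]] <- 1                     # bin "1": 0 pos, 2 neg
  tab2 <- scoreBins(assignBins(vals2, binSpec("t", "discrete"), universe),
                    sets)
  expect_equal(tab2$log2_ratio[tab2$bin == "1"], log2(0.05 / 0.2))

  # equal fractions are uninformative
  vals3 <- stats::setNames(rep(0, length(universe)), universe)
  vals3[c(pos[1:2], neg[1:2])] <- 1
  tab3 <- scoreBins(assignBins(vals3, binSpec("t", "discrete"), universe),
                    sets)
  expect_equal(tab3$log2_ratio[tab3$bin == "1"], 0)

  # conservation: bin counts sum to the training-set sizes
  expect_equal(sum(tab$n_pos), 10)
  expect_equal(sum(tab$n_neg), 10)
  expect_true(all(is.finite(tab$log2_ratio)))
})

test_that("the prior odds follow the expected/total gene counts", {
  pr <- computeOprior(300, 20129)
  expect_equal(pr$priorOdds, 300 / 19829)
  expect_equal(pr$opriorLog2, log2(300 / 19829))
  expect_equal(round(pr$priorOdds, 6), 0.015129)
  expect_equal(round(pr$opriorLog2, 3), -6.047)
  expect_equal(round(computeOprior(1000, 20129)$priorOdds, 6), 0.052277)
  expect_equal(computeOprior(50, 100)$opriorLog2, 0)
  expect_error(computeOprior(0, 100), "integer")
  expect_error(computeOprior(100, 100), "smaller")
})

test_that("integration matches a brute-force naive-Bayes oracle", {
  set.seed(101)
  for (i in 1:5) {
    inst <- randomToyInstance(n_genes = 40L, n_tracks = sample(2:4, 1),
                              n_bins = 3L)
    sets <- TrainingSets(inst$pos, inst$neg[1:4], inst$neg[5:8])
    prior <- computeOprior(5, 50)
    specs <- lapply(names(inst$evidence), function(nm) {
      binSpec(nm, "discrete")
    })
    names(specs) <- names(inst$evidence)
    res <- integrateEvidence(inst$evidence, sets, prior,
                             universe = inst$universe, binSpecs = specs)
    expected <- oracleNaiveBayesScores(inst$evidence, inst$pos, inst$neg,
                                       prior$priorOdds, inst$universe)
    got <- geneScores(res)[inst$universe]
    expect_lt(max(abs(got - expected)), 1e-9)
  }
})

test_that("a gene missing everywhere gets the prior plus missing-bin ratios", {
  universe <- c(paste0("p", 1:3), paste0("n", 1:4), "ghost")
  sets <- TrainingSets(paste0("p", 1:3), paste0("n", 1:2), paste0("n", 3:4))
  ev <- list(t1 = c(p1 = 1, p2 = 1, p3 = 2, n1 = 2, n2 = 2, n3 = 1, n4 = 2))
  prior <- computeOprior(2, 10)
  res <- integrateEvidence(ev, sets, prior, universe = universe,
                           binSpecs = list(t1 = binSpec("t1", "discrete")))
  tab <- binScores(res)$t1
  miss_ratio <- tab$log2_ratio[tab$bin == "missing"]
  expect_equal(unname(geneScores(res)["ghost"]),
               prior$opriorLog2 + miss_ratio)
})

test_that("an everywhere-uninformative track changes no score", {
  universe <- c(paste0("p", 1:4), paste0("n", 1:4), paste0("x", 1:4))
  sets <- TrainingSets(paste0("p", 1:4), paste0("n", 1:2), paste0("n", 3:4))
  prior <- computeOprior(3, 12)
  informative <- stats::setNames(c(1, 1, 1, 2, 2, 1, 2, 2, 1, 2, 1, 2),
                                 universe)
  # equal positive and negative fractions in both bins of the dull track
  dull <- stats::setNames(c(1, 1, 2, 2, 1, 1, 2, 2, 1, 1, 2, 2), universe)
  specs <- list(a = binSpec("a", "discrete"), b = binSpec("b", "discrete"))
  with_dull <- integrateEvidence(list(a = informative, b = dull), sets, prior,
                                 universe = universe, binSpecs = specs)
  without <- integrateEvidence(list(a = informative), sets, prior,
                               universe = universe,
                               binSpecs = specs["a"])
  expect_equal(geneScores(with_dull), geneScores(without))
})

test_that("changing the prior shifts all scores equally and keeps the ranking", {
  set.seed(202)
  inst <- randomToyInstance(n_genes = 30L, n_tracks = 3L)
  sets <- TrainingSets(inst$pos, inst$neg[1:4], inst$neg[5:8])
  specs <- lapply(stats::setNames(nm = names(inst$evidence)),
                  function(nm) binSpec(nm, "discrete"))
  r300 <- integrateEvidence(inst$evidence, sets, computeOprior(300, 20129),
                            universe = inst$universe, binSpecs = specs)
  r1000 <- integrateEvidence(inst$evidence, sets, computeOprior(1000, 20129),
                             universe = inst$universe, binSpecs = specs)
  d <- geneScores(r1000)[inst$universe] - geneScores(r300)[inst$universe]
  expect_equal(unname(d), rep(d[[1]], length(d)))
  expect_identical(rankedTable(r300)$gene_id, rankedTable(r1000)$gene_id)
})

test_that("ranking breaks score ties by fold-change then gene id", {
  scores <- c(A = 5, B = 5, C = 3)
  ranks <- rankGenes(scores, tieBreak = c(A = 1.0, B = 2.0))
  expect_equal(ranks, c(A = 2L, B = 1L, C = 3L))

  # distinct scores ignore the tie-break
  expect_equal(rankGenes(c(A = 1, B = 2), tieBreak = c(A = 9, B = 0)),
               c(A = 2L, B = 1L))

  # ties with no fold-change fall back to lexicographic order
  expect_equal(rankGenes(c(B = 1, A = 1)), c(B = 2L, A = 1L))
})

test_that("quantile bin specs collapse duplicate borders", {
  v <- stats::setNames(c(rep(0, 80), 1:20), paste0("g", 1:100))
  sp <- quantileBinSpec("zeroish", v, nBins = 5)
  expect_false(is.unsorted(sp@borders, strictly = TRUE))
  asg <- assignBins(v, sp, universe = names(v))
  expect_true(all(table(asg) >= 0))
  expect_error(quantileBinSpec("none", c(a = NA_real_)), "no observed")
})
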