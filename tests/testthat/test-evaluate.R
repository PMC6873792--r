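test_that("confusion at a cutoff counts training genes only", {
  universe <- c(paste0("p", 1:4), paste0("n", 1:4), paste0("x", 1:12))
  sets <- TrainingSets(paste0("p", 1:4), paste0("n", 1:2), paste0("n", 3:4))
  rk <- makeRanking(universe, sets, high = c("p1", "p2", "p3", "n1", "x1"))
  s <- geneScores(rk)
  cut_mid <- mean(c(max(s), min(s)))
  cm <- confusionAtCutoff(rk, sets, cut_mid)
  expect_equal(cm$n_selected, 5)
  expect_equal(cm$sensitivity, 3 / 4)
  expect_equal(cm$specificity, 1 - 1 / 4)

  # degenerate cutoffs
  expect_equal(confusionAtCutoff(rk, sets, max(s) + 1)$sensitivity, 0)
  low <- confusionAtCutoff(rk, sets, -Inf)
  expect_equal(low$sensitivity, 1)
  expect_equal(low$specificity, 0)
})

test_that("corrected FDR reweights error rates by the prior odds", {
  expect_equal(round(correctedFdr(0.958, 0.968, 300 / 19829), 3), 0.688)
  expect_equal(cfdrPercent(0.958, 0.968, 300 / 19829), 69)
  expect_equal(cfdrPercent(0.958, 0.968, 1000 / 19129), 39)
  expect_equal(correctedFdr(1, 1, 0.5), 0)
  expect_equal(correctedFdr(0, 1, 0.5), 0)   # no selections
  expect_error(correctedFdr(1.2, 0.5, 0.1), "\\[0, 1\\]")

  # monotone: decreasing in specificity, decreasing in sensitivity * odds
  sp <- seq(0.5, 0.99, by = 0.07)
  expect_true(all(diff(correctedFdr(0.9, sp, 0.02)) < 0))
  se <- seq(0.1, 1, by = 0.1)
  expect_true(all(diff(correctedFdr(se, 0.9, 0.02)) < 0))

  # equals the raw training-set FDR when the prior matches the set ratio
  n_pos <- 20; n_neg <- 100; tp <- 15; fp <- 8
  expect_equal(correctedFdr(tp / n_pos, 1 - fp / n_neg, n_pos / n_neg),
               fp / (fp + tp))
})

test_that("ROC construction matches pair counting and pROC", {
  expect_equal(rocCurve(c(3, 1, 2, 0), c(TRUE, TRUE, FALSE, FALSE))$auc,
               0.75)
  expect_equal(rocCurve(c(5, 4, 1, 0), c(TRUE, TRUE, FALSE, FALSE))$auc, 1)
  expect_error(rocCurve(1:3, c(TRUE, TRUE, TRUE)), "at least one")

  set.seed(33)
  for (i in 1:5) {
    n <- 18
    scores <- sample(1:6, n, replace = TRUE)   # plenty of ties
    labels <- sample(c(TRUE, FALSE), n, replace = TRUE, prob = c(0.4, 0.6))
    if (!any(labels) || all(labels)) next
    roc <- rocCurve(scores, labels)
    expect_equal(roc$auc, oracleAuc(scores, labels))
    proc_auc <- as.numeric(pROC::auc(pROC::roc(labels, scores,
                                               quiet = TRUE,
                                               direction = "<")))
    expect_equal(roc$auc, proc_auc)
    # curve is monotone from (0,0) to (1,1)
    expect_equal(roc$points[1, ], data.frame(fpr = 0, tpr = 0))
    expect_equal(unlist(roc$points[nrow(roc$points), ]),
                 c(fpr = 1, tpr = 1))
    expect_true(all(diff(roc$points$fpr) >= 0))
    expect_true(all(diff(roc$points$tpr) >= 0))
  }

  # label-independent scores give chance-level AUC
  set.seed(44)
  auc0 <- rocCurve(rnorm(4000), rep(c(TRUE, FALSE), 2000))$auc
  expect_lt(abs(auc0 - 0.5), 0.05)
})

test_that("cross-validation holds out every training gene exactly once", {
  set.seed(55)
  inst <- randomToyInstance(n_genes = 50L, n_tracks = 3L, n_bins = 3L)
  sets <- TrainingSets(inst$pos, inst$neg[1:4], inst$neg[5:8])
  prior <- computeOprior(5, 50)
  cv <- crossValidate(inst$evidence, sets, prior, k = 2, seed = 9,
                      universe = inst$universe)
  train <- c(positives(sets), negatives(sets))
  expect_setequal(cv$heldOut$gene_id, train)
  expect_equal(nrow(cv$heldOut), length(train))
  expect_equal(anyDuplicated(cv$heldOut$gene_id), 0L)
  # stratified: fold sizes differ by at most one within each class
  pos_tab <- table(cv$folds[positives(sets)])
  neg_tab <- table(cv$folds[negatives(sets)])
  expect_lte(diff(range(pos_tab)), 1)
  expect_lte(diff(range(neg_tab)), 1)

  # determinism under the seed
  cv2 <- crossValidate(inst$evidence, sets, prior, k = 2, seed = 9,
                       universe = inst$universe)
  expect_identical(cv$heldOut, cv2$heldOut)
  expect_identical(cv$auc, cv2$auc)

  expect_error(crossValidate(inst$evidence, sets, prior, k = 7, seed = 1,
                             universe = inst$universe), "at least k")
})

test_that("held-out genes cannot influence their fold's bin tables", {
  set.seed(66)
  inst <- randomToyInstance(n_genes = 40L, n_tracks = 2L, n_bins = 3L)
  sets <- TrainingSets(inst$pos, inst$neg[1:4], inst$neg[5:8])
  prior <- computeOprior(5, 50)
  specs <- lapply(stats::setNames(nm = names(inst$evidence)),
                  function(nm) binSpec(nm, "discrete"))
  cv <- crossValidate(inst$evidence, sets, prior, k = 3, seed = 2,
                      universe = inst$universe, binSpecs = specs)
  tr <- names(inst$evidence)[1]
  present <- cv$heldOut$gene_id %in% names(inst$evidence[[tr]])
  held_gene <- cv$heldOut$gene_id[present][1]
  fold <- cv$heldOut$fold[present][1]
  out_genes <- names(cv$folds)[cv$folds == fold]
  sets_f <- TrainingSets(setdiff(positives(sets), out_genes),
                         setdiff(negatives(sets, "mito_nonrna"), out_genes),
                         setdiff(negatives(sets, "rna_nonmito"), out_genes))
  base <- integrateEvidence(inst$evidence, sets_f, prior,
                            universe = inst$universe, binSpecs = specs)
  flipped <- inst$evidence
  # move the held-out gene to a different existing bin
  other <- setdiff(unique(flipped[[tr]]), flipped[[tr]][held_gene])[1]
  flipped[[tr]][held_gene] <- other
  alt <- integrateEvidence(flipped, sets_f, prior,
                           universe = inst$universe, binSpecs = specs)
  for (nm in names(specs)) {
    expect_identical(binScores(base)[[nm]][c("n_pos", "n_neg")],
                     binScores(alt)[[nm]][c("n_pos", "n_neg")])
  }
})

test_that("rank metrics grow monotonically and end at full sensitivity", {
  universe <- c(paste0("p", 1:4), paste0("n", 1:4), paste0("x", 1:6))
  sets <- TrainingSets(paste0("p", 1:4), paste0("n", 1:2), paste0("n", 3:4))
  rk <- makeRanking(universe, sets, high = c("p1", "p2", "x1"))
  prior <- computeOprior(3, 14)
  tab <- rankMetricsTable(rk, sets, prior)
  expect_equal(tab$n_selected, 0:length(universe))
  expect_equal(tab$sensitivity[1], 0)
  expect_equal(tab$cFDR[1], 0)
  expect_equal(tab$sensitivity[nrow(tab)], 1)
  expect_true(all(diff(tab$sensitivity) >= 0))
  expect_true(all(diff(tab$specificity) <= 0))

  cut <- cutoffForCfdr(rk, sets, prior, target = 0.69)
  expect_lte(cut$cFDR, 0.69)
  # most inclusive choice: the next rank would exceed the target
  nxt <- tab$cFDR[tab$rank == cut$rank + 1]
  if (length(nxt)) expect_gt(nxt, 0.69)
})
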