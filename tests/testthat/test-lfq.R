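test_that("log2 transform imputes missing cells with the measured floor", {
  m <- matrix(c(8, 4, NA, 16), nrow = 2,
              dimnames = list(c("A", "B"), c("s1", "s2")))
  out <- log2TransformAndImpute(makeLfq(m))
  lm <- SummarizedExperiment::assay(out, "intensities")
  expect_equal(lm, matrix(c(3, 2, 2, 4), nrow = 2,
                          dimnames = dimnames(m)))
  expect_equal(imputedMask(out),
               matrix(c(FALSE, FALSE, TRUE, FALSE), nrow = 2,
                      dimnames = dimnames(m)))
  expect_true(isLog2(out))
  expect_equal(S4Vectors::metadata(out)$imputeFloor, 2)

  # single protein across three samples: floor is log2 of the smallest value
  m1 <- matrix(c(1024, NA, 2), nrow = 1,
               dimnames = list("P", c("x1", "x2", "x3")))
  out1 <- log2TransformAndImpute(makeLfq(m1))
  expect_equal(as.numeric(SummarizedExperiment::assay(out1, "intensities")),
               c(10, 1, 1))
})

test_that("a complete matrix is transformed element-wise with no flags", {
  m <- matrix(c(2, 4, 8, 16), nrow = 2,
              dimnames = list(c("A", "B"), c("s1", "s2")))
  out <- log2TransformAndImpute(makeLfq(m))
  expect_equal(SummarizedExperiment::assay(out, "intensities"), log2(m))
  expect_false(any(imputedMask(out)))
})

test_that("degenerate matrices are rejected", {
  m <- matrix(NA_real_, 2, 2, dimnames = list(c("A", "B"), c("s1", "s2")))
  expect_error(log2TransformAndImpute(makeLfq(m)), "nothing to impute")
  expect_error(LfqExperiment(matrix(c(-1, 2, 3, 4), 2, 2,
                                    dimnames = list(c("A", "B"),
                                                    c("s1", "s2"))),
                             data.frame(sample_id = c("s1", "s2"),
                                        approach = "MXL",
                                        condition = c("crosslinked", "control"),
                                        biological_rep = 1L,
                                        technical_rep = 1:2)),
               "strictly positive")
  m2 <- matrix(c(2, 4, 8, 16), nrow = 2,
               dimnames = list(c("A", "B"), c("s1", "s2")))
  expect_error(log2TransformAndImpute(log2TransformAndImpute(makeLfq(m2))),
               "already")
})

test_that("imputation never changes present values and preserves the minimum", {
  set.seed(42)
  for (i in 1:5) {
    m <- matrix(2^runif(60, 1, 20), nrow = 10)
    m[sample(60, 15)] <- NA
    dimnames(m) <- list(paste0("P", 1:10), paste0("s", 1:6))
    out <- log2TransformAndImpute(makeLfq(m))
    lm <- SummarizedExperiment::assay(out, "intensities")
    present <- !is.na(m)
    expect_equal(lm[present], log2(m[present]))
    expect_equal(min(lm), min(log2(m[present])))
    expect_true(all(is.finite(lm)))
  }
})

test_that("replicates average hierarchically, technical within biological", {
  m <- matrix(2^c(2, 4, 6, 0, 0, 0), nrow = 1,
              dimnames = list("P", paste0("s", 1:6)))
  sm <- data.frame(sample_id = paste0("s", 1:6), approach = "MXL",
                   condition = rep(c("crosslinked", "control"), each = 3),
                   biological_rep = c(1L, 1L, 2L, 1L, 2L, 3L),
                   technical_rep = c(1L, 2L, 1L, 1L, 1L, 1L))
  x <- log2TransformAndImpute(LfqExperiment(m, sm))
  # biorep means: mean(2, 4) = 3 and 6, then mean(3, 6) = 4.5
  expect_equal(unname(averageReplicates(x, "MXL", "crosslinked")), 4.5)
  expect_equal(unname(averageReplicates(x, "MXL", "crosslinked",
                                        method = "flat")), 4)
  # single sample passes through; constants are fixed points
  expect_equal(unname(averageReplicates(x, "MXL", "control")), 0)
  expect_error(averageReplicates(x, "WCXL", "control"), "no samples")
})

test_that("fold-change is the difference of means and is antisymmetric", {
  expect_equal(computeFoldChange(10, 8), 2)
  expect_equal(computeFoldChange(7, 7), 0)
  expect_equal(computeFoldChange(8, 9.585), -1.585)
  a <- c(1.2, -3, 0.5)
  b <- c(0.1, 2, -1)
  expect_equal(computeFoldChange(a, b), -computeFoldChange(b, a))
  expect_error(computeFoldChange(NA_real_, 1), "finite")
})

test_that("enrichment calls threshold detected proteins, boundary included", {
  fct <- data.frame(gene_id = c("A", "B", "C"),
                    log2_fc_MXL = c(2.0, 1.0, log2(3)),
                    stringsAsFactors = FALSE)
  expect_setequal(classifyEnriched(fct, "MXL"), c("A", "C"))
  expect_setequal(classifyEnriched(fct, "MXL", inclusive = FALSE), "A")
  expect_length(classifyEnriched(fct[0, ], "MXL"), 0)
  expect_length(classifyEnriched(fct, "MXL", threshold = 10), 0)
  expect_error(classifyEnriched(fct, "XXL"), "unknown approach")
  # monotone: raising the threshold never adds proteins
  set.seed(7)
  fct2 <- data.frame(gene_id = paste0("g", 1:50),
                     log2_fc_MXL = rnorm(50), stringsAsFactors = FALSE)
  thresholds <- sort(runif(6, -2, 2))
  sets <- lapply(thresholds, function(t) classifyEnriched(fct2, "MXL", t))
  for (i in seq_len(length(sets) - 1)) {
    expect_true(all(sets[[i + 1]] %in% sets[[i]]))
  }
})

test_that("approaches combine by mean, single value, or stay missing", {
  fct <- data.frame(gene_id = c("A", "B", "C", "D"),
                    log2_fc_MXL = c(2.0, 1.5, NA, 3),
                    log2_fc_WCXL = c(4.0, NA, NA, 3),
                    stringsAsFactors = FALSE)
  comb <- combineApproaches(fct)
  expect_equal(unname(comb), c(3.0, 1.5, NA, 3))
  # equals each approach where both agree
  expect_equal(comb[["D"]], 3)
})

test_that("fold-change table flags detection and excludes EtBr from the combined track", {
  m <- matrix(2^c(5, 3, 6, 2,
                  NA, NA, 4, 4,
                  7, 3, NA, NA), nrow = 3, byrow = TRUE,
              dimnames = list(c("A", "B", "C"), paste0("s", 1:4)))
  sm <- data.frame(sample_id = paste0("s", 1:4),
                   approach = rep(c("MXL", "WCXL"), each = 2),
                   condition = rep(c("crosslinked", "control"), 2),
                   biological_rep = 1L, technical_rep = 1L)
  fct <- foldChangeTable(log2TransformAndImpute(LfqExperiment(m, sm)))
  expect_true(all(c("log2_fc_MXL", "detected_MXL", "log2_fc_WCXL",
                    "detected_WCXL", "combined_log2_fc") %in% colnames(fct)))
  expect_equal(fct$log2_fc_MXL[1], 2)        # 5 - 3
  expect_false(fct$detected_MXL[2])          # nothing measured in MXL
  expect_true(is.na(fct$log2_fc_MXL[2]))
  expect_false(fct$detected_WCXL[3])
  expect_equal(fct$combined_log2_fc[3], 4)   # MXL-only passthrough (7 - 3)
  expect_equal(fct$combined_log2_fc[2], 0)   # WCXL-only (4 - 4)
})

test_that("category fractions count annotation classes with integer percents", {
  ids <- paste0("g", 1:500)
  ann <- makeAnnotations(ids, mito = 1:222, rna = 200:320)
  enriched <- ids[1:398]
  cf <- categoryFractions(enriched, ann)
  expect_equal(cf$n_enriched, 398L)
  expect_equal(cf$n_mito, 222L)
  expect_equal(cf$pct_mito, 56)
  expect_true(cf$n_mito_and_rna_go <= min(cf$n_mito, cf$n_rna_go))
  expect_error(categoryFractions(c("nope", enriched), ann), "nope")
})

test_that("overlap sensitivity divides hits by the reference size", {
  expect_equal(overlapSensitivity(53, 180), 0.294)
  expect_equal(overlapSensitivity(22, 180), 0.122)
  expect_equal(overlapSensitivity(0, 180), 0)
  expect_error(overlapSensitivity(181, 180), "nHitsInReference")
  expect_error(overlapSensitivity(1, 0), "positive")
})

test_that("a noiseless synthetic shift is recovered exactly by enrichment calling", {
  cfg <- simConfig(n_genes = 300, n_true = 30, seed = 5,
                   lfq_noise_sd = 0, missing_rate_background = 0,
                   missing_rate_detected = 0, lfq_effect = 2.5,
                   wcxl_attenuation = 1, wcxl_contaminant_shift = 0,
                   frac_mito_extra = 0.1, frac_cyto_rna = 0.1,
                   training_pos_size = 5,
                   training_neg_size_per_category = 10)
  truth <- generateUniverse(cfg)
  lfq <- generateLfq(truth, cfg)
  fct <- foldChangeTable(log2TransformAndImpute(lfq))
  expect_equal(fct$log2_fc_MXL[truth$is_mtRNA_interactor],
               rep(2.5, 30))
  hits <- classifyEnriched(fct, "MXL", threshold = 2)
  expect_setequal(hits, truth$gene_id[truth$is_mtRNA_interactor])
})
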