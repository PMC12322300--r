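test_that("confidence filter applies strict P and peptide thresholds", {
  q <- matrix(1.0, 5, 4, dimnames = list(paste0("P", 1:5),
                                         paste0("S", 1:4)))
  np <- matrix(1L, 5, 4, dimnames = dimnames(q))
  np[1, 2] <- 3L; np[3, 1] <- 5L; np[4, 4] <- 2L; np[5, 3] <- 2L
  pv <- c(0.01, 0.04, 0.06, 0.001, 0.049)
  pqm <- makeToyPQM(q, npep = np, id_pvalue = pv)
  kept <- filterLowConfidence(pqm)
  expect_identical(rownames(kept), c("P1", "P4", "P5"))

  # boundary: id_pvalue exactly 0.05 is dropped (strict <)
  pqm2 <- makeToyPQM(q, npep = matrix(2L, 5, 4, dimnames = dimnames(q)),
                     id_pvalue = c(0.05, 0.0499, 0.05, 0.01, 0.05))
  expect_identical(rownames(filterLowConfidence(pqm2)), c("P2", "P4"))

  # idempotence
  expect_identical(rownames(filterLowConfidence(kept)), rownames(kept))
  expect_error(filterLowConfidence(makeToyPQM(q, npep = np,
                                              id_pvalue = rep(0.9, 5))),
               "no protein passes")
})

test_that("the 80/20 rule labels missing cells as stated, with exact
           boundary arithmetic", {
  # 15 + 15 paired design
  mk <- function(n_miss_cnf, n_miss_skin) {
    q <- matrix(2.0, 1, 30, dimnames = list("P1", c(
      paste0("L", 1:15, "_c"), paste0("L", 1:15, "_s"))))
    if (n_miss_cnf > 0) q[1, seq_len(n_miss_cnf)] <- NA
    if (n_miss_skin > 0) q[1, 15 + seq_len(n_miss_skin)] <- NA
    makeToyPQM(q, tissue = rep(c("cNF", "skin"), each = 15),
               lesion = paste0("L", rep(1:15, 2)))
  }
  # skin 15/15 detected, cNF 10/15: 33% missing > 20% -> all 5 imputed
  cls <- classifyMissingness(mk(5, 0))
  expect_identical(sum(cls@labels == "impute_lod"), 5L)
  # skin 13/15 (86.7% >= 80%), cNF 12/15: exactly 20% missing, not in
  # excess of 20% -> nothing imputed (12/15 boundary is exact)
  cls2 <- classifyMissingness(mk(3, 2))
  expect_identical(sum(cls2@labels == "impute_lod"), 0L)
  expect_identical(sum(cls2@labels == "leave_mar"), 5L)
  # detected 11/15 in both tissues (< 80% both) -> no imputation
  cls3 <- classifyMissingness(mk(4, 4))
  expect_identical(sum(cls3@labels == "impute_lod"), 0L)
})

test_that("excess mode imputes only the cells above the 20% allowance", {
  q <- matrix(2.0, 1, 30, dimnames = list("P1", c(
    paste0("L", 1:15, "_c"), paste0("L", 1:15, "_s"))))
  q[1, 1:5] <- NA   # cNF missing 5/15, skin complete
  pqm <- makeToyPQM(q, tissue = rep(c("cNF", "skin"), each = 15),
                    lesion = paste0("L", rep(1:15, 2)))
  cls <- classifyMissingness(pqm, mode = "excess")
  expect_identical(sum(cls@labels == "impute_lod"), 2L)  # 5 - floor(3)
  cls_all <- classifyMissingness(pqm, mode = "all")
  expect_identical(sum(cls_all@labels == "impute_lod"), 5L)
})

test_that("imputation writes the dataset minimum and touches nothing
           else", {
  set.seed(404)
  pqm <- randomSmallPQM(8, 8, 0.25)
  cls <- classifyMissingness(pqm)
  out <- imputeBelowLOD(pqm, cls)
  q0 <- quantities(pqm); q1 <- quantities(out$matrix)
  obs <- !is.na(q0)
  expect_identical(q1[obs], q0[obs])             # conservation
  imp_cells <- cls@labels == "impute_lod"
  expect_true(all(q1[imp_cells] == min(q0, na.rm = TRUE)))
  expect_true(all(is.na(q1[cls@labels == "leave_mar"])))
  expect_identical(out$report$n_imputed_total, sum(imp_cells))
  expect_identical(out$report$n_remaining_missing,
                   sum(cls@labels == "leave_mar"))
  expect_identical(out$report$n_imputed_total,
                   Reduce(`+`, out$report$n_imputed_by_tissue))
  expect_true(isImputed(out$matrix))

  # idempotence: a second pass has nothing left to impute
  cls2 <- classifyMissingness(out$matrix)
  out2 <- imputeBelowLOD(out$matrix, cls2)
  expect_identical(out2$report$n_imputed_total, 0L)

  # fully observed matrix: all-zero report
  full <- randomSmallPQM(4, 3, 0)
  rep0 <- imputeBelowLOD(full, classifyMissingness(full))$report
  expect_identical(rep0$n_imputed_total, 0L)
  expect_identical(rep0$n_remaining_missing, 0L)
})

test_that("classification agrees with the brute-force rule on random
           matrices", {
  set.seed(101)
  for (i in 1:60) {
    pqm <- randomSmallPQM(sample(2:10, 1), sample(2:4, 1), runif(1, 0, 0.5))
    cd <- as.data.frame(SummarizedExperiment::colData(pqm))
    expect_identical(classifyMissingness(pqm)@labels,
                     bruteClassify(quantities(pqm), cd$tissue))
  }
})

test_that("missingness summary reports per-sample and per-donor
           fractions", {
  q <- matrix(1.0, 20, 4, dimnames = list(sprintf("P%02d", 1:20),
                                          paste0("S", 1:4)))
  q[1:2, 2] <- NA
  pqm <- makeToyPQM(q, tissue = c("cNF", "skin", "cNF", "skin"),
                    lesion = c("L1", "L1", "L2", "L2"))
  ms <- missingnessSummary(pqm)
  expect_equal(ms$per_sample$missing_fraction,
               c(0, 0.10, 0, 0), tolerance = 1e-12)
  donor <- ms$per_donor
  cnf <- donor[donor$tissue == "cNF", ]
  expect_equal(cnf$frac_in_any_sample, 1)      # seen in S1 or S3
  skin <- donor[donor$tissue == "skin", ]
  expect_equal(skin$frac_in_all_samples, 18 / 20)
})

test_that("strong one-tissue censoring is recovered as below-LOD", {
  # cNF shifted far below the detection limit, skin detected ~100%:
  # nearly every censored cell must be labeled impute_lod
  cfg <- simulationConfig(term_log_ratio = log(0.15),
                          protein_baseline_sd = 0.2, sd_patient = 0.02,
                          sd_lesion = 0.05, sd_protein = 0.2,
                          sd_residual = 0.2, lod = 9, mar_rate = 0,
                          n_background_proteins = 0L, seed = 77L)
  sim <- simulateStudy(cfg)
  cls <- classifyMissingness(sim$matrix)
  censored <- sim$truth$missing_cause == "censored_lod"
  expect_gt(sum(censored), 100)
  expect_gte(mean(cls@labels[censored] == "impute_lod"), 0.95)
})
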