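test_that("tissue coefficient matches OLS in the zero-variance limit", {
  # balanced complete data generated without any random-effect variance:
  # the mixed model must reproduce the ordinary regression coefficient
  cfg <- simulationConfig(n_terms = 2L, proteins_per_term = 8L,
                          n_background_proteins = 0L,
                          term_log_ratio = log(c(0.6, 1.4)),
                          sd_patient = 0, sd_lesion = 0,
                          sd_residual = 0.4, lod = -Inf, mar_rate = 0,
                          seed = 31L)
  sim <- simulateStudy(cfg)
  for (tid in names(sim$annotations)) {
    tab <- buildTermTable(sim$matrix, sim$annotations, tid)
    fit <- fitTissueModel(tab, proteinIntercept = TRUE)
    ols <- coef(lm(log_quantity ~ protein_id + tissue, data = tab))
    expect_equal(fit$coef, ols[["tissuecNF"]], tolerance = 1e-6)
  }
})

test_that("an exact two-fold paired construction is recovered exactly", {
  skin <- exp(rnorm(15, 8, 1))
  q <- rbind(P1 = c(2 * skin, skin))
  colnames(q) <- c(paste0("L", 1:15, "_c"), paste0("L", 1:15, "_s"))
  pqm <- makeToyPQM(q, tissue = rep(c("cNF", "skin"), each = 15),
                    lesion = paste0("L", rep(1:15, 2)),
                    patient = rep(rep(c("a", "b", "c"), each = 5), 2))
  est <- testProtein(pqm, "P1")
  expect_equal(est$ratio, 2, tolerance = 1e-6)

  # identical pairs -> ratio exactly 1
  q1 <- rbind(P1 = c(skin, skin))
  colnames(q1) <- colnames(q)
  pqm1 <- makeToyPQM(q1, tissue = rep(c("cNF", "skin"), each = 15),
                     lesion = paste0("L", rep(1:15, 2)))
  expect_equal(testProtein(pqm1, "P1")$ratio, 1, tolerance = 1e-6)
})

test_that("the fallback cascade simplifies strictly in order", {
  sim <- simulateStudy(simulationConfig(seed = 8L, n_terms = 2L,
                                        n_background_proteins = 0L))
  tab <- buildTermTable(sim$matrix, sim$annotations, "GO:0000001")
  expect_identical(fitTissueModel(tab)$structure, "full")
  expect_identical(fitTissueModel(tab, failLevels = "full")$structure,
                   "no_patient")
  expect_identical(
    fitTissueModel(tab, failLevels = c("full", "no_patient"))$structure,
    "minimal")
  expect_error(fitTissueModel(tab, failLevels = c("full", "no_patient",
                                                  "minimal")),
               "no model structure converged")
  # single-protein cascade ends in ordinary regression
  est <- testProtein(sim$matrix, rownames(sim$matrix)[1],
                     failLevels = c("full", "no_patient"))
  expect_identical(est$model_structure_used, "minimal")
  expect_identical(est$df_method, "residual")
})

test_that("specimen-level sample intercepts are available", {
  sim <- simulateStudy(simulationConfig(seed = 14L, n_terms = 1L,
                                        proteins_per_term = 10L,
                                        n_background_proteins = 0L))
  tab <- buildTermTable(sim$matrix, sim$annotations, "GO:0000001")
  f1 <- fitTissueModel(tab, sampleUnit = "lesion")
  f2 <- fitTissueModel(tab, sampleUnit = "specimen")
  expect_true(is.finite(f2$coef))
  # same data, different grouping: estimates close but not forced equal
  expect_equal(f1$coef, f2$coef, tolerance = 0.2)
})

test_that("errors on degenerate model inputs", {
  q <- matrix(exp(rnorm(20, 8, 1)), 2, 10,
              dimnames = list(c("P1", "P2"), paste0("S", 1:10)))
  pqm <- makeToyPQM(q, tissue = rep("cNF", 10),
                    lesion = paste0("L", 1:10))
  tab <- data.frame(protein_id = "P1", sample_id = paste0("S", 1:10),
                    patient_id = "pat1", lesion_id = paste0("L", 1:10),
                    tissue = factor(rep("cNF", 10),
                                    levels = c("skin", "cNF")),
                    log_quantity = rnorm(10))
  expect_error(fitTissueModel(tab), "both tissues")
  expect_error(testProtein(pqm, "NOPE"), "not in matrix")
})

test_that("Bonferroni correction is exact, monotone and capped", {
  expect_equal(bonferroniAdjust(0.01, 12), 0.12)
  expect_equal(bonferroniAdjust(c(0.2, 0.05), 1), c(0.2, 0.05))
  expect_equal(bonferroniAdjust(0.047, 22), 1)     # capped
  p <- c(0.001, 0.02, 0.5)
  prev <- bonferroniAdjust(p, 1)
  for (m in 2:40) {
    cur <- bonferroniAdjust(p, m)
    expect_true(all(cur >= prev))   # monotone in m
    expect_true(all(cur >= p) && all(cur <= 1))
    prev <- cur
  }
  expect_error(bonferroniAdjust(0.1, 0), "family size")
})

test_that("sensitivity subsets keep pairs and reproduce the identity
           subset", {
  sim <- simulateStudy(simulationConfig(seed = 19L, n_terms = 3L,
                                        n_background_proteins = 0L))
  full <- testGOTerm(sim$matrix, sim$annotations, "GO:0000002")
  same <- runSensitivity(sim$matrix, function(m)
    testGOTerm(m, sim$annotations, "GO:0000002"), which = "all")
  expect_equal(same$ratio, full$ratio, tolerance = 1e-9)
  expect_equal(same$p_plain, full$p_plain, tolerance = 1e-9)

  grow <- subsetSamples(sim$matrix, "growing")
  cdg <- as.data.frame(SummarizedExperiment::colData(grow))
  expect_true(all(cdg$growing == "yes"))
  expect_true(all(table(cdg$lesion_id) == 2L))  # pairs intact

  pat <- subsetSamples(sim$matrix, "patient", patient = "patient4")
  cdp <- as.data.frame(SummarizedExperiment::colData(pat))
  expect_setequal(unique(cdp$patient_id), "patient4")
  expect_identical(ncol(pat), 8L)   # 4 lesions x 2 tissues

  expect_error(subsetSamples(sim$matrix, "lesions", lesions = "nope"),
               "whole tissue|subset")
})
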