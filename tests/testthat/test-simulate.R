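test_that("null configuration collapses to identical paired quantities", {
  cfg <- simulationConfig(term_log_ratio = 0, sd_patient = 0,
                          sd_lesion = 0, sd_protein = 0, sd_residual = 0,
                          protein_baseline_sd = 0, lod = -Inf,
                          mar_rate = 0, n_terms = 4L,
                          proteins_per_term = 5L,
                          n_background_proteins = 0L, seed = 11L)
  sim <- simulateStudy(cfg)
  q <- quantities(sim$matrix)
  expect_identical(nMissing(sim$matrix), 0L)
  # every protein constant across all samples
  expect_true(all(apply(q, 1, function(r) max(r) - min(r)) == 0))
  est <- testGOTerm(sim$matrix, sim$annotations, "GO:0000001",
                    familySize = 4L)
  expect_equal(est$ratio, 1, tolerance = 1e-9)
})

test_that("same configuration and seed reproduce the study bit for bit", {
  cfg <- simulationConfig(seed = 42L, lod = 6.5, mar_rate = 0.05,
                          n_contaminants = 3L)
  a <- simulateStudy(cfg)
  b <- simulateStudy(cfg)
  expect_identical(quantities(a$matrix), quantities(b$matrix))
  expect_identical(peptideCounts(a$matrix), peptideCounts(b$matrix))
  expect_identical(a$truth$missing_cause, b$truth$missing_cause)
  expect_identical(a$truth$effects, b$truth$effects)
})

test_that("censored fraction matches the closed-form normal expectation", {
  # iid cells: all shared variance components switched off, so
  # y ~ N(10, 1) independently and the censoring probability is exactly
  # pnorm(lod, 10, 1). lod at the 10th percentile, no MAR dropout.
  lod <- qnorm(0.1, 10, 1)
  cfg <- simulationConfig(n_terms = 50L, proteins_per_term = 10L,
                          n_background_proteins = 0L,
                          term_log_ratio = 0, protein_baseline_sd = 0,
                          sd_patient = 0, sd_lesion = 0, sd_protein = 0,
                          sd_residual = 1, lod = lod, mar_rate = 0,
                          seed = 1L)
  sim <- simulateStudy(cfg)
  n_cells <- prod(dim(sim$matrix))
  frac <- sum(sim$truth$missing_cause == "censored_lod") / n_cells
  se <- sqrt(0.1 * 0.9 / n_cells)
  expect_lt(abs(frac - 0.1), 2 * se)
})

test_that("paired log differences recover the tissue effect", {
  beta <- log(0.6)
  cfg <- simulationConfig(n_terms = 1L, proteins_per_term = 200L,
                          n_background_proteins = 0L,
                          term_log_ratio = beta, sd_patient = 0,
                          sd_lesion = 0, sd_residual = 0.3,
                          lod = -Inf, mar_rate = 0, seed = 5L)
  sim <- simulateStudy(cfg)
  q <- log(quantities(sim$matrix))
  cd <- as.data.frame(SummarizedExperiment::colData(sim$matrix))
  cnf <- q[, cd$tissue == "cNF"]
  skin <- q[, cd$tissue == "skin"]
  skin <- skin[, match(cd$lesion_id[cd$tissue == "cNF"],
                       cd$lesion_id[cd$tissue == "skin"])]
  diffs <- cnf - skin   # per protein per lesion; mean should be beta
  se <- sd(diffs) / sqrt(length(diffs))
  expect_lt(abs(mean(diffs) - beta), 2 * se)
})

test_that("censoring is monotone in the threshold on a fixed draw", {
  cfg1 <- simulationConfig(lod = 7.0, mar_rate = 0, seed = 9L)
  cfg2 <- simulationConfig(lod = 8.0, mar_rate = 0, seed = 9L)
  a <- simulateStudy(cfg1)
  b <- simulateStudy(cfg2)
  ca <- a$truth$missing_cause == "censored_lod"
  cb <- b$truth$missing_cause == "censored_lod"
  expect_true(all(cb[ca]))        # every cell censored at 7 also at 8
  expect_lte(sum(ca), sum(cb))
})

test_that("missingness causes partition the missing cells exactly", {
  sim <- simulateStudy(simulationConfig(lod = 7.5, mar_rate = 0.1,
                                        seed = 13L))
  cause <- sim$truth$missing_cause
  missing <- is.na(quantities(sim$matrix))
  expect_identical(cause != "observed", missing)
  expect_true(all(cause %in% c("observed", "censored_lod",
                               "dropout_mar")))
})

test_that("the small fixture matches the paired study design", {
  fx <- fixtureSmall()
  expect_identical(ncol(fx$matrix), 30L)
  st <- fx$samples
  expect_identical(sum(st$tissue == "cNF"), 15L)
  expect_identical(sum(st$tissue == "skin"), 15L)
  expect_identical(length(unique(st$patient_id)), 4L)
  expect_identical(as.integer(table(st$patient_id[st$tissue == "cNF"])),
                   c(3L, 4L, 4L, 4L))
  expect_silent(validateSampleTable(st))
  # deterministic: regeneration reproduces the fixture exactly
  fx2 <- fixtureSmall()
  expect_identical(quantities(fx$matrix), quantities(fx2$matrix))
})

test_that("export/read round trip preserves the simulated study", {
  sim <- simulateStudy(simulationConfig(seed = 21L, lod = 6.5,
                                        n_terms = 5L,
                                        n_background_proteins = 10L))
  dir <- withr::local_tempdir()
  exportStudy(sim, dir)
  expect_true(all(file.exists(file.path(dir,
    c("quantities.tsv", "quantities_peptides.tsv", "samples.tsv",
      "annotations.tsv", "truth.json")))))
  back <- readQuantMatrix(file.path(dir, "quantities.tsv"), "wide")
  back <- attachSampleData(back,
                           readSampleMetadata(file.path(dir, "samples.tsv")))
  expect_equal(quantities(back), quantities(sim$matrix),
               tolerance = 1e-12)
  anno <- readGOAnnotations(file.path(dir, "annotations.tsv"), "tsv", back)
  expect_identical(sort(names(anno)), sort(names(sim$annotations)))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_equal(unlist(truth$term_ratio),
               sim$truth$term_ratio, tolerance = 1e-9)
})
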