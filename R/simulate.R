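#' Simulation configuration for a paired tumor/skin proteomics study
#'
#' Defines the generative model mirrored on the analysis model: for
#' protein \eqn{p} in sample \eqn{s},
#' \deqn{y_{ps} = \mu_p + \beta_{g(p)} 1[\mathrm{tissue}(s)=cNF]
#'       + a_{\mathrm{patient}(s)} + b_{\mathrm{lesion}(s)}
#'       + \varepsilon_{ps},}
#' with \eqn{\mu_p} decomposed into a per-term mean
#' (\code{Normal(protein_baseline_mean, protein_baseline_sd^2)}) plus a
#' within-term protein deviation (\code{Normal(0, sd_protein^2)});
#' quantities are \eqn{\exp(y)}. Realized \eqn{y} below `lod` is censored
#' (missing, cause `censored_lod`); surviving cells then drop out
#' independently with probability `mar_rate` (cause `dropout_mar`).
#'
#' Defaults describe the study design emulated throughout the package:
#' 4 patients contributing 3, 4, 4 and 4 lesions (15 matched cNF/skin
#' pairs, 30 samples), 20 GO terms of 10 proteins each plus 60
#' unannotated background proteins, term-level true ratios recycled over
#' \{0.4, 0.6, 0.76, 1.0, 1.13, 1.5, 2.1\} and modest nested variance
#' components (see the vignette for the rationale).
#'
#' @param n_patients number of donors.
#' @param lesions_per_patient integer vector, one entry per patient.
#' @param n_terms,proteins_per_term GO structure of the simulated
#'   proteome.
#' @param n_background_proteins proteins with no term annotation
#'   (and no tissue effect).
#' @param term_log_ratio per-term log-scale cNF effect; recycled to
#'   `n_terms`.
#' @param protein_baseline_mean,protein_baseline_sd log-intensity
#'   location/spread of per-term means.
#' @param sd_patient,sd_lesion,sd_protein,sd_residual random-effect and
#'   residual SDs on the log scale.
#' @param lod log-intensity censoring threshold (`-Inf` disables).
#' @param mar_rate random-dropout probability for observed cells.
#' @param n_contaminants proteins deliberately failing the confidence
#'   filters (high identification P value or a single peptide), for
#'   filter tests.
#' @param sample_scale_sd SD of optional per-sample log scale factors
#'   (0 = data are already normalized, the default, since the modeled
#'   pipeline starts from a normalized matrix).
#' @param seed integer RNG seed.
#' @return a `SimulationConfig` (classed list).
#' @export
simulationConfig <- function(n_patients = 4L,
                             lesions_per_patient = c(3L, 4L, 4L, 4L),
                             n_terms = 20L,
                             proteins_per_term = 10L,
                             n_background_proteins = 60L,
                             term_log_ratio =
                               log(c(0.4, 0.6, 0.76, 1.0, 1.13, 1.5, 2.1)),
                             protein_baseline_mean = 10,
                             protein_baseline_sd = 1.5,
                             sd_patient = 0.10,
                             sd_lesion = 0.15,
                             sd_protein = 0.50,
                             sd_residual = 0.30,
                             lod = -Inf,
                             mar_rate = 0.02,
                             n_contaminants = 0L,
                             sample_scale_sd = 0,
                             seed = 1L) {
  cfg <- list(n_patients = as.integer(n_patients),
              lesions_per_patient = as.integer(lesions_per_patient),
              n_terms = as.integer(n_terms),
              proteins_per_term = as.integer(proteins_per_term),
              n_background_proteins = as.integer(n_background_proteins),
              term_log_ratio = rep_len(term_log_ratio, n_terms),
              protein_baseline_mean = protein_baseline_mean,
              protein_baseline_sd = protein_baseline_sd,
              sd_patient = sd_patient, sd_lesion = sd_lesion,
              sd_protein = sd_protein, sd_residual = sd_residual,
              lod = lod, mar_rate = mar_rate,
              n_contaminants = as.integer(n_contaminants),
              sample_scale_sd = sample_scale_sd,
              seed = as.integer(seed))
  if (cfg$n_patients < 1L || cfg$n_terms < 1L ||
      cfg$proteins_per_term < 1L || cfg$n_background_proteins < 0L)
    stop("simulation dimensions must be positive")
  if (length(cfg$lesions_per_patient) != cfg$n_patients)
    stop("lesions_per_patient must have one entry per patient")
  if (any(cfg$lesions_per_patient < 1L))
    stop("each patient needs at least one lesion")
  sds <- c(cfg$sd_patient, cfg$sd_lesion, cfg$sd_protein, cfg$sd_residual,
           cfg$protein_baseline_sd)
  if (any(sds < 0)) stop("all SDs must be >= 0")
  if (cfg$mar_rate < 0 || cfg$mar_rate > 1)
    stop("mar_rate must lie in [0, 1]")
  class(cfg) <- "SimulationConfig"
  cfg
}

#' Simulate a paired cNF/skin proteomics study
#'
#' Generates a full dataset under the model documented in
#' [simulationConfig()], with a single seeded RNG stream consumed in a
#' fixed draw order (patient effects, lesion effects, term means, protein
#' deviations, residuals, identification metadata, MAR mask) so that a
#' given config is bit-reproducible.
#'
#' @param config a [simulationConfig()].
#' @return a list with elements `matrix` (a
#'   [ProteinQuantMatrix-class] with design metadata attached), `samples`
#'   (the design `data.frame`), `annotations` (a
#'   [GOAnnotationMap-class]) and `truth` (ground truth: per-term true
#'   ratio, per-cell missingness cause in \{`observed`, `censored_lod`,
#'   `dropout_mar`\}, realized random-effect draws and the config echo).
#' @examples
#' sim <- simulateStudy(simulationConfig(seed = 7L))
#' sim$matrix
#' head(sim$truth$term_ratio)
#' @export
simulateStudy <- function(config = simulationConfig()) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(config$seed)

  ## design: one cNF + one skin sample per lesion
  patient_id <- rep(sprintf("patient%d", seq_len(config$n_patients)),
                    config$lesions_per_patient)
  lesion_id <- sprintf("lesion%02d", seq_along(patient_id))
  samples <- data.frame(
    sample_id = c(paste0(lesion_id, "_cNF"), paste0(lesion_id, "_skin")),
    patient_id = rep(patient_id, 2L),
    lesion_id = rep(lesion_id, 2L),
    tissue = rep(c("cNF", "skin"), each = length(lesion_id)),
    growing = rep(rep(c("no", "yes"), length.out =
                        length(unique(patient_id)))[
                          match(patient_id, unique(patient_id))], 2L))
  ord <- order(samples$lesion_id, samples$tissue)
  samples <- samples[ord, , drop = FALSE]
  rownames(samples) <- NULL
  n_samp <- nrow(samples)

  ## proteome: n_terms blocks of proteins_per_term, then background,
  ## then optional contaminants
  n_term_prot <- config$n_terms * config$proteins_per_term
  n_prot <- n_term_prot + config$n_background_proteins +
    config$n_contaminants
  protein_id <- sprintf("SIMP%04d", seq_len(n_prot))
  term_of <- rep(NA_integer_, n_prot)
  term_of[seq_len(n_term_prot)] <-
    rep(seq_len(config$n_terms), each = config$proteins_per_term)
  term_id <- sprintf("GO:%07d", seq_len(config$n_terms))

  ## draw order 1: random effects (patients, lesions, term means,
  ## protein deviations)
  a_pat <- stats::rnorm(config$n_patients, 0, config$sd_patient)
  names(a_pat) <- unique(patient_id)
  b_les <- stats::rnorm(length(lesion_id), 0, config$sd_lesion)
  names(b_les) <- lesion_id
  term_mean <- stats::rnorm(config$n_terms, config$protein_baseline_mean,
                            config$protein_baseline_sd)
  prot_dev <- stats::rnorm(n_prot, 0, config$sd_protein)
  mu_p <- ifelse(is.na(term_of),
                 stats::rnorm(n_prot, config$protein_baseline_mean,
                              config$protein_baseline_sd),
                 term_mean[term_of]) + prot_dev
  beta_p <- ifelse(is.na(term_of), 0, config$term_log_ratio[term_of])

  ## draw order 2: residuals, then the linear predictor
  eps <- matrix(stats::rnorm(n_prot * n_samp, 0, config$sd_residual),
                n_prot, n_samp)
  is_cnf <- samples$tissue == "cNF"
  y <- mu_p + outer(beta_p, as.numeric(is_cnf)) +
    matrix(a_pat[samples$patient_id], n_prot, n_samp, byrow = TRUE) +
    matrix(b_les[samples$lesion_id], n_prot, n_samp, byrow = TRUE) + eps
  if (config$sample_scale_sd > 0) {
    scale_s <- stats::rnorm(n_samp, 0, config$sample_scale_sd)
    y <- y + matrix(scale_s, n_prot, n_samp, byrow = TRUE)
  } else {
    scale_s <- rep(0, n_samp)
  }
  dimnames(y) <- list(protein_id, samples$sample_id)

  ## draw order 3: identification metadata
  id_pvalue <- stats::runif(n_prot, 0, 0.04)
  npep <- matrix(stats::rpois(n_prot * n_samp, 5) + 1L, n_prot, n_samp,
                 dimnames = dimnames(y))
  ## guarantee >= 2 peptides in at least one sample for genuine proteins
  top <- max.col(npep, ties.method = "first")
  npep[cbind(seq_len(n_prot), top)] <-
    pmax(npep[cbind(seq_len(n_prot), top)], 2L)
  if (config$n_contaminants > 0L) {
    bad <- (n_prot - config$n_contaminants + 1L):n_prot
    flip <- stats::runif(length(bad)) < 0.5
    id_pvalue[bad[flip]] <- stats::runif(sum(flip), 0.05, 0.5)
    npep[bad[!flip], ] <- 1L
  }

  ## censoring on the realized y, then MAR dropout (draw order 4)
  cause <- matrix("observed", n_prot, n_samp, dimnames = dimnames(y))
  cause[y < config$lod] <- "censored_lod"
  mar_draw <- matrix(stats::runif(n_prot * n_samp), n_prot, n_samp)
  cause[cause == "observed" & mar_draw < config$mar_rate] <- "dropout_mar"

  q <- exp(y)
  q[cause != "observed"] <- NA_real_
  npep[cause != "observed"] <- 0L

  pqm <- ProteinQuantMatrix(q, npep, idPvalue = id_pvalue,
                            sampleData = samples)
  anno <- GOAnnotationMap(
    split(protein_id[!is.na(term_of)], term_id[term_of[!is.na(term_of)]]),
    termInfo = data.frame(term_id = term_id,
                          term_name = sprintf("simulated process %d",
                                              seq_len(config$n_terms)),
                          namespace = "biological_process"))
  truth <- list(
    term_ratio = stats::setNames(exp(config$term_log_ratio), term_id),
    term_of_protein = stats::setNames(
      ifelse(is.na(term_of), NA_character_, term_id[term_of]), protein_id),
    missing_cause = cause,
    effects = list(patient = a_pat, lesion = b_les,
                   term_mean = stats::setNames(term_mean, term_id),
                   protein_mu = stats::setNames(mu_p, protein_id),
                   sample_scale = stats::setNames(scale_s,
                                                  samples$sample_id)),
    config = unclass(config))
  list(matrix = pqm, samples = samples, annotations = anno, truth = truth)
}

#' Small deterministic test fixture
#'
#' A fixed-seed call to [simulateStudy()] at the standard design: 4
#' patients with 3, 4, 4, 4 lesions (15 matched pairs, 30 samples), 20
#' terms of 10 proteins plus background, mild censoring so that all
#' three missingness causes occur.
#'
#' @return the same list as [simulateStudy()].
#' @export
fixtureSmall <- function() {
  simulateStudy(simulationConfig(lod = 6.5, mar_rate = 0.02,
                                 seed = 20210702L))
}

#' Export a simulated study to a directory
#'
#' Writes `quantities.tsv` (+ `quantities_peptides.tsv`), `samples.tsv`,
#' `annotations.tsv` and `truth.json` so a simulated dataset can be fed
#' back through the file-based entry points.
#'
#' @param sim a [simulateStudy()] result.
#' @param dir output directory (created if needed).
#' @export
exportStudy <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeQuantMatrix(sim$matrix, file.path(dir, "quantities.tsv"),
                   layout = "wide")
  utils::write.table(sim$samples, file.path(dir, "samples.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  anno <- sim$annotations
  long <- data.frame(
    protein_id = unlist(anno@terms, use.names = FALSE),
    term_id = rep(names(anno), termSizes(anno)))
  long <- merge(long, as.data.frame(anno@termInfo), by = "term_id",
                sort = TRUE)[, c("protein_id", "term_id", "term_name",
                                 "namespace")]
  utils::write.table(long, file.path(dir, "annotations.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  truth <- sim$truth
  truth$missing_cause <- NULL  # large; causes retained in-memory only
  truth$term_ratio <- as.list(truth$term_ratio)
  truth$term_of_protein <- as.list(truth$term_of_protein)
  truth$effects <- lapply(truth$effects, as.list)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(dir)
}
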