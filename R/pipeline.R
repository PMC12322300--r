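#' Default pipeline configuration
#'
#' Every threshold of the analysis is a config entry, never a hard-coded
#' constant: identification P value cutoff 0.05, minimum 2 peptides,
#' 80% reliable-detection fraction with mode `"all"`, terms eligible at
#' >4 dataset proteins, Bonferroni family = number of terms tested,
#' complete linkage on z-scored log quantities.
#'
#' @return nested list of defaults; override any entry via
#'   [readPipelineConfig()] or the `config` argument of [runPipeline()].
#' @export
defaultConfig <- function() {
  list(
    filters = list(p_max = 0.05, min_peptides = 2L),
    imputation = list(reliable_fraction = 0.8, mode = "all"),
    go = list(min_proteins = 5L, propagate = FALSE),
    model = list(sample_unit = "lesion", family_size = NULL),
    correction = list(method = "bonferroni"),
    correlation = list(
      # NULL = first eligible terms (3 responses x 4 predictors); set
      # explicit GO ids to reproduce a specific panel, e.g. the
      # angiogenesis/proliferation/MAPK vs ECM-and-metabolism grid
      y_terms = NULL,
      x_terms = NULL,
      tissue = "cNF"),
    clustering = list(linkage = "complete", metric = "euclidean",
                      scaling = "zscore_log"),
    subset = list(which = "all", patient = NULL))
}

#' Read a YAML pipeline configuration
#'
#' Reads a YAML file with any subset of the [defaultConfig()] sections
#' and merges it over the defaults (file entries win).
#'
#' @param path YAML file path.
#' @return merged config list.
#' @export
readPipelineConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  modifyList(defaultConfig(), user)
}

#' Run the full paired differential-abundance pipeline
#'
#' Executes, in order: confidence filtering, missingness classification
#' and below-LOD imputation, GO-term mixed-model testing with Bonferroni
#' correction, single-protein testing for the proteins in
#' `proteinTargets`, the GO-index correlation panel, and hierarchical
#' clustering. When `outDir` is given, writes `go_results.tsv`,
#' `protein_results.tsv`, `correlations.tsv`, `dendrogram.nwk`,
#' `missingness_labels.tsv` (cell-level audit trail) and
#' `run_report.json`.
#'
#' @param x a raw [ProteinQuantMatrix-class] with design metadata
#'   attached (or attachable via `samples`).
#' @param annotations a [GOAnnotationMap-class] (restricted or not; it
#'   is re-restricted after filtering).
#' @param samples optional sample `data.frame` to attach first.
#' @param proteinTargets accessions for single-protein analysis
#'   (default: none).
#' @param config a [defaultConfig()]-style list.
#' @param outDir optional output directory.
#' @return list: `filtered`, `imputed` (matrix + report),
#'   `go_results`, `protein_results`, `correlations`, `clustering`,
#'   `report`.
#' @export
runPipeline <- function(x, annotations, samples = NULL,
                        proteinTargets = character(),
                        config = defaultConfig(), outDir = NULL) {
  if (!is.null(samples)) x <- attachSampleData(x, samples)
  if (config$subset$which != "all")
    x <- subsetSamples(x, which = config$subset$which,
                       patient = config$subset$patient)
  n_in <- nrow(x)

  filtered <- filterLowConfidence(x, pMax = config$filters$p_max,
                                  minPeptides = config$filters$min_peptides)
  cls <- classifyMissingness(filtered,
                             reliableFraction =
                               config$imputation$reliable_fraction,
                             mode = config$imputation$mode)
  imp <- imputeBelowLOD(filtered, cls)
  mat <- imp$matrix

  anno <- .restrictAnnotations(annotations, rownames(mat))
  terms <- eligibleTerms(anno, minProteins = config$go$min_proteins)
  fam <- if (is.null(config$model$family_size)) length(terms)
    else config$model$family_size
  go_results <- if (length(terms)) do.call(rbind, lapply(terms, function(tid)
    testGOTerm(mat, anno, tid, familySize = fam,
               sampleUnit = config$model$sample_unit))) else NULL

  prot_targets <- intersect(proteinTargets, rownames(mat))
  protein_results <- if (length(prot_targets))
    do.call(rbind, lapply(prot_targets, function(pid)
      testProtein(mat, pid, familySize = length(prot_targets),
                  sampleUnit = config$model$sample_unit))) else NULL

  y_terms <- config$correlation$y_terms
  x_terms <- config$correlation$x_terms
  if (is.null(y_terms)) y_terms <- utils::head(terms, 3L)
  if (is.null(x_terms))
    x_terms <- utils::head(setdiff(terms, y_terms), 4L)
  corr <- tryCatch(
    correlationPanel(mat, anno, yTerms = intersect(y_terms, terms),
                     xTerms = intersect(x_terms, terms),
                     tissue = config$correlation$tissue),
    error = function(e) NULL)

  clus <- tryCatch(clusterStudy(mat, scaling = config$clustering$scaling),
                   error = function(e) NULL)

  report <- list(
    config = config,
    n_proteins_in = n_in,
    n_proteins_after_filter = nrow(filtered),
    imputation = imp$report,
    n_terms_tested = length(terms),
    bonferroni_family_size = fam,
    model = list(log_base = "natural", estimation = "REML",
                 df_method = "satterthwaite",
                 fallback_levels = if (!is.null(go_results))
                   as.list(table(go_results$model_structure_used))
                 else list()),
    clustering_purity = if (!is.null(clus)) clus$pooled$purity else NA)

  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    if (!is.null(go_results))
      writeResultsTable(go_results, file.path(outDir, "go_results.tsv"))
    if (!is.null(protein_results))
      writeResultsTable(protein_results,
                        file.path(outDir, "protein_results.tsv"))
    if (!is.null(corr))
      utils::write.table(corr, file.path(outDir, "correlations.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(clus))
      exportDendrogram(clus$pooled$dendrogram,
                       file.path(outDir, "dendrogram.nwk"), "newick")
    .writeLabelAudit(cls, file.path(outDir, "missingness_labels.tsv"))
    jsonlite::write_json(report, file.path(outDir, "run_report.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  list(filtered = filtered, imputed = imp, go_results = go_results,
       protein_results = protein_results, correlations = corr,
       clustering = clus, report = report)
}

.restrictAnnotations <- function(annotations, proteins) {
  kept <- lapply(as.list(annotations@terms), intersect, proteins)
  kept <- kept[lengths(kept) > 0L]
  if (!length(kept))
    stop("no annotated protein overlaps the quantity matrix")
  GOAnnotationMap(kept,
                  termInfo = as.data.frame(
                    annotations@termInfo[match(names(kept),
                                               annotations@termInfo$term_id),
                                         , drop = FALSE]))
}

.writeLabelAudit <- function(cls, path) {
  lab <- cls@labels
  cells <- which(lab != "observed", arr.ind = TRUE)
  tab <- data.frame(protein_id = rownames(lab)[cells[, 1]],
                    sample_id = colnames(lab)[cells[, 2]],
                    label = lab[cells])
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
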