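#' @import methods
#' @importFrom S4Vectors DataFrame SimpleList metadata metadata<-
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#'   rowData colData rowData<- colData<- assay<- assays<-
#' @importFrom IRanges CharacterList
NULL

#' Protein quantity matrix for a paired DIA proteomics study
#'
#' `ProteinQuantMatrix` extends
#' [SummarizedExperiment::SummarizedExperiment] with the conventions used
#' throughout this package:
#'
#' * assay `"quantity"` — protein x sample normalized intensities, strictly
#'   positive; `NA` marks a missing (undetected) cell.
#' * assay `"npep"` — protein x sample peptide counts (non-negative
#'   integers; 0 where the protein was not detected).
#' * `rowData()$id_pvalue` — per-protein identification P value in [0, 1].
#' * `rowData()$seq_coverage` — optional per-protein sequence coverage
#'   fraction, descriptive only.
#' * `colData()` — once [attachSampleData()] has been called, the design
#'   columns `patient_id`, `lesion_id`, `tissue` (factor with levels
#'   `skin`, `cNF`; skin is the model baseline) and `growing`
#'   (`yes`/`no`/`unknown`).
#'
#' @slot imputed logical scalar; `TRUE` after [imputeBelowLOD()] has been
#'   applied (guards double imputation and records provenance).
#'
#' @seealso [ProteinQuantMatrix()] for the constructor,
#'   [readQuantMatrix()] to build one from a TSV file.
#' @export
setClass("ProteinQuantMatrix",
  contains = "SummarizedExperiment",
  representation(imputed = "logical"),
  prototype(imputed = FALSE)
)

setValidity("ProteinQuantMatrix", function(object) {
  msg <- character()
  an <- names(assays(object))
  if (!all(c("quantity", "npep") %in% an))
    return("assays must include 'quantity' and 'npep'")
  q <- assay(object, "quantity")
  np <- assay(object, "npep")
  if (!identical(dim(q), dim(np)))
    msg <- c(msg, "'quantity' and 'npep' assays must have identical shape")
  if (any(!is.na(q) & q <= 0))
    msg <- c(msg, "all non-missing quantities must be > 0")
  if (any(is.na(np)) || any(np < 0))
    msg <- c(msg, "peptide counts must be non-negative and non-missing")
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "protein identifiers (rownames) must be unique")
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, "sample identifiers (colnames) must be unique")
  if (!"id_pvalue" %in% colnames(rowData(object))) {
    msg <- c(msg, "rowData must contain 'id_pvalue'")
  } else {
    pv <- rowData(object)$id_pvalue
    if (any(is.na(pv)) || any(pv < 0 | pv > 1))
      msg <- c(msg, "id_pvalue must lie in [0, 1] with no NA")
  }
  if (length(object@imputed) != 1L)
    msg <- c(msg, "'imputed' must be a logical scalar")
  if (length(msg)) msg else TRUE
})

#' Construct a ProteinQuantMatrix
#'
#' @param quantities numeric protein x sample matrix of positive
#'   intensities, `NA` for missing cells; rownames are protein accessions,
#'   colnames sample identifiers.
#' @param peptideCounts integer matrix of the same shape with per-cell
#'   peptide counts.
#' @param idPvalue numeric vector of per-protein identification P values,
#'   parallel to the rows.
#' @param seqCoverage optional numeric vector of per-protein sequence
#'   coverage fractions in [0, 1].
#' @param sampleData optional `data.frame` of per-sample design metadata
#'   (see [readSampleMetadata()]); attached via [attachSampleData()].
#' @return a validated [ProteinQuantMatrix-class] object.
#' @examples
#' q <- matrix(c(10, 20, NA, 40), 2, 2,
#'             dimnames = list(c("P1", "P2"), c("S1", "S2")))
#' np <- matrix(2L, 2, 2, dimnames = dimnames(q))
#' pqm <- ProteinQuantMatrix(q, np, idPvalue = c(0.01, 0.02))
#' nMissing(pqm)
#' @export
ProteinQuantMatrix <- function(quantities, peptideCounts, idPvalue,
                               seqCoverage = NULL, sampleData = NULL) {
  quantities <- as.matrix(quantities)
  peptideCounts <- as.matrix(peptideCounts)
  storage.mode(peptideCounts) <- "integer"
  rd <- DataFrame(id_pvalue = as.numeric(idPvalue),
                  row.names = rownames(quantities))
  if (!is.null(seqCoverage)) rd$seq_coverage <- as.numeric(seqCoverage)
  se <- SummarizedExperiment(
    assays = SimpleList(quantity = quantities, npep = peptideCounts),
    rowData = rd)
  out <- new("ProteinQuantMatrix", se, imputed = FALSE)
  validObject(out)
  if (!is.null(sampleData)) out <- attachSampleData(out, sampleData)
  out
}

#' GO annotation map restricted to a dataset
#'
#' Maps each Gene Ontology term to the set of protein accessions from the
#' quantity matrix annotated with it. Built by [readGOAnnotations()], which
#' restricts the raw annotation source to proteins actually present in the
#' dataset.
#'
#' @slot terms a named [IRanges::CharacterList]; element names are GO term
#'   identifiers, element values unique protein accessions.
#' @slot termInfo `DataFrame` with one row per term: `term_id`,
#'   `term_name`, `namespace` (any may be `NA` for a bare TSV source).
#' @export
setClass("GOAnnotationMap",
  representation(terms = "CharacterList", termInfo = "DataFrame"))

setValidity("GOAnnotationMap", function(object) {
  msg <- character()
  if (is.null(names(object@terms)) || anyDuplicated(names(object@terms)))
    msg <- c(msg, "terms must be uniquely named by GO id")
  if (any(vapply(object@terms, anyDuplicated, 0L) > 0L))
    msg <- c(msg, "protein sets must not contain duplicates within a term")
  if (!identical(object@termInfo$term_id, names(object@terms)))
    msg <- c(msg, "termInfo rows must parallel terms")
  if (length(msg)) msg else TRUE
})

#' @describeIn GOAnnotationMap-class construct from a named list of
#'   character vectors (protein accessions per term).
#' @param terms named list or `CharacterList` of protein accessions.
#' @param termInfo optional `DataFrame`/`data.frame` with columns
#'   `term_id`, `term_name`, `namespace`.
#' @export
GOAnnotationMap <- function(terms, termInfo = NULL) {
  terms <- CharacterList(lapply(terms, function(x) unique(as.character(x))))
  if (is.null(termInfo)) {
    termInfo <- DataFrame(term_id = names(terms),
                          term_name = NA_character_,
                          namespace = NA_character_)
  } else {
    termInfo <- DataFrame(termInfo)
    termInfo <- termInfo[match(names(terms), termInfo$term_id), , drop = FALSE]
    termInfo$term_id <- names(terms)
    rownames(termInfo) <- NULL
  }
  out <- new("GOAnnotationMap", terms = terms, termInfo = termInfo)
  validObject(out)
  out
}

#' Per-cell missingness classification under the 80/20 rule
#'
#' Produced by [classifyMissingness()]. Labels every missing cell of a
#' [ProteinQuantMatrix-class] either `impute_lod` (informative, below the
#' limit of detection, to be imputed with the dataset minimum) or
#' `leave_mar` (assumed missing at random, left missing).
#'
#' @slot labels character protein x sample matrix: `"observed"` for
#'   detected cells, else `"impute_lod"` or `"leave_mar"`.
#' @slot detection numeric protein x tissue matrix of detection fractions.
#' @slot globalMinimum the minimum observed quantity over the whole
#'   matrix; the imputation value.
#' @slot mode `"all"` or `"excess"` (see [classifyMissingness()]).
#' @export
setClass("MissingnessClassification",
  representation(labels = "matrix", detection = "matrix",
                 globalMinimum = "numeric", mode = "character"))
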