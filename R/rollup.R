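#' GO terms eligible for term-level testing
#'
#' A term is analyzed when it is associated with more than four distinct
#' proteins present in the dataset, i.e. at least `minProteins` (default
#' 5).
#'
#' @param annotations a [GOAnnotationMap-class] (already restricted to
#'   the dataset).
#' @param minProteins minimum dataset-protein set size (`>=`).
#' @return character vector of eligible term identifiers (possibly
#'   empty).
#' @export
eligibleTerms <- function(annotations, minProteins = 5L) {
  sz <- termSizes(annotations)
  names(sz)[sz >= minProteins]
}

#' Assemble the long observation table for one GO term
#'
#' One row per (term protein, sample) cell with a non-missing quantity:
#' missing-at-random cells are excluded, imputed below-LOD cells
#' participate with their imputed value. Quantities are natural-log
#' transformed (the exponentiated tissue coefficient is base-invariant).
#'
#' @param x an imputed [ProteinQuantMatrix-class] with design metadata.
#' @param annotations a [GOAnnotationMap-class].
#' @param termId a single GO term identifier.
#' @return `data.frame` with columns `protein_id`, `sample_id`,
#'   `patient_id`, `lesion_id`, `tissue`, `growing`, `log_quantity`.
#' @export
buildTermTable <- function(x, annotations, termId) {
  prots <- intersect(termProteins(annotations, termId), rownames(x))
  if (!length(prots))
    stop("term ", termId, " has no protein in the matrix")
  cd <- .sampleData(x)
  q <- quantities(x)[prots, , drop = FALSE]
  obs <- which(!is.na(q), arr.ind = TRUE)
  if (!nrow(obs))
    stop("term ", termId, " has zero observations")
  tab <- data.frame(
    protein_id = prots[obs[, 1]],
    sample_id = colnames(q)[obs[, 2]],
    patient_id = cd$patient_id[obs[, 2]],
    lesion_id = cd$lesion_id[obs[, 2]],
    tissue = cd$tissue[obs[, 2]],
    growing = cd$growing[obs[, 2]],
    log_quantity = log(q[obs]))
  tab[order(tab$protein_id, tab$sample_id), , drop = FALSE]
}
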