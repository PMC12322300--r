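#' @rdname ProteinQuantMatrix-utils
#' @export
setGeneric("quantities", function(x) standardGeneric("quantities"))

#' @rdname ProteinQuantMatrix-utils
#' @export
setGeneric("peptideCounts", function(x) standardGeneric("peptideCounts"))

#' @rdname ProteinQuantMatrix-utils
#' @export
setGeneric("idPvalue", function(x) standardGeneric("idPvalue"))

#' @rdname ProteinQuantMatrix-utils
#' @export
setGeneric("nMissing", function(x) standardGeneric("nMissing"))

#' @rdname ProteinQuantMatrix-utils
#' @export
setGeneric("isImputed", function(x) standardGeneric("isImputed"))

#' @rdname GOAnnotationMap-utils
#' @export
setGeneric("termSizes", function(x) standardGeneric("termSizes"))

#' @rdname GOAnnotationMap-utils
#' @export
setGeneric("termProteins", function(x, term) standardGeneric("termProteins"))

#' Accessors for ProteinQuantMatrix
#'
#' `quantities()` returns the quantity assay (NA = missing),
#' `peptideCounts()` the peptide-count assay, `idPvalue()` the per-protein
#' identification P values, `nMissing()` the number of missing cells and
#' `isImputed()` whether below-LOD imputation has been applied.
#'
#' @param x a [ProteinQuantMatrix-class].
#' @name ProteinQuantMatrix-utils
NULL

#' @rdname ProteinQuantMatrix-utils
#' @export
setMethod("quantities", "ProteinQuantMatrix",
          function(x) assay(x, "quantity"))

#' @rdname ProteinQuantMatrix-utils
#' @export
setMethod("peptideCounts", "ProteinQuantMatrix",
          function(x) assay(x, "npep"))

#' @rdname ProteinQuantMatrix-utils
#' @export
setMethod("idPvalue", "ProteinQuantMatrix",
          function(x) stats::setNames(rowData(x)$id_pvalue, rownames(x)))

#' @rdname ProteinQuantMatrix-utils
#' @export
setMethod("nMissing", "ProteinQuantMatrix",
          function(x) sum(is.na(assay(x, "quantity"))))

#' @rdname ProteinQuantMatrix-utils
#' @export
setMethod("isImputed", "ProteinQuantMatrix", function(x) x@imputed)

setMethod("show", "ProteinQuantMatrix", function(object) {
  cat("ProteinQuantMatrix:", nrow(object), "proteins x",
      ncol(object), "samples\n")
  cat("  missing cells:", nMissing(object),
      sprintf("(%.2f%%)", 100 * nMissing(object) /
                max(1, nrow(object) * ncol(object))), "\n")
  cat("  imputed:", object@imputed, "\n")
  if ("tissue" %in% colnames(colData(object))) {
    tt <- table(colData(object)$tissue)
    cat("  design:", paste(names(tt), tt, sep = "=", collapse = ", "), "\n")
  } else {
    cat("  design: no sample metadata attached\n")
  }
})

#' Accessors for GOAnnotationMap
#'
#' `termSizes()` returns the number of dataset proteins per term;
#' `termProteins()` the accession set of one term; `names()` and
#' `length()` behave as for a list.
#'
#' @param x a [GOAnnotationMap-class].
#' @param term a single GO term identifier.
#' @name GOAnnotationMap-utils
NULL

#' @rdname GOAnnotationMap-utils
#' @export
setMethod("termSizes", "GOAnnotationMap",
          function(x) lengths(x@terms))

#' @rdname GOAnnotationMap-utils
#' @export
setMethod("termProteins", "GOAnnotationMap", function(x, term) {
  if (!term %in% names(x@terms))
    stop("unknown GO term: ", term)
  as.character(x@terms[[term]])
})

#' @rdname GOAnnotationMap-utils
#' @export
setMethod("names", "GOAnnotationMap", function(x) names(x@terms))

#' @rdname GOAnnotationMap-utils
#' @export
setMethod("length", "GOAnnotationMap", function(x) length(x@terms))

setMethod("show", "GOAnnotationMap", function(object) {
  sz <- termSizes(object)
  cat("GOAnnotationMap:", length(object), "terms over",
      length(unique(unlist(object@terms))), "proteins\n")
  if (length(sz))
    cat("  term sizes: min", min(sz), "median", stats::median(sz),
        "max", max(sz), "\n")
})

setMethod("show", "MissingnessClassification", function(object) {
  tab <- table(factor(object@labels,
                      levels = c("observed", "impute_lod", "leave_mar")))
  cat("MissingnessClassification (mode:", object@mode, ")\n")
  cat("  observed:", tab[["observed"]],
      " impute_lod:", tab[["impute_lod"]],
      " leave_mar:", tab[["leave_mar"]], "\n")
  cat("  imputation value (dataset minimum):", object@globalMinimum, "\n")
})
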