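#' Sample-specific GO index for one term
#'
#' Each protein's quantity is normalized to that protein's average
#' observed quantity over *all* samples (both tissues), and the
#' normalized values of the term's proteins are averaged per sample. For
#' complete data the index therefore has grand mean 1 and is invariant
#' to rescaling the whole matrix. Samples where some term proteins are
#' missing use the mean of the available normalized values;
#' `n_proteins_used` records how many.
#'
#' @param x an imputed [ProteinQuantMatrix-class].
#' @param annotations a [GOAnnotationMap-class].
#' @param termId a single term.
#' @return `data.frame` with columns `sample_id`, `index`,
#'   `n_proteins_used`; the term id is kept in `attr(, "term_id")`.
#' @export
computeTermIndex <- function(x, annotations, termId) {
  prots <- intersect(termProteins(annotations, termId), rownames(x))
  if (!length(prots))
    stop("term ", termId, " has no protein in the matrix")
  q <- quantities(x)[prots, , drop = FALSE]
  pmean <- rowMeans(q, na.rm = TRUE)
  norm <- q / pmean
  idx <- colMeans(norm, na.rm = TRUE)
  nused <- as.integer(colSums(!is.na(norm)))
  if (any(nused == 0L)) {
    warning("sample(s) with no available protein for ", termId, ": ",
            paste(colnames(q)[nused == 0L], collapse = ", "))
    idx[nused == 0L] <- NA_real_
  }
  out <- data.frame(sample_id = colnames(q), index = idx,
                    n_proteins_used = nused, row.names = NULL)
  attr(out, "term_id") <- termId
  out
}

#' Mixed-model correlation between two GO indices within a tissue
#'
#' Fits `log(index_y) ~ log(index_x)` with a random intercept per
#' patient on the samples of one tissue, and returns the slope with its
#' two-sided P value. If the patient-intercept model cannot be fit the
#' model simplifies to ordinary linear regression (recorded in
#' `structure`).
#'
#' @param indexY,indexX [computeTermIndex()] results (response,
#'   predictor).
#' @param x the [ProteinQuantMatrix-class] supplying the design.
#' @param tissue `"cNF"` or `"skin"`.
#' @return list with `slope`, `se`, `p`, `n`, `structure`.
#' @export
correlateIndices <- function(indexY, indexX, x, tissue = c("cNF", "skin")) {
  tissue <- match.arg(tissue)
  cd <- .sampleData(x)
  ids <- cd$sample_id[cd$tissue == tissue]
  tab <- data.frame(
    sample_id = ids,
    patient_id = cd$patient_id[match(ids, cd$sample_id)],
    y = log(indexY$index[match(ids, indexY$sample_id)]),
    x = log(indexX$index[match(ids, indexX$sample_id)]))
  tab <- tab[is.finite(tab$y) & is.finite(tab$x), , drop = FALSE]
  if (nrow(tab) < 3L)
    stop("fewer than 3 usable samples in tissue ", tissue)
  fit <- tryCatch(
    suppressWarnings(suppressMessages(lmerTest::lmer(
      y ~ x + (1 | patient_id), data = tab, REML = TRUE,
      control = lme4::lmerControl(check.conv.singular = "ignore")))),
    error = function(e) NULL)
  if (!is.null(fit)) {
    sm <- tryCatch(summary(fit)$coefficients, error = function(e) NULL)
    if (!is.null(sm) && "x" %in% rownames(sm) &&
        is.finite(sm["x", "Std. Error"]) &&
        is.finite(sm["x", "Pr(>|t|)"])) {
      return(list(slope = sm["x", "Estimate"], se = sm["x", "Std. Error"],
                  p = sm["x", "Pr(>|t|)"], n = nrow(tab),
                  structure = "patient_intercept"))
    }
  }
  lfit <- suppressWarnings(summary(lm(y ~ x, data = tab)))$coefficients
  list(slope = lfit["x", "Estimate"], se = lfit["x", "Std. Error"],
       p = lfit["x", "Pr(>|t|)"], n = nrow(tab), structure = "ols")
}

#' Correlation panel between two groups of GO terms
#'
#' Computes [correlateIndices()] for every (response, predictor) term
#' pair within one tissue. The default pairs the process group
#' angiogenesis / cell population proliferation / positive regulation of
#' the MAPK cascade against extracellular-matrix disassembly and the
#' protein, carbohydrate and lipid metabolic processes. P values are
#' reported uncorrected.
#'
#' @param x an imputed [ProteinQuantMatrix-class].
#' @param annotations a [GOAnnotationMap-class].
#' @param yTerms,xTerms term identifier vectors (responses, predictors).
#' @param tissue `"cNF"` or `"skin"`.
#' @return `data.frame` with one row per (y, x) pair: `term_y`,
#'   `term_x`, `slope`, `se`, `p`, `n`, `structure`.
#' @export
correlationPanel <- function(x, annotations,
                             yTerms = c("GO:0001525", "GO:0008283",
                                        "GO:0043410"),
                             xTerms = c("GO:0022617", "GO:0044267",
                                        "GO:0005975", "GO:0006629"),
                             tissue = c("cNF", "skin")) {
  tissue <- match.arg(tissue)
  idx <- lapply(stats::setNames(unique(c(yTerms, xTerms)),
                                unique(c(yTerms, xTerms))),
                function(tid) computeTermIndex(x, annotations, tid))
  grid <- expand.grid(term_y = yTerms, term_x = xTerms,
                      stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    r <- correlateIndices(idx[[grid$term_y[i]]], idx[[grid$term_x[i]]],
                          x, tissue)
    data.frame(term_y = grid$term_y[i], term_x = grid$term_x[i],
               slope = r$slope, se = r$se, p = r$p, n = r$n,
               structure = r$structure)
  })
  do.call(rbind, res)
}
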