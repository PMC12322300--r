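## Exact threshold comparison: detection/missing fractions are ratios of
## small integers, and thresholds like 0.8 are not exactly representable
## in binary floating point (0.8 * 15 > 12 in double arithmetic). The
## user threshold is rationalized to denominator 1e6 and both sides are
## compared as integer-valued doubles, which is exact for any threshold
## stated to <= 6 decimals and any count below 2^40.
.fracGE <- function(num, den, frac) {   # num/den >= frac
  num * 1e6 >= round(frac * 1e6) * den
}
.fracGT <- function(num, den, frac) {   # num/den > frac
  num * 1e6 > round(frac * 1e6) * den
}

#' Filter low-confidence protein identifications
#'
#' Retains exactly the proteins with identification P value strictly
#' below `pMax` and at least `minPeptides` peptides in at least one
#' sample. Samples and quantities are untouched.
#'
#' @param x a [ProteinQuantMatrix-class].
#' @param pMax identification P value cutoff (strict `<`).
#' @param minPeptides minimum peptide count required in some sample.
#' @return the filtered [ProteinQuantMatrix-class].
#' @export
filterLowConfidence <- function(x, pMax = 0.05, minPeptides = 2L) {
  keep <- rowData(x)$id_pvalue < pMax &
    apply(peptideCounts(x), 1L, max) >= minPeptides
  if (!any(keep))
    stop("no protein passes the confidence filter")
  x[keep, ]
}

#' Classify missing cells as below-LOD or missing-at-random
#'
#' Implements the 80/20 rule: a protein's detection in a tissue is
#' *reliable* when it is quantified in at least `reliableFraction` (80%)
#' of that tissue's samples. If one tissue is reliable and the other
#' tissue's missing fraction exceeds `1 - reliableFraction` (20%), the
#' missing cells in the unreliable tissue are attributed to expression
#' below the limit of detection and labeled `impute_lod`; with
#' `mode = "all"` (default) every such missing cell is labeled, with
#' `mode = "excess"` only the count above the 20% allowance (cells taken
#' in sample order). A protein detected below the threshold in both
#' tissues gets no `impute_lod` label at all; every other missing cell
#' is `leave_mar`. Fractions are compared exactly (no floating-point
#' boundary artifacts at e.g. 12/15).
#'
#' @param x a [ProteinQuantMatrix-class] with sample metadata attached.
#' @param reliableFraction detection fraction defining reliability
#'   (`>=`); its complement is the allowed missing fraction (`>` for
#'   excess).
#' @param mode `"all"` or `"excess"` (see above).
#' @return a [MissingnessClassification-class].
#' @export
classifyMissingness <- function(x, reliableFraction = 0.8,
                                mode = c("all", "excess")) {
  mode <- match.arg(mode)
  cd <- .sampleData(x)
  q <- quantities(x)
  tissues <- levels(cd$tissue)
  n_by_tissue <- table(cd$tissue)
  if (any(n_by_tissue == 0L))
    stop("both tissues must have at least one sample")
  det <- vapply(tissues, function(tt) {
    rowSums(!is.na(q[, cd$tissue == tt, drop = FALSE]))
  }, numeric(nrow(q)))
  dim(det) <- c(nrow(q), length(tissues))
  dimnames(det) <- list(rownames(q), tissues)
  detfrac <- sweep(det, 2L, as.numeric(n_by_tissue[tissues]), "/")
  labels <- matrix("observed", nrow(q), ncol(q), dimnames = dimnames(q))
  labels[is.na(q)] <- "leave_mar"
  for (tt in tissues) {
    other <- setdiff(tissues, tt)
    n_t <- as.integer(n_by_tissue[[tt]])
    n_o <- as.integer(n_by_tissue[[other]])
    n_miss <- n_t - det[, tt]
    lod_protein <- .fracGE(det[, other], n_o, reliableFraction) &
      .fracGT(n_miss, n_t, 1 - reliableFraction)
    cols <- which(cd$tissue == tt)
    for (p in which(lod_protein)) {
      miss_cols <- cols[is.na(q[p, cols])]
      if (mode == "excess") {
        allowance <- floor(n_t * (1 - reliableFraction) + 1e-9)
        miss_cols <- miss_cols[seq_len(max(0L, length(miss_cols) -
                                             allowance))]
      }
      labels[p, miss_cols] <- "impute_lod"
    }
  }
  gmin <- suppressWarnings(min(q, na.rm = TRUE))
  if (!is.finite(gmin)) gmin <- NA_real_
  new("MissingnessClassification", labels = labels, detection = detfrac,
      globalMinimum = gmin, mode = mode)
}

#' Impute below-LOD missing values with the dataset minimum
#'
#' Every cell labeled `impute_lod` is set to the single minimum quantity
#' observed anywhere in the matrix (informative missingness: the value
#' was too low to detect). `leave_mar` cells remain missing; observed
#' cells are never modified.
#'
#' @param x the [ProteinQuantMatrix-class] the classification was
#'   computed on.
#' @param classification a [MissingnessClassification-class].
#' @return a list with `matrix` (the imputed
#'   [ProteinQuantMatrix-class], flagged via [isImputed()]) and `report`,
#'   a list of imputation counts: total, by tissue, proteins touched,
#'   remaining missing cells/proteins and per-sample missing fractions
#'   before/after.
#' @export
imputeBelowLOD <- function(x, classification) {
  stopifnot(is(classification, "MissingnessClassification"))
  q <- quantities(x)
  lab <- classification@labels
  if (!identical(dim(lab), dim(q)))
    stop("classification does not match this matrix")
  cd <- .sampleData(x)
  before <- colMeans(is.na(q))
  todo <- lab == "impute_lod" & is.na(q)
  q[todo] <- classification@globalMinimum
  by_tissue <- vapply(levels(cd$tissue), function(tt)
    sum(todo[, cd$tissue == tt, drop = FALSE]), integer(1))
  report <- list(
    n_imputed_total = sum(todo),
    n_imputed_by_tissue = as.list(by_tissue),
    n_proteins_touched = sum(rowSums(todo) > 0L),
    n_remaining_missing = sum(is.na(q)),
    n_proteins_with_remaining_missing = sum(rowSums(is.na(q)) > 0L),
    imputation_value = classification@globalMinimum,
    per_sample_missing_before = as.list(before),
    per_sample_missing_after = as.list(colMeans(is.na(q))))
  out <- x
  SummarizedExperiment::assay(out, "quantity") <- q
  out@imputed <- TRUE
  validObject(out)
  list(matrix = out, report = report)
}

#' Summarize missingness per sample and per donor
#'
#' @param x a [ProteinQuantMatrix-class] (sample metadata attached for
#'   the per-donor block).
#' @return a list: `per_sample` (`data.frame` of missing fractions) and,
#'   when design metadata is present, `per_donor` — per patient and
#'   tissue, the fraction of proteins observed in at least one sample
#'   and in all samples of that donor.
#' @export
missingnessSummary <- function(x) {
  q <- quantities(x)
  per_sample <- data.frame(sample_id = colnames(q),
                           missing_fraction = colMeans(is.na(q)))
  rownames(per_sample) <- NULL
  out <- list(per_sample = per_sample)
  cd <- try(.sampleData(x), silent = TRUE)
  if (!inherits(cd, "try-error")) {
    combos <- unique(cd[, c("patient_id", "tissue")])
    per_donor <- do.call(rbind, lapply(seq_len(nrow(combos)), function(i) {
      cols <- cd$patient_id == combos$patient_id[i] &
        cd$tissue == combos$tissue[i]
      obs <- !is.na(q[, cols, drop = FALSE])
      data.frame(patient_id = combos$patient_id[i],
                 tissue = as.character(combos$tissue[i]),
                 frac_in_any_sample = mean(rowSums(obs) > 0L),
                 frac_in_all_samples = mean(rowSums(obs) == sum(cols)))
    }))
    out$per_donor <- per_donor
  }
  out
}
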