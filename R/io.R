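#' Read a protein quantity matrix from TSV
#'
#' Two layouts are supported. `"wide"`: one row per protein with columns
#' `protein_id`, `id_pvalue`, optionally `seq_coverage`, then one column
#' per sample; missing cells are empty fields (never 0 — zero is not a
#' valid intensity). Peptide counts come from a companion wide TSV
#' (`protein_id` plus the same sample columns), by default
#' `<path>` with `_peptides` inserted before the extension. `"long"`: one
#' row per observed (protein, sample) cell with columns `protein_id`,
#' `sample_id`, `quantity`, `peptide_count`, `id_pvalue`; a missing cell
#' is simply an absent row.
#'
#' @param path TSV file path.
#' @param layout `"wide"` or `"long"`.
#' @param peptidePath companion peptide-count TSV for the wide layout;
#'   ignored for long.
#' @return a [ProteinQuantMatrix-class] (no sample metadata attached).
#' @export
readQuantMatrix <- function(path, layout = c("wide", "long"),
                            peptidePath = NULL) {
  layout <- match.arg(layout)
  if (!file.exists(path)) stop("file not found: ", path)
  if (layout == "wide") {
    tab <- utils::read.delim(path, check.names = FALSE,
                             colClasses = NA, na.strings = "")
    if (anyDuplicated(tab$protein_id))
      stop("duplicate protein identifiers in ", path)
    meta_cols <- intersect(c("protein_id", "id_pvalue", "seq_coverage"),
                           colnames(tab))
    sample_cols <- setdiff(colnames(tab), meta_cols)
    if (anyDuplicated(sample_cols))
      stop("duplicate sample identifiers in ", path)
    q <- as.matrix(tab[, sample_cols, drop = FALSE])
    rownames(q) <- tab$protein_id
    if (is.null(peptidePath))
      peptidePath <- sub("(\\.[^.]+)?$", "_peptides\\1", path)
    ptab <- utils::read.delim(peptidePath, check.names = FALSE,
                              na.strings = "")
    np <- as.matrix(ptab[, sample_cols, drop = FALSE])
    rownames(np) <- ptab$protein_id
    np <- np[rownames(q), , drop = FALSE]
    np[is.na(np)] <- 0L
    .checkPositive(q)
    ProteinQuantMatrix(q, np, idPvalue = tab$id_pvalue,
                       seqCoverage = tab$seq_coverage)
  } else {
    tab <- utils::read.delim(path, na.strings = "")
    need <- c("protein_id", "sample_id", "quantity", "peptide_count",
              "id_pvalue")
    if (!all(need %in% colnames(tab)))
      stop("long layout requires columns: ", paste(need, collapse = ", "))
    if (anyDuplicated(tab[, c("protein_id", "sample_id")]))
      stop("duplicate (protein, sample) rows in ", path)
    prots <- unique(tab$protein_id)
    samps <- unique(tab$sample_id)
    q <- matrix(NA_real_, length(prots), length(samps),
                dimnames = list(prots, samps))
    np <- matrix(0L, length(prots), length(samps),
                 dimnames = list(prots, samps))
    idx <- cbind(match(tab$protein_id, prots), match(tab$sample_id, samps))
    q[idx] <- tab$quantity
    np[idx] <- as.integer(tab$peptide_count)
    pv <- tab$id_pvalue[match(prots, tab$protein_id)]
    cov <- if ("seq_coverage" %in% colnames(tab))
      tab$seq_coverage[match(prots, tab$protein_id)] else NULL
    .checkPositive(q)
    ProteinQuantMatrix(q, np, idPvalue = pv, seqCoverage = cov)
  }
}

.checkPositive <- function(q) {
  bad <- which(!is.na(q) & q <= 0, arr.ind = TRUE)
  if (nrow(bad))
    stop("non-positive quantity at (",
         rownames(q)[bad[1, 1]], ", ", colnames(q)[bad[1, 2]], ")")
  invisible(TRUE)
}

#' Write a protein quantity matrix to TSV
#'
#' Inverse of [readQuantMatrix()]: wide layout writes the quantity table
#' plus a companion peptide-count TSV; long layout writes one row per
#' observed cell. Missing cells are empty fields (wide) or absent rows
#' (long), so round trips preserve the missing mask exactly.
#'
#' @param x a [ProteinQuantMatrix-class].
#' @param path output TSV path.
#' @param layout `"wide"` or `"long"`.
#' @param peptidePath companion output path for the wide layout.
#' @export
writeQuantMatrix <- function(x, path, layout = c("wide", "long"),
                             peptidePath = NULL) {
  layout <- match.arg(layout)
  q <- quantities(x)
  np <- peptideCounts(x)
  if (layout == "wide") {
    tab <- data.frame(protein_id = rownames(q),
                      id_pvalue = rowData(x)$id_pvalue,
                      check.names = FALSE)
    if ("seq_coverage" %in% colnames(rowData(x)))
      tab$seq_coverage <- rowData(x)$seq_coverage
    tab <- cbind(tab, as.data.frame(q, check.names = FALSE))
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "")
    if (is.null(peptidePath))
      peptidePath <- sub("(\\.[^.]+)?$", "_peptides\\1", path)
    ptab <- cbind(data.frame(protein_id = rownames(np)),
                  as.data.frame(np, check.names = FALSE))
    utils::write.table(ptab, peptidePath, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "")
  } else {
    obs <- which(!is.na(q), arr.ind = TRUE)
    obs <- obs[order(obs[, 1], obs[, 2]), , drop = FALSE]
    tab <- data.frame(
      protein_id = rownames(q)[obs[, 1]],
      sample_id = colnames(q)[obs[, 2]],
      quantity = q[obs],
      peptide_count = np[obs],
      id_pvalue = rowData(x)$id_pvalue[obs[, 1]])
    if ("seq_coverage" %in% colnames(rowData(x)))
      tab$seq_coverage <- rowData(x)$seq_coverage[obs[, 1]]
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "")
  }
  invisible(path)
}

#' Read and validate per-sample design metadata
#'
#' Expects a TSV with columns `sample_id`, `patient_id`, `lesion_id`,
#' `tissue` and optionally `growing`. A lesion identifies one excision
#' pair: it must map to exactly one patient, at most one cNF sample and
#' at most one skin sample. `tissue` must be `cNF` or `skin`; a missing
#' `growing` column defaults every sample to `"unknown"`.
#'
#' @param path TSV file path.
#' @return a validated `data.frame` with `tissue` as a factor with levels
#'   `c("skin", "cNF")` (skin = model baseline).
#' @export
readSampleMetadata <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.delim(path, colClasses = "character")
  validateSampleTable(tab)
}

#' @rdname readSampleMetadata
#' @param tab a data.frame with the columns above (in-memory variant).
#' @export
validateSampleTable <- function(tab) {
  need <- c("sample_id", "patient_id", "lesion_id", "tissue")
  if (!all(need %in% colnames(tab)))
    stop("sample metadata requires columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(tab$sample_id))
    stop("duplicate sample_id in sample metadata")
  bad <- setdiff(unique(tab$tissue), c("cNF", "skin"))
  if (length(bad))
    stop("unknown tissue label(s): ", paste(bad, collapse = ", "))
  if (!"growing" %in% colnames(tab)) {
    tab$growing <- "unknown"
  } else {
    tab$growing[is.na(tab$growing) | tab$growing == ""] <- "unknown"
    badg <- setdiff(unique(tab$growing), c("yes", "no", "unknown"))
    if (length(badg))
      stop("unknown growing label(s): ", paste(badg, collapse = ", "))
  }
  per <- table(tab$lesion_id, tab$tissue)
  if (any(per > 1)) {
    off <- rownames(per)[apply(per > 1, 1, any)]
    stop("lesion(s) with more than one sample of a tissue: ",
         paste(off, collapse = ", "))
  }
  np <- tapply(tab$patient_id, tab$lesion_id,
               function(p) length(unique(p)))
  if (any(np > 1))
    stop("lesion(s) mapped to more than one patient: ",
         paste(names(np)[np > 1], collapse = ", "))
  tab$tissue <- factor(tab$tissue, levels = c("skin", "cNF"))
  tab$growing <- factor(tab$growing, levels = c("yes", "no", "unknown"))
  rownames(tab) <- tab$sample_id
  tab
}

#' Attach sample design metadata to a quantity matrix
#'
#' Joins a validated sample table (see [readSampleMetadata()]) onto the
#' columns of a [ProteinQuantMatrix-class]. Every matrix column must be
#' described by the table.
#'
#' @param x a [ProteinQuantMatrix-class].
#' @param samples a `data.frame` as returned by [readSampleMetadata()].
#' @return `x` with populated `colData()`.
#' @export
attachSampleData <- function(x, samples) {
  samples <- validateSampleTable(as.data.frame(samples))
  miss <- setdiff(colnames(x), samples$sample_id)
  if (length(miss))
    stop("sample metadata missing for: ", paste(miss, collapse = ", "))
  samples <- samples[colnames(x), , drop = FALSE]
  colData(x) <- DataFrame(samples)
  x
}

.sampleData <- function(x) {
  cd <- as.data.frame(colData(x))
  if (!all(c("patient_id", "lesion_id", "tissue") %in% colnames(cd)))
    stop("no sample metadata attached; call attachSampleData() first")
  cd
}

#' Read GO annotations and restrict them to the dataset
#'
#' Accepts either a two-column `protein_id` / `term_id` TSV (optionally
#' with `term_name` and `namespace` columns) or a GAF 2.2 file
#' (17 tab-separated columns, `!` comment lines; the DB object ID in
#' column 2 is the join key, the GO ID is column 5 and rows whose
#' qualifier contains `NOT` are excluded). Annotations are intersected
#' with the proteins present in `matrix`; terms left empty are dropped.
#' No ancestor propagation over the GO graph is performed — annotations
#' are used as listed.
#'
#' @param path annotation file path.
#' @param format `"tsv"` or `"gaf"`.
#' @param matrix the [ProteinQuantMatrix-class] defining the protein
#'   universe.
#' @return a [GOAnnotationMap-class].
#' @export
readGOAnnotations <- function(path, format = c("tsv", "gaf"), matrix) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "tsv") {
    tab <- utils::read.delim(path, colClasses = "character")
    if (!all(c("protein_id", "term_id") %in% colnames(tab)))
      stop("annotation TSV requires columns protein_id, term_id")
    info <- unique(tab[, intersect(c("term_id", "term_name", "namespace"),
                                   colnames(tab)), drop = FALSE])
  } else {
    lines <- readLines(path)
    lines <- lines[!startsWith(lines, "!") & nzchar(lines)]
    fields <- strsplit(lines, "\t", fixed = TRUE)
    ok <- lengths(fields) >= 15L
    if (any(!ok))
      warning(sum(!ok), " malformed GAF line(s) skipped")
    fields <- fields[ok]
    qualifier <- vapply(fields, `[`, "", 4L)
    isnot <- vapply(strsplit(qualifier, "|", fixed = TRUE),
                    function(q) "NOT" %in% q, TRUE)
    fields <- fields[!isnot]
    aspect <- vapply(fields, `[`, "", 9L)
    tab <- data.frame(protein_id = vapply(fields, `[`, "", 2L),
                      term_id = vapply(fields, `[`, "", 5L),
                      namespace = c(P = "biological_process",
                                    F = "molecular_function",
                                    C = "cellular_component")[aspect])
    info <- unique(tab[, c("term_id", "namespace")])
  }
  tab <- tab[tab$protein_id %in% rownames(matrix), , drop = FALSE]
  if (!nrow(tab))
    stop("no annotated protein overlaps the quantity matrix")
  terms <- split(tab$protein_id, tab$term_id)
  info <- info[match(names(terms), info$term_id), , drop = FALSE]
  if (!"term_name" %in% colnames(info)) info$term_name <- NA_character_
  if (!"namespace" %in% colnames(info)) info$namespace <- NA_character_
  GOAnnotationMap(terms, termInfo = info[, c("term_id", "term_name",
                                             "namespace")])
}

#' Format a ratio with its confidence interval
#'
#' Renders `"0.41 (0.32 to 0.52)"`-style strings with three significant
#' digits, the convention used in the package's result tables.
#'
#' @param ratio,lo,hi numeric vectors.
#' @return character vector.
#' @export
formatRatioCI <- function(ratio, lo, hi) {
  f <- function(x) vapply(x, function(v) format(signif(v, 3),
                                                scientific = FALSE), "")
  paste0(f(ratio), " (", f(lo), " to ", f(hi), ")")
}

#' Write a differential-abundance results table
#'
#' Writes one row per effect estimate with columns `target`,
#' `n_proteins`, `ratio`, `ci_low`, `ci_high`, `estimate_ci` (the
#' rendered `"0.41 (0.32 to 0.52)"` string), `p_plain`, `p_corrected`
#' (rendered capped at `1.000`) and `model_structure_used`.
#'
#' @param estimates a `data.frame` of estimates as returned by
#'   [testGOTerm()] / [testProtein()] (possibly row-bound).
#' @param path output TSV path.
#' @export
writeResultsTable <- function(estimates, path) {
  if (is.null(estimates) || nrow(estimates) == 0L) {
    warning("no estimates to write; skipping ", path)
    return(invisible(NULL))
  }
  out <- data.frame(
    target = estimates$target,
    n_proteins = estimates$n_proteins,
    ratio = signif(estimates$ratio, 6),
    ci_low = signif(estimates$ci_low, 6),
    ci_high = signif(estimates$ci_high, 6),
    estimate_ci = formatRatioCI(estimates$ratio, estimates$ci_low,
                                estimates$ci_high),
    p_plain = signif(estimates$p_plain, 4),
    p_corrected = sprintf("%.3f", pmin(1, estimates$p_corrected)),
    model_structure_used = estimates$model_structure_used)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
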