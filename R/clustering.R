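#' Prepare a sample x protein grid for clustering
#'
#' Complete-case proteins only (any remaining missing value excludes the
#' protein), natural-log transform, and optionally per-protein z-scoring
#' so every protein contributes on a comparable scale. Under
#' `"zscore_log"` proteins with zero variance are dropped (their z-score
#' is undefined); under `"log_only"` constant proteins are retained.
#'
#' @param x an imputed [ProteinQuantMatrix-class].
#' @param scaling `"zscore_log"` (default) or `"log_only"`.
#' @return numeric sample x protein matrix.
#' @export
prepareClusterMatrix <- function(x, scaling = c("zscore_log", "log_only")) {
  scaling <- match.arg(scaling)
  q <- quantities(x)
  complete <- rowSums(is.na(q)) == 0L
  if (sum(complete) < 2L)
    stop("fewer than 2 proteins with complete data")
  grid <- t(log(q[complete, , drop = FALSE]))
  if (scaling == "zscore_log") {
    sds <- apply(grid, 2L, stats::sd)
    if (any(sds == 0)) {
      message("dropping ", sum(sds == 0),
              " zero-variance protein(s) before z-scoring")
      grid <- grid[, sds > 0, drop = FALSE]
      sds <- sds[sds > 0]
    }
    grid <- scale(grid, center = TRUE, scale = TRUE)
    attr(grid, "scaled:center") <- NULL
    attr(grid, "scaled:scale") <- NULL
  }
  grid
}

#' Agglomerative clustering of samples
#'
#' Complete-linkage hierarchical clustering (inter-cluster distance =
#' maximum pairwise distance, which makes merge heights monotone
#' non-decreasing) on Euclidean distances by default.
#'
#' @param grid sample x protein matrix from [prepareClusterMatrix()].
#' @param linkage agglomeration method (default `"complete"`).
#' @param metric distance metric for [stats::dist()].
#' @return an [stats::hclust] dendrogram over the samples.
#' @export
clusterSamples <- function(grid, linkage = "complete",
                           metric = "euclidean") {
  if (nrow(grid) < 2L) stop("need at least 2 samples")
  if (any(!is.finite(grid))) stop("non-finite values in cluster matrix")
  stats::hclust(stats::dist(grid, method = metric), method = linkage)
}

#' Tissue purity of the two-cluster cut
#'
#' Cuts the dendrogram into two clusters and scores how well the cut
#' separates the tissues: the majority-tissue count summed over both
#' clusters, divided by the number of samples. 1 means perfect
#' separation; values near 0.5-0.6 are what random labels give.
#'
#' @param dend an [stats::hclust] object over samples.
#' @param tissue character/factor of tissue labels named by (or parallel
#'   to) the dendrogram labels.
#' @return purity in [0.5, 1].
#' @export
tissueBipartitionScore <- function(dend, tissue) {
  if (!is.null(names(tissue))) tissue <- tissue[dend$labels]
  tissue <- as.character(tissue)
  if (length(unique(tissue)) < 2L)
    stop("need both tissues to score a bipartition")
  cl <- stats::cutree(dend, k = 2L)
  sum(vapply(split(tissue, cl), function(tt) max(table(tt)), 0)) /
    length(tissue)
}

#' Export a dendrogram
#'
#' `"newick"` writes a Newick tree (branch lengths are merge-height
#' differences, via [ape::as.phylo()]); `"merge_table"` writes a TSV of
#' the agglomeration schedule (`left`, `right`, `height`, `size`, with
#' negative entries denoting leaves as in [stats::hclust()]).
#'
#' @param dend an [stats::hclust] object.
#' @param path output file path.
#' @param format `"newick"` or `"merge_table"`.
#' @export
exportDendrogram <- function(dend, path,
                             format = c("newick", "merge_table")) {
  format <- match.arg(format)
  if (format == "newick") {
    ape::write.tree(ape::as.phylo(dend), file = path)
  } else {
    sizes <- .mergeSizes(dend)
    tab <- data.frame(left = dend$merge[, 1], right = dend$merge[, 2],
                      height = dend$height, size = sizes)
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

.mergeSizes <- function(dend) {
  n <- nrow(dend$merge)
  sizes <- integer(n)
  for (i in seq_len(n)) {
    l <- dend$merge[i, 1]; r <- dend$merge[i, 2]
    sizes[i] <- (if (l < 0) 1L else sizes[l]) +
      (if (r < 0) 1L else sizes[r])
  }
  sizes
}

#' Per-patient and pooled clustering
#'
#' Mirrors the two views used to describe tumor/skin similarity: one
#' dendrogram per donor over that donor's samples, plus a pooled
#' dendrogram over all samples, each with its tissue bipartition purity.
#'
#' @param x an imputed [ProteinQuantMatrix-class] with design metadata.
#' @param scaling passed to [prepareClusterMatrix()].
#' @return list with `pooled` (list: `dendrogram`, `purity`) and
#'   `per_patient` (named list of the same shape).
#' @export
clusterStudy <- function(x, scaling = "zscore_log") {
  cd <- .sampleData(x)
  run <- function(sub) {
    grid <- prepareClusterMatrix(sub, scaling = scaling)
    dend <- clusterSamples(grid)
    tt <- stats::setNames(as.character(.sampleData(sub)$tissue),
                          colnames(sub))
    list(dendrogram = dend, purity = tissueBipartitionScore(dend, tt))
  }
  per_patient <- lapply(stats::setNames(unique(cd$patient_id),
                                        unique(cd$patient_id)),
                        function(p) run(x[, cd$patient_id == p]))
  list(pooled = run(x), per_patient = per_patient)
}
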