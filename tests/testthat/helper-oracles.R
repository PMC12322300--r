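# Independent oracles and fixture builders. These re-derive the rules
# from first principles, deliberately sharing no code with the package
# internals they check.

# Brute-force 80/20 missingness classification: for every protein and
# every tissue, re-apply the verbal rule directly. Thresholds fixed at
# 4/5 detection and 1/5 allowance, compared as integer cross-products.
bruteClassify <- function(q, tissue) {
  tissues <- unique(as.character(tissue))
  labels <- matrix("observed", nrow(q), ncol(q), dimnames = dimnames(q))
  labels[is.na(q)] <- "leave_mar"
  for (p in seq_len(nrow(q))) {
    for (tt in tissues) {
      other <- setdiff(tissues, tt)
      in_t <- which(tissue == tt)
      in_o <- which(tissue == other)
      det_o <- sum(!is.na(q[p, in_o]))
      miss_t <- sum(is.na(q[p, in_t]))
      reliable_other <- det_o * 5L >= 4L * length(in_o)
      excess <- miss_t * 5L > length(in_t)
      if (reliable_other && excess)
        labels[p, in_t[is.na(q[p, in_t])]] <- "impute_lod"
    }
  }
  labels
}

# Brute-force O(n^3) complete-linkage agglomeration over a distance
# matrix; returns merge heights and the partition after each merge.
bruteCompleteLinkage <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  partitions <- list()
  while (length(clusters) > 1L) {
    best <- c(NA, NA); best_h <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (i >= j) next
        h <- max(d[clusters[[i]], clusters[[j]]])
        if (h < best_h) { best_h <- h; best <- c(i, j) }
      }
    }
    merged <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters <- c(clusters[-best], list(merged))
    heights <- c(heights, best_h)
    part <- integer(n)
    for (k in seq_along(clusters)) part[clusters[[k]]] <- k
    partitions[[length(partitions) + 1L]] <- part
  }
  list(heights = heights, partitions = partitions)
}

samePartition <- function(a, b) {
  length(unique(paste(a, b))) == length(unique(a)) &&
    length(unique(a)) == length(unique(b))
}

# Quick ProteinQuantMatrix with an attached paired design.
makeToyPQM <- function(q, npep = NULL, id_pvalue = NULL,
                       tissue = NULL, patient = NULL, lesion = NULL) {
  if (is.null(npep)) npep <- matrix(3L, nrow(q), ncol(q),
                                    dimnames = dimnames(q))
  if (is.null(id_pvalue)) id_pvalue <- rep(0.01, nrow(q))
  ns <- ncol(q)
  if (is.null(tissue)) tissue <- rep(c("cNF", "skin"), length.out = ns)
  if (is.null(lesion)) lesion <- paste0("L", rep(seq_len(ceiling(ns / 2)),
                                                 each = 2)[seq_len(ns)])
  if (is.null(patient)) patient <- "pat1"
  samples <- data.frame(sample_id = colnames(q),
                        patient_id = rep_len(patient, ns),
                        lesion_id = lesion, tissue = tissue,
                        growing = "unknown")
  ProteinQuantMatrix(q, npep, idPvalue = id_pvalue, sampleData = samples)
}

# Random small matrix with a balanced two-tissue design and random gaps.
randomSmallPQM <- function(n_prot, n_samp_per_tissue, miss_rate) {
  ns <- 2L * n_samp_per_tissue
  q <- matrix(exp(rnorm(n_prot * ns, 8, 1)), n_prot, ns,
              dimnames = list(sprintf("P%02d", seq_len(n_prot)),
                              sprintf("S%02d", seq_len(ns))))
  q[runif(length(q)) < miss_rate] <- NA
  tissue <- rep(c("cNF", "skin"), each = n_samp_per_tissue)
  makeToyPQM(q, tissue = tissue,
             lesion = paste0("L", rep(seq_len(n_samp_per_tissue), 2)))
}
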