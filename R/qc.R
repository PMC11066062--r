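#' Most variably accessible regions
#'
#' @param mat Region-by-sample numeric matrix (VST values).
#' @param n Number of regions to return.
#' @return Region ids of the `n` regions with largest sample variance;
#'   ties broken by region-id order.
#' @export
top_variable_regions <- function(mat, n) {
  if (n <= 0) abort_validation("n must be positive")
  if (n > nrow(mat)) abort_validation("n exceeds the number of regions")
  v <- row_vars(mat)
  ord <- order(-v, rownames(mat))
  rownames(mat)[ord[seq_len(n)]]
}

#' Principal component analysis of samples
#'
#' Column-centered SVD with samples as observations, optionally restricted
#' to a region subset (e.g. the top 500 most variable regions).
#'
#' @param mat Region-by-sample numeric matrix.
#' @param region_ids Optional subset of regions to use.
#' @param n_components Number of components to keep.
#' @return A `pca_result` list: `scores` (samples x components),
#'   `loadings`, `variance_explained`.
#' @export
pca_samples <- function(mat, region_ids = NULL, n_components = 10) {
  if (!is.null(region_ids)) mat <- mat[region_ids, , drop = FALSE]
  if (ncol(mat) < 2) abort_validation("PCA needs at least 2 samples")
  X <- scale(t(mat), center = TRUE, scale = FALSE)
  if (all(abs(X) < 1e-12)) abort_validation("matrix is constant; PCA undefined")
  k <- min(n_components, ncol(X), nrow(X) - 1)
  sv <- svd(X, nu = k, nv = k)
  scores <- sv$u %*% diag(sv$d[seq_len(k)], k, k)
  rownames(scores) <- colnames(mat)
  colnames(scores) <- paste0("PC", seq_len(k))
  ve <- sv$d^2 / sum(sv$d^2)
  structure(list(scores = scores, loadings = sv$v,
                 variance_explained = ve[seq_len(k)]),
            class = "pca_result")
}

#' Impute missing PBMC-type labels from a PCA embedding
#'
#' Samples are embedded in the top two principal components of the top-100
#' most variable regions; each unlabeled sample takes the majority label of
#' its `k` nearest labeled neighbors (Euclidean distance in PC space), with
#' ties resolved by the single nearest neighbor.
#'
#' @param mat Region-by-sample VST matrix.
#' @param metadata Sample table with a `pbmc_type` column (NA = missing).
#' @param k Number of neighbors.
#' @param n_top Number of variable regions for the embedding.
#' @return `metadata` with `pbmc_type` completed and a logical
#'   `pbmc_imputed` column.
#' @export
impute_pbmc_labels <- function(mat, metadata, k = 15, n_top = 100) {
  labels <- metadata$pbmc_type
  labeled <- which(!is.na(labels))
  if (length(labeled) < k) {
    abort_validation("need at least k = %d labeled samples", k)
  }
  missing_idx <- which(is.na(labels))
  metadata$pbmc_imputed <- FALSE
  if (!length(missing_idx)) return(metadata)
  ids <- top_variable_regions(mat, min(n_top, nrow(mat)))
  emb <- pca_samples(mat, ids, n_components = 2)$scores
  for (i in missing_idx) {
    d <- sqrt(rowSums((emb[labeled, , drop = FALSE] -
                         matrix(emb[i, ], length(labeled), 2, byrow = TRUE))^2))
    nn <- labeled[order(d)[seq_len(k)]]
    tab <- table(labels[nn])
    top <- names(tab)[tab == max(tab)]
    labels[i] <- if (length(top) == 1) top else labels[labeled[which.min(d)]]
  }
  metadata$pbmc_type <- labels
  metadata$pbmc_imputed[missing_idx] <- TRUE
  metadata
}

#' Chromosome-X reads-not-in-peaks statistic
#'
#' Per sample: `(chrx_reads - chrx_reads_in_peaks) / total_reads`, the
#' normalized background-read dosage on chrX. Group medians by sex and a
#' two-sided Mann-Whitney comparison are reported; in females the silenced
#' X contributes background (non-peak) reads, so their normalized RniP runs
#' higher than males'.
#'
#' @param metadata Sample table with `total_reads`, `chrx_reads`,
#'   `chrx_reads_in_peaks` and `sex`.
#' @return An `rnip_result` list: `per_sample` (data.frame), `medians`
#'   (named by sex), `mw_p_value`.
#' @export
chrx_rnip <- function(metadata) {
  with(metadata, {
    if (any(chrx_reads_in_peaks > chrx_reads)) {
      abort_validation("chrx_reads_in_peaks exceeds chrx_reads")
    }
    if (any(chrx_reads > total_reads)) {
      abort_validation("chrx_reads exceeds total_reads")
    }
  })
  val <- (metadata$chrx_reads - metadata$chrx_reads_in_peaks) / metadata$total_reads
  per_sample <- data.frame(sample_id = metadata$sample_id, sex = metadata$sex,
                           chrx_rnip_normalized = val, stringsAsFactors = FALSE)
  med <- tapply(val, metadata$sex, stats::median)
  p <- if (length(unique(metadata$sex)) == 2) {
    stats::wilcox.test(val ~ metadata$sex)$p.value
  } else NA_real_
  structure(list(per_sample = per_sample, medians = med, mw_p_value = p),
            class = "rnip_result")
}

# guarded two-cluster cut shared by the QC and progression modules:
# Pearson correlation matrix -> Euclidean distance between its columns ->
# complete-link tree -> cut in 2; the smaller cluster is flagged only when
# it holds < size_guard of samples AND its members correlate with the rest
# of the cohort at least cor_margin less than the larger cluster's members
# do (the margin keeps chance splits of a homogeneous cohort unflagged;
# genuinely decorrelated samples sit far below it)
correlation_cluster_cut <- function(mat, size_guard = 0.2, cor_margin = 0.1) {
  C <- stats::cor(mat)
  hc <- stats::hclust(stats::dist(t(C)), method = "complete")
  cl <- stats::cutree(hc, k = 2)
  sizes <- table(cl)
  small <- as.integer(names(sizes)[which.min(sizes)])
  flagged <- character(0)
  mean_offdiag <- function(members) {
    mean(vapply(members, function(i) mean(C[i, -i]), numeric(1)))
  }
  idx_small <- which(cl == small); idx_large <- which(cl != small)
  if (length(idx_small) < size_guard * ncol(mat) &&
      mean_offdiag(idx_small) < mean_offdiag(idx_large) - cor_margin) {
    flagged <- colnames(mat)[idx_small]
  }
  list(tree = hc, correlation = C, clusters = cl, flagged = flagged)
}

#' Inter-sample correlation clustering and outlier flagging
#'
#' @param mat Region-by-sample VST matrix (>= 3 samples).
#' @param size_guard Maximum flagged-cluster fraction.
#' @param cor_margin Minimum mean-correlation separation between the
#'   clusters before the smaller one is flagged.
#' @return List: `tree` (hclust), `correlation`, `clusters`, `flagged`
#'   (sample ids).
#' @export
inter_sample_correlation_cluster <- function(mat, size_guard = 0.2,
                                             cor_margin = 0.1) {
  if (ncol(mat) < 3) abort_validation("need at least 3 samples")
  correlation_cluster_cut(mat, size_guard, cor_margin)
}
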