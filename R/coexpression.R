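#' Candidate peak-gene pairs within a cis window
#'
#' All and only (gene, region) pairs on the same chromosome with
#' `|center - tss| <= window`.
#'
#' @param genes Gene table.
#' @param regions Region set.
#' @param window Window in bp (default 250000).
#' @return A `data.frame`: `gene_id`, `region_id`, `distance` (signed,
#'   strand-oriented center-to-TSS).
#' @export
pair_candidates <- function(genes, regions, window = 250000) {
  centers <- region_centers(regions)
  out <- vector("list", nrow(genes))
  for (g in seq_len(nrow(genes))) {
    idx <- which(regions$chrom == genes$chrom[g] &
                   abs(centers - genes$tss[g]) <= window)
    if (!length(idx)) next
    d <- centers[idx] - genes$tss[g]
    if (genes$strand[g] == "-") d <- -d
    out[[g]] <- data.frame(gene_id = genes$gene_id[g],
                           region_id = regions$region_id[idx],
                           distance = d, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(gene_id = character(0), region_id = character(0),
                      distance = numeric(0))
  }
  res
}

# orthonormal basis of the covariate space (with intercept), for
# residualization
covariate_projector <- function(metadata, covariates) {
  if (!length(covariates)) {
    n <- nrow(metadata)
    return(list(Q = matrix(1 / sqrt(n), n, 1), p_cov = 0L))
  }
  df <- metadata[, covariates, drop = FALSE]
  for (v in covariates) {
    if (is.character(df[[v]]) || is.logical(df[[v]])) df[[v]] <- factor(df[[v]])
  }
  X <- stats::model.matrix(~., data = df)
  qrX <- qr(X)
  list(Q = qr.Q(qrX)[, seq_len(qrX$rank), drop = FALSE],
       p_cov = qrX$rank - 1L)
}

#' Covariate-adjusted association of one peak with one gene
#'
#' Residualizes expression and accessibility on the covariate design (with
#' intercept) by least squares, regresses the expression residuals on the
#' accessibility residuals, and tests the slope with a two-sided Student's
#' t test on `n - p_cov - 2` degrees of freedom. By the
#' Frisch-Waugh-Lovell identity, the slope equals the accessibility
#' coefficient of the joint multiple regression.
#'
#' @param expression Numeric vector (one gene, matched samples).
#' @param accessibility Numeric vector (one region, matched samples).
#' @param metadata Sample table for the covariates.
#' @param covariates Covariate names (categoricals are treatment-coded).
#' @return List: `slope`, `t_stat`, `p_value`, `df`.
#' @export
association_test <- function(expression, accessibility, metadata,
                             covariates = c("frip", "sequencer", "case_status",
                                            "sex", "pbmc_type")) {
  proj <- covariate_projector(metadata, covariates)
  n <- length(expression)
  if (n <= proj$p_cov + 2) abort_validation("too few samples for the covariate design")
  re <- expression - proj$Q %*% crossprod(proj$Q, expression)
  ra <- accessibility - proj$Q %*% crossprod(proj$Q, accessibility)
  ss_a <- sum(ra^2)
  if (ss_a < 1e-16) abort_validation("accessibility has zero residual variance")
  slope <- sum(ra * re) / ss_a
  df <- n - proj$p_cov - 2
  sigma2 <- sum((re - slope * ra)^2) / df
  t_stat <- slope / sqrt(sigma2 / ss_a)
  list(slope = slope, t_stat = t_stat,
       p_value = 2 * stats::pt(-abs(t_stat), df), df = df)
}

#' Map all cis peak-gene associations
#'
#' Tests every candidate pair on the matched samples, Bonferroni-adjusts
#' over the number of pairs actually tested, flags significant pairs at
#' `adj_p < alpha`, classifies them by slope sign and promoter proximity
#' (`|distance| < proximal`), and extracts dual-sign peaks (regions
#' significantly associated with both an up- and a down-regulated gene).
#'
#' @param expr Gene-by-sample normalized expression matrix.
#' @param acc Region-by-sample VST accessibility matrix.
#' @param genes,regions Gene table and region set.
#' @param metadata Sample table.
#' @param covariates Adjustment covariates.
#' @param window Cis window in bp (default 250000).
#' @param alpha Significance level on adjusted p-values (default 0.01).
#' @param proximal Promoter-proximal threshold in bp (default 2500).
#' @param min_sd Variance filter: pairs where either variable has residual
#'   sd below this are not tested (numerical safety).
#' @return A `coexpression_result` list: `pairs` (all tested pairs with
#'   statistics and flags), `dual_sign_peaks`, `summary`.
#' @export
map_all_pairs <- function(expr, acc, genes, regions, metadata,
                          covariates = c("frip", "sequencer", "case_status",
                                         "sex", "pbmc_type"),
                          window = 250000, alpha = 0.01, proximal = 2500,
                          min_sd = 1e-8) {
  shared <- intersect(colnames(expr), colnames(acc))
  shared <- intersect(shared, metadata$sample_id)
  if (!length(shared)) abort_validation("no overlapping samples between matrices")
  proj_md <- metadata[match(shared, metadata$sample_id), , drop = FALSE]
  ok <- stats::complete.cases(proj_md[, covariates, drop = FALSE])
  shared <- shared[ok]
  proj_md <- proj_md[ok, , drop = FALSE]
  proj <- covariate_projector(proj_md, covariates)
  n <- length(shared)
  if (n <= proj$p_cov + 2) abort_validation("too few matched samples")
  cand <- pair_candidates(genes, regions, window)
  cand <- cand[cand$gene_id %in% rownames(expr) &
                 cand$region_id %in% rownames(acc), , drop = FALSE]
  E <- expr[, shared, drop = FALSE]
  A <- acc[, shared, drop = FALSE]
  # residualize both matrices on the covariate space once
  RE <- E - (E %*% proj$Q) %*% t(proj$Q)
  RA <- A - (A %*% proj$Q) %*% t(proj$Q)
  gi <- match(cand$gene_id, rownames(expr))
  ri <- match(cand$region_id, rownames(acc))
  ss_a <- rowSums(RA^2)[ri]
  ss_e <- rowSums(RE^2)[gi]
  testable <- ss_a > (min_sd^2 * n) & ss_e > (min_sd^2 * n)
  cand <- cand[testable, , drop = FALSE]
  gi <- gi[testable]; ri <- ri[testable]; ss_a <- ss_a[testable]
  cross <- rowSums(RE[gi, , drop = FALSE] * RA[ri, , drop = FALSE])
  slope <- cross / ss_a
  df <- n - proj$p_cov - 2
  resid_ss <- rowSums(RE[gi, , drop = FALSE]^2) - slope * cross
  sigma2 <- pmax(resid_ss, 0) / df
  t_stat <- slope / sqrt(sigma2 / ss_a)
  p <- 2 * stats::pt(-abs(t_stat), df)
  m <- nrow(cand)
  adj <- pmin(1, p * m)
  pairs <- data.frame(
    gene_id = cand$gene_id, region_id = cand$region_id,
    distance = cand$distance, slope = slope, t_stat = t_stat,
    p_value = p, adj_p_value = adj,
    significant = adj < alpha,
    sign = ifelse(slope >= 0, "positive", "negative"),
    promoter_proximal = abs(cand$distance) < proximal,
    stringsAsFactors = FALSE
  )
  sig <- pairs[pairs$significant, , drop = FALSE]
  dual <- do.call(rbind, lapply(split(sig, sig$region_id), function(s) {
    pos <- s$gene_id[s$sign == "positive"]
    neg <- s$gene_id[s$sign == "negative"]
    if (length(pos) && length(neg)) {
      data.frame(region_id = s$region_id[1],
                 positively_linked_genes = paste(pos, collapse = ","),
                 negatively_linked_genes = paste(neg, collapse = ","),
                 stringsAsFactors = FALSE)
    }
  }))
  per_gene <- table(sig$gene_id)
  structure(
    list(
      pairs = pairs,
      dual_sign_peaks = dual,
      summary = list(
        n_pairs_tested = m, n_samples = n,
        n_significant = nrow(sig),
        n_genes_significant = length(unique(sig$gene_id)),
        n_regions_significant = length(unique(sig$region_id)),
        negative_fraction = if (nrow(sig)) mean(sig$sign == "negative") else NA_real_,
        n_dual_sign_peaks = if (is.null(dual)) 0L else nrow(dual),
        peaks_per_gene = per_gene
      )
    ),
    class = "coexpression_result"
  )
}
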