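#' Fit a negative-binomial GLM to one region's counts
#'
#' Log-link NB regression with offset `log(s_j)` and known dispersion
#' `alpha`, fit by iteratively reweighted least squares with weights
#' `mu / (1 + alpha * mu)`. A small ridge penalty (`1e-6`) on the
#' non-intercept coefficients damps separation when a group is all-zero.
#' Convergence: `max |delta beta| < 1e-8` or 100 iterations.
#'
#' @param y Counts for one region (length n).
#' @param design Full-column-rank design matrix (n x p), first column the
#'   intercept.
#' @param size_factors Positive size factors (length n).
#' @param alpha Dispersion (`>= 0`; 0 gives Poisson regression).
#' @return List: `beta` (natural-log coefficients), `cov` (observed-
#'   information covariance), `converged`, `mu` (fitted means).
#' @export
fit_nb_glm <- function(y, design, size_factors, alpha,
                       max_iter = 100, tol = 1e-8, ridge = 1e-6) {
  n <- length(y); p <- ncol(design)
  stopifnot(nrow(design) == n, length(size_factors) == n, alpha >= 0)
  if (all(y == 0)) {
    return(list(beta = rep(NaN, p), cov = matrix(NaN, p, p),
                converged = FALSE, mu = rep(0, n)))
  }
  offset <- log(size_factors)
  pen <- diag(c(0, rep(ridge, p - 1)), p, p)
  beta <- c(log(mean(y / size_factors) + 0.1), rep(0, p - 1))
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(design %*% beta) + offset
    mu <- pmin(exp(eta), 1e12)
    w <- mu / (1 + alpha * mu)
    z <- eta - offset + (y - mu) / mu
    xw <- design * w
    info <- crossprod(design, xw) + pen
    beta_new <- tryCatch(solve(info, crossprod(xw, z)),
                         error = function(e) NULL)
    if (is.null(beta_new)) {
      return(list(beta = rep(NaN, p), cov = matrix(NaN, p, p),
                  converged = FALSE, mu = mu))
    }
    beta_new <- drop(beta_new)
    delta <- max(abs(beta_new - beta))
    beta <- beta_new
    if (is.finite(delta) && delta < tol) { converged <- TRUE; break }
  }
  eta <- drop(design %*% beta) + offset
  mu <- pmin(exp(eta), 1e12)
  w <- mu / (1 + alpha * mu)
  info <- crossprod(design, design * w) + pen
  cov <- tryCatch(solve(info), error = function(e) matrix(NaN, p, p))
  if (!converged) beta <- rep(NaN, p)
  list(beta = beta, cov = cov, converged = converged, mu = mu)
}

#' Two-sided Wald test against a standard normal reference
#'
#' @param beta Coefficient estimate(s).
#' @param se Standard error(s), all `> 0`.
#' @return List: `z`, `p`.
#' @export
wald_test <- function(beta, se) {
  if (any(!is.na(se) & se <= 0)) abort_validation("standard errors must be > 0")
  z <- beta / se
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p P-values in `[0, 1]` (NAs allowed and preserved).
#' @return Adjusted p-values.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    abort_validation("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Build a treatment-coded design matrix from sample covariates
#'
#' Categorical covariates are treatment-coded with the alphabetically first
#' level as reference; continuous covariates enter as-is. The contrast
#' variable's coefficient is the last listed level versus the reference.
#'
#' @param metadata Sample table.
#' @param contrast Name of the contrast covariate (factor with >= 2
#'   observed levels).
#' @param covariates Character vector of adjustment covariate names.
#' @return List: `design` (matrix), `contrast_col` (index of the tested
#'   coefficient), `rows` (sample rows used, i.e. complete cases).
#' @export
build_design <- function(metadata, contrast, covariates = character(0)) {
  vars <- c(contrast, covariates)
  missing_vars <- setdiff(vars, names(metadata))
  if (length(missing_vars)) {
    abort_validation("covariates not in sample table: %s",
                     paste(missing_vars, collapse = ", "))
  }
  df <- metadata[, vars, drop = FALSE]
  rows <- which(stats::complete.cases(df))
  df <- df[rows, , drop = FALSE]
  for (v in vars) {
    if (is.character(df[[v]]) || is.factor(df[[v]]) || is.logical(df[[v]])) {
      df[[v]] <- factor(df[[v]])
    }
  }
  if (is.factor(df[[contrast]]) && nlevels(droplevels(df[[contrast]])) < 2) {
    abort_validation("contrast variable '%s' has fewer than 2 observed levels",
                     contrast)
  }
  df <- droplevels(df)
  fml <- stats::as.formula(paste("~", paste(c(covariates, contrast), collapse = " + ")))
  X <- stats::model.matrix(fml, data = df)
  if (qr(X)$rank < ncol(X)) abort_validation("design matrix is rank deficient")
  # tested coefficient: last column belonging to the contrast variable
  ass <- attr(X, "assign")
  term_labels <- attr(stats::terms(fml), "term.labels")
  contrast_col <- max(which(ass == match(contrast, term_labels)))
  list(design = X, contrast_col = contrast_col, rows = rows)
}

#' Differential accessibility with covariates
#'
#' Per-region NB GLM fits (Wald test on the contrast coefficient,
#' Benjamini-Hochberg adjustment across all tested regions), reporting
#' log2 fold changes (natural-log coefficients divided by `ln 2`). Regions
#' passing both `adj_p` and `min_abs_lfc` thresholds are flagged as
#' differentially accessible (DARs).
#'
#' @param counts Region-by-sample integer matrix.
#' @param metadata Sample table aligned to `colnames(counts)`.
#' @param contrast Contrast covariate name; for factors with more than two
#'   levels supply `contrast_levels = c(reference, tested)` to subset.
#' @param covariates Adjustment covariate names (default: the technical and
#'   biological covariates used throughout: FRiP, sequencer, sex,
#'   PBMC type).
#' @param contrast_levels Optional two levels of `contrast` to compare
#'   (samples at other levels are dropped).
#' @param size_factors,dispersions Optional precomputed normalization; when
#'   `NULL` they are estimated from the tested samples.
#' @param adj_p,min_abs_lfc DAR thresholds.
#' @return A `data.frame`: `region_id`, `base_mean`, `log2fc`, `se`,
#'   `wald_z`, `p_value`, `adj_p_value`, `is_dar`, plus attributes
#'   `contrast_label`.
#' @export
run_differential <- function(counts, metadata, contrast,
                             covariates = c("frip", "sequencer", "sex", "pbmc_type"),
                             contrast_levels = NULL,
                             size_factors = NULL, dispersions = NULL,
                             adj_p = 0.01, min_abs_lfc = 0.5) {
  validate_counts(counts)
  stopifnot(identical(colnames(counts), metadata$sample_id))
  if (!is.null(contrast_levels)) {
    keep <- metadata[[contrast]] %in% contrast_levels
    metadata <- metadata[keep, , drop = FALSE]
    metadata[[contrast]] <- factor(metadata[[contrast]], levels = contrast_levels)
    counts <- counts[, keep, drop = FALSE]
  }
  d <- build_design(metadata, contrast, covariates)
  X <- d$design
  counts <- counts[, d$rows, drop = FALSE]
  if (is.null(size_factors)) {
    size_factors <- size_factors_median_of_ratios(counts)
  } else {
    stopifnot(!is.null(names(size_factors)))
    size_factors <- size_factors[colnames(counts)]
  }
  if (is.null(dispersions)) {
    dm <- estimate_dispersions(counts, size_factors)
    dispersions <- ifelse(is.na(dm$alpha_hat),
                          dispersion_trend(dm, dm$mu_hat), dm$alpha_hat)
  } else if (!is.null(names(dispersions))) {
    dispersions <- dispersions[rownames(counts)]
  }
  m <- nrow(counts)
  log2fc <- se <- rep(NA_real_, m)
  norm <- sweep(counts, 2, size_factors, "/")
  base_mean <- rowMeans(norm)
  for (i in seq_len(m)) {
    fit <- fit_nb_glm(counts[i, ], X, size_factors, dispersions[i])
    if (!fit$converged) next
    k <- d$contrast_col
    log2fc[i] <- fit$beta[k] / log(2)
    se[i] <- sqrt(fit$cov[k, k]) / log(2)
  }
  wt <- wald_test(log2fc, se)
  adj <- bh_adjust(wt$p)
  res <- data.frame(
    region_id = rownames(counts),
    base_mean = base_mean,
    log2fc = log2fc, se = se, wald_z = wt$z,
    p_value = wt$p, adj_p_value = adj,
    is_dar = !is.na(adj) & adj < adj_p & abs(log2fc) > min_abs_lfc,
    stringsAsFactors = FALSE
  )
  lev <- colnames(X)[d$contrast_col]
  attr(res, "contrast_label") <- sprintf("log2FC: %s vs reference", lev)
  res
}
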