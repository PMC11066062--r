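#' Partition one region's accessibility variance across covariates
#'
#' Fits `y = X beta + sum_k Z_k u_k + e` by REML, with every categorical
#' covariate as a random intercept (`u_k ~ N(0, sigma2_k I)`) and every
#' continuous covariate as a fixed effect. The variance fraction of a
#' random covariate is `sigma2_k / T`; of a fixed covariate, the sample
#' variance of its fitted term `Var(x_j beta_j) / T`; of the residual,
#' `sigma2_e / T`, with `T` the sum of all numerators, so fractions sum to
#' one exactly.
#'
#' @param y Numeric response (one region's transformed accessibility).
#' @param metadata Sample table.
#' @param random_covariates Names of categorical covariates (random
#'   intercepts; each needs >= 2 observed levels).
#' @param fixed_covariates Names of continuous covariates (fixed effects).
#' @return Named numeric vector of fractions (covariates then `residual`),
#'   summing to 1; all-`NaN` with attribute `converged = FALSE` when the
#'   fit fails.
#' @export
partition_variance <- function(y, metadata, random_covariates,
                               fixed_covariates = character(0)) {
  if (length(intersect(random_covariates, fixed_covariates))) {
    abort_validation("random and fixed covariate sets must be disjoint")
  }
  vars <- c(random_covariates, fixed_covariates)
  missing_vars <- setdiff(vars, names(metadata))
  if (length(missing_vars)) {
    abort_validation("covariates not in sample table: %s",
                     paste(missing_vars, collapse = ", "))
  }
  df <- metadata[, vars, drop = FALSE]
  df$.y <- y
  df <- df[stats::complete.cases(df), , drop = FALSE]
  for (v in random_covariates) {
    df[[v]] <- factor(df[[v]])
    if (nlevels(df[[v]]) < 2) {
      abort_validation("random covariate '%s' has fewer than 2 levels", v)
    }
  }
  n_par <- 1 + length(fixed_covariates) +
    sum(vapply(random_covariates, function(v) nlevels(df[[v]]), 1L))
  if (nrow(df) <= n_par) {
    abort_validation("fewer samples than model parameters")
  }
  out_names <- c(vars, "residual")
  fail <- structure(stats::setNames(rep(NaN, length(out_names)), out_names),
                    converged = FALSE)
  fml <- stats::as.formula(paste(
    ".y ~", paste(c(fixed_covariates, "1",
                    sprintf("(1 | %s)", random_covariates)), collapse = " + ")))
  fit <- tryCatch(
    suppressMessages(suppressWarnings(
      lme4::lmer(fml, data = df, REML = TRUE,
                 control = lme4::lmerControl(calc.derivs = FALSE,
                                             check.conv.singular = "ignore"))
    )),
    error = function(e) NULL
  )
  if (is.null(fit)) return(fail)
  vc <- as.data.frame(lme4::VarCorr(fit))
  sig2 <- stats::setNames(vc$vcov, vc$grp)
  num <- numeric(0)
  for (v in random_covariates) num[v] <- sig2[[v]]
  fe <- lme4::fixef(fit)
  for (v in fixed_covariates) {
    num[v] <- if (v %in% names(fe)) stats::var(df[[v]] * fe[[v]]) else 0
  }
  num["residual"] <- sig2[["Residual"]]
  fr <- num / sum(num)
  structure(fr[out_names], converged = TRUE)
}

#' Variance partitioning across all regions of a matrix
#'
#' @param mat Region-by-sample numeric matrix (e.g. VST values).
#' @param metadata Sample table aligned to `colnames(mat)`.
#' @inheritParams partition_variance
#' @return A `data.frame` with `region_id` and one fraction column per
#'   covariate plus `residual`.
#' @export
partition_variance_matrix <- function(mat, metadata, random_covariates,
                                      fixed_covariates = character(0)) {
  res <- t(apply(mat, 1, function(y) {
    as.numeric(partition_variance(y, metadata, random_covariates,
                                  fixed_covariates))
  }))
  colnames(res) <- c(random_covariates, fixed_covariates, "residual")
  data.frame(region_id = rownames(mat), res,
             check.names = FALSE, stringsAsFactors = FALSE)
}

#' Summarize variance fractions across regions
#'
#' Reports the median fraction per covariate and the number of regions in
#' which a covariate explains more than `threshold` of the variance.
#'
#' @param fractions Output of [partition_variance_matrix()].
#' @param threshold Fraction threshold (default 0.25).
#' @return A `data.frame`: `covariate`, `median_fraction`,
#'   `n_regions_above`.
#' @export
summarize_variance_fractions <- function(fractions, threshold = 0.25) {
  cols <- setdiff(names(fractions), "region_id")
  data.frame(
    covariate = cols,
    median_fraction = vapply(cols, function(cc)
      stats::median(fractions[[cc]], na.rm = TRUE), numeric(1)),
    n_regions_above = vapply(cols, function(cc)
      sum(fractions[[cc]] > threshold, na.rm = TRUE), numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
}
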