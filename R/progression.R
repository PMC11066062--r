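#' ALSFRS-R slope prediction from TSS-proximal chromatin accessibility
#'
#' The predictor pipeline: subset to regions within 2 kb of a TSS, drop
#' poorly correlated samples (guarded complete-link cut of the inter-sample
#' correlation matrix), drop ALSFRS-R-slope outliers (1.5-IQR rule), drop
#' samples from under-represented differentiation batches, split 90/10,
#' then run LASSO feature selection with ten-fold cross-validated
#' regularization, re-drawing the fold assignment across many runs;
#' regions selected in over half of the runs form the majority-vote set,
#' and per-run predictors are ordinary least-squares refits evaluated on
#' the fixed held-out test set with the total variation anchored at the
#' training mean.
#'
#' @name progression
NULL

#' Subset a matrix to TSS-proximal regions
#'
#' @param mat Region-by-sample matrix (rownames are region ids).
#' @param regions Region set matching the rownames.
#' @param genes Gene table.
#' @param halfwidth Maximum center-to-TSS distance in bp (default 2000).
#' @return The row-subset matrix.
#' @export
subset_tss_regions <- function(mat, regions, genes, halfwidth = 2000) {
  regions <- regions[match(rownames(mat), regions$region_id), , drop = FALSE]
  d <- nearest_tss_distance(regions, genes)
  keep <- which(d <= halfwidth)
  if (!length(keep)) abort_validation("no region lies within %d bp of a TSS", halfwidth)
  mat[keep, , drop = FALSE]
}

#' Exclude poorly correlated samples
#'
#' Guarded two-cluster complete-link cut of the inter-sample correlation
#' matrix (see [inter_sample_correlation_cluster()]): the smaller cluster
#' is excluded only if it holds under `size_guard` of the samples and its
#' members correlate less with the cohort than the rest.
#'
#' @param mat Region-by-sample matrix (>= 10 samples).
#' @param size_guard Maximum excluded fraction (default 0.2).
#' @param cor_margin Minimum mean-correlation separation between the two
#'   clusters before exclusion (default 0.1).
#' @return Character vector of excluded sample ids (possibly empty).
#' @export
correlation_outlier_filter <- function(mat, size_guard = 0.2,
                                       cor_margin = 0.1) {
  if (ncol(mat) < 10) abort_validation("need at least 10 samples")
  correlation_cluster_cut(mat, size_guard, cor_margin)$flagged
}

#' Exclude slope outliers by the 1.5-IQR rule
#'
#' Quartiles use linear interpolation (the type-7 convention); values
#' below `Q1 - multiplier * IQR` or above `Q3 + multiplier * IQR` are
#' excluded. Single-pass by contract.
#'
#' @param slopes Named numeric vector (names = sample ids).
#' @param multiplier IQR multiplier (default 1.5).
#' @return Names of excluded samples.
#' @export
iqr_outlier_filter <- function(slopes, multiplier = 1.5) {
  ok <- !is.na(slopes)
  if (sum(ok) < 4) abort_validation("need at least 4 non-missing slopes")
  qs <- stats::quantile(slopes[ok], c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- qs[2] - qs[1]
  out <- ok & (slopes < qs[1] - multiplier * iqr | slopes > qs[2] + multiplier * iqr)
  names(slopes)[out]
}

#' Exclude samples from under-represented batches
#'
#' Batch counts are computed on the sample set as passed in (i.e. after any
#' previous filters).
#'
#' @param metadata Sample table (the current sample set).
#' @param min_per_batch Minimum representatives per batch (default 4).
#' @return Excluded sample ids.
#' @export
batch_filter <- function(metadata, min_per_batch = 4) {
  tab <- table(metadata$diff_batch)
  bad <- names(tab)[tab < min_per_batch]
  metadata$sample_id[metadata$diff_batch %in% bad]
}

# population-sd column standardization (so t(x) x / n = 1), zero-variance
# columns get sd 1 and stay at coefficient zero
standardize_columns <- function(X, center = NULL, sd_n = NULL) {
  if (is.null(center)) center <- colMeans(X)
  Xc <- sweep(X, 2, center)
  if (is.null(sd_n)) sd_n <- sqrt(colMeans(Xc^2))
  sd_use <- ifelse(sd_n < 1e-12, 1, sd_n)
  list(X = sweep(Xc, 2, sd_use, "/"), center = center, sd = sd_n,
       zero_var = sd_n < 1e-12)
}

#' The largest penalty with a non-null solution
#'
#' `lambda_max = max_j |x_j' y| / n` on the standardized design and
#' centered response; at or above it all lasso slopes are zero.
#'
#' @param X Predictor matrix (n x p, original scale).
#' @param y Response.
#' @return `lambda_max`.
#' @export
lasso_lambda_max <- function(X, y) {
  st <- standardize_columns(X)
  yc <- y - mean(y)
  max(abs(crossprod(st$X, yc))) / nrow(X)
}

#' Fit the lasso at fixed penalty
#'
#' Minimizes `(1/2n) ||y - b0 - X b||^2 + lambda ||b||_1` by cyclic
#' coordinate descent with soft-thresholding, on the internally
#' standardized design (mean 0, population sd 1) with the intercept
#' unpenalized; coefficients are returned on the original predictor scale.
#'
#' @param X Predictor matrix (n x p).
#' @param y Response (length n).
#' @param lambda Penalty (`>= 0`).
#' @param tol Convergence tolerance on the maximum coefficient change.
#' @param max_iter Maximum outer iterations.
#' @return List: `intercept`, `coefficients` (length p, named by columns),
#'   `lambda`.
#' @export
lasso_fit <- function(X, y, lambda, tol = 1e-7, max_iter = 100000) {
  if (lambda < 0) abort_validation("lambda must be >= 0")
  X <- as.matrix(X)
  st <- standardize_columns(X)
  if (any(st$zero_var)) {
    warning(sum(st$zero_var), " zero-variance column(s) dropped from the lasso")
  }
  yc <- y - mean(y)
  b_std <- lasso_path_cpp(st$X, yc, as.numeric(lambda), tol, as.integer(max_iter))[, 1]
  b <- ifelse(st$zero_var, 0, b_std / ifelse(st$sd < 1e-12, 1, st$sd))
  names(b) <- colnames(X)
  list(intercept = mean(y) - sum(b * st$center), coefficients = b,
       lambda = lambda)
}

# decreasing 100-point log-spaced path from lambda_max down 3 decades
default_lambda_path <- function(lambda_max, n_lambda = 100, ratio = 1e-3) {
  10^seq(log10(lambda_max), log10(lambda_max * ratio), length.out = n_lambda)
}

#' Select the lasso penalty by k-fold cross-validation
#'
#' The path is 100 log-spaced penalties from `lambda_max` down to
#' `lambda_max / 1000`; folds are assigned by a seeded random permutation
#' with sizes differing by at most one; the chosen penalty minimizes the
#' mean cross-validated MSE.
#'
#' @param X Predictor matrix.
#' @param y Response.
#' @param n_folds Number of folds (default 10).
#' @param fold_seed Seed for the fold assignment.
#' @param lambda_path Optional penalty sequence (decreasing).
#' @param tol Coordinate-descent tolerance.
#' @param lambda_rule `"min"` (minimum mean CV MSE) or `"1se"` (largest
#'   penalty within one standard error of the minimum).
#' @return List: `lambda` (chosen), `lambda_index`, `lambda_path`,
#'   `cv_mse`, `cv_se`.
#' @export
cv_select_lambda <- function(X, y, n_folds = 10, fold_seed = 1,
                             lambda_path = NULL, tol = 1e-7,
                             lambda_rule = c("min", "1se")) {
  lambda_rule <- match.arg(lambda_rule)
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < n_folds) abort_validation("need at least n_folds samples")
  if (is.null(lambda_path)) {
    lambda_path <- default_lambda_path(lasso_lambda_max(X, y))
  }
  folds <- with_seed(fold_seed, sample(rep(seq_len(n_folds), length.out = n)))
  mse <- matrix(NA_real_, n_folds, length(lambda_path))
  for (f in seq_len(n_folds)) {
    tr <- folds != f
    st <- standardize_columns(X[tr, , drop = FALSE])
    ytr <- y[tr]
    b_std <- lasso_path_cpp(st$X, ytr - mean(ytr), lambda_path, tol, 100000L)
    sd_use <- ifelse(st$sd < 1e-12, 1, st$sd)
    Xv <- standardize_columns(X[!tr, , drop = FALSE], st$center, st$sd)$X
    pred <- mean(ytr) + Xv %*% b_std
    mse[f, ] <- colMeans((y[!tr] - pred)^2)
  }
  cvm <- colMeans(mse)
  cvse <- apply(mse, 2, stats::sd) / sqrt(n_folds)
  i_min <- which.min(cvm)
  i_sel <- if (lambda_rule == "min") i_min else {
    min(which(cvm <= cvm[i_min] + cvse[i_min]))
  }
  list(lambda = lambda_path[i_sel], lambda_index = i_sel,
       lambda_path = lambda_path, cv_mse = cvm, cv_se = cvse)
}

#' Ordinary least-squares refit and train-mean-anchored evaluation
#'
#' Fits OLS of the response on the selected regions (least-norm solution
#' with a warning when rank deficient) and reports training and test RMSE
#' and R-squared, with the test total variation computed relative to the
#' *training* mean; the squared correlation between predictions and truth
#' is reported as a secondary test metric.
#'
#' @param X_train,X_test Matrices restricted to the selected regions.
#' @param y_train,y_test Responses.
#' @return List: `intercept`, `coefficients`, `train_rmse`, `train_r2`,
#'   `test_rmse`, `test_r2`, `test_cor2`.
#' @export
refit_ols_and_evaluate <- function(X_train, y_train, X_test, y_test) {
  X_train <- as.matrix(X_train); X_test <- as.matrix(X_test)
  if (ncol(X_train) == 0) abort_validation("empty region selection")
  if (ncol(X_train) >= nrow(X_train)) {
    abort_validation("more selected regions than training samples")
  }
  A <- cbind(1, X_train)
  qrA <- qr(A)
  if (qrA$rank < ncol(A)) {
    warning("rank-deficient OLS refit; using the least-norm solution")
    sv <- svd(A)
    pos <- sv$d > max(sv$d) * 1e-10
    cf <- sv$v[, pos, drop = FALSE] %*%
      ((crossprod(sv$u[, pos, drop = FALSE], y_train)) / sv$d[pos])
    cf <- drop(cf)
  } else {
    cf <- qr.coef(qrA, y_train)
  }
  pred_tr <- drop(A %*% cf)
  pred_te <- drop(cbind(1, X_test) %*% cf)
  ybar_tr <- mean(y_train)
  r2 <- function(obs, pred) 1 - sum((obs - pred)^2) / sum((obs - ybar_tr)^2)
  list(
    intercept = cf[1], coefficients = stats::setNames(cf[-1], colnames(X_train)),
    train_rmse = sqrt(mean((y_train - pred_tr)^2)),
    train_r2 = r2(y_train, pred_tr),
    test_rmse = sqrt(mean((y_test - pred_te)^2)),
    test_r2 = r2(y_test, pred_te),
    test_cor2 = if (stats::sd(pred_te) > 0) stats::cor(pred_te, y_test)^2 else NA_real_
  )
}

#' Stability selection over cross-validation fold reassignments
#'
#' Repeats the feature-selection step `n_runs` times, each run re-drawing
#' the fold assignment (seed derived from `master_seed` and the run index),
#' choosing the penalty by CV, taking the lasso support on the full
#' training set at that penalty, refitting by OLS and evaluating on the
#' fixed test set. Regions selected in more than `majority_threshold` of
#' runs (denominator: all runs, including those with empty support) form
#' the majority set; aggregate metrics average over runs with non-empty
#' support.
#'
#' @param X_train,y_train Filtered training data.
#' @param X_test,y_test Fixed held-out test data.
#' @param n_runs Number of fold-reassignment runs (default 1000).
#' @param master_seed Master seed; run `r` uses a derived fold seed.
#' @param n_folds CV folds (default 10).
#' @param majority_threshold Selection-frequency cutoff (default 0.5).
#' @param majority_denominator `"all"` (default) or `"nonempty"`.
#' @param lambda_rule Penalty rule passed to [cv_select_lambda()]:
#'   `"1se"` (default; parsimonious, stable supports at this n/p) or
#'   `"min"`.
#' @param tol Coordinate-descent tolerance for the support-defining fit.
#' @param cv_tol Looser tolerance used only to evaluate the CV error
#'   curve (the curve is insensitive at this scale and fold fits dominate
#'   the run time).
#' @return A `stability_result` list: `runs` (per-run data.frame),
#'   `selection_frequency`, `majority_set`, `aggregate` (means and
#'   standard errors), `n_nonempty`.
#' @export
stability_selection <- function(X_train, y_train, X_test, y_test,
                                n_runs = 1000, master_seed = 1, n_folds = 10,
                                majority_threshold = 0.5,
                                majority_denominator = c("all", "nonempty"),
                                lambda_rule = c("1se", "min"),
                                tol = 1e-7, cv_tol = 1e-5) {
  majority_denominator <- match.arg(majority_denominator)
  lambda_rule <- match.arg(lambda_rule)
  X_train <- as.matrix(X_train); X_test <- as.matrix(X_test)
  p <- ncol(X_train)
  lam_max <- lasso_lambda_max(X_train, y_train)
  path <- default_lambda_path(lam_max)
  # the full-training-set path does not depend on the fold assignment, so
  # the per-penalty supports are computed once and shared across runs
  st <- standardize_columns(X_train)
  b_path <- lasso_path_cpp(st$X, y_train - mean(y_train), path, tol, 100000L)
  support_at <- function(l) which(b_path[, l] != 0)

  sel_count <- numeric(p)
  runs <- vector("list", n_runs)
  for (r in seq_len(n_runs)) {
    fs <- derive_seed(master_seed, paste0("run", r))
    cv <- cv_select_lambda(X_train, y_train, n_folds = n_folds,
                           fold_seed = fs, lambda_path = path, tol = cv_tol,
                           lambda_rule = lambda_rule)
    l_idx <- cv$lambda_index
    sel <- support_at(l_idx)
    sel_count[sel] <- sel_count[sel] + 1
    met <- if (length(sel) && length(sel) < nrow(X_train)) {
      refit_ols_and_evaluate(X_train[, sel, drop = FALSE], y_train,
                             X_test[, sel, drop = FALSE], y_test)
    } else NULL
    runs[[r]] <- data.frame(
      run = r, fold_seed = fs, lambda = path[l_idx], n_selected = length(sel),
      train_rmse = met$train_rmse %||% NA_real_,
      train_r2 = met$train_r2 %||% NA_real_,
      test_rmse = met$test_rmse %||% NA_real_,
      test_r2 = met$test_r2 %||% NA_real_,
      test_cor2 = met$test_cor2 %||% NA_real_,
      selected = I(list(colnames(X_train)[sel]))
    )
  }
  runs <- do.call(rbind, runs)
  nonempty <- runs$n_selected > 0
  denom <- if (majority_denominator == "all") n_runs else max(1L, sum(nonempty))
  freq <- stats::setNames(sel_count / denom, colnames(X_train))
  agg <- function(x) {
    x <- x[nonempty]
    c(mean = mean(x), se = stats::sd(x) / sqrt(length(x)))
  }
  structure(
    list(
      runs = runs,
      selection_frequency = freq,
      majority_set = names(freq)[freq > majority_threshold],
      n_nonempty = sum(nonempty),
      aggregate = list(
        n_selected = agg(runs$n_selected),
        train_rmse = agg(runs$train_rmse), train_r2 = agg(runs$train_r2),
        test_rmse = agg(runs$test_rmse), test_r2 = agg(runs$test_r2),
        test_cor2 = agg(runs$test_cor2)
      )
    ),
    class = "stability_result"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# largest-remainder allocation of n_test across batch strata
stratified_split <- function(sample_ids, batches, test_fraction, seed) {
  n_test <- round(test_fraction * length(sample_ids))
  tab <- table(batches)
  quota <- as.numeric(tab) * test_fraction
  base <- floor(quota)
  rem <- n_test - sum(base)
  if (rem > 0) {
    ord <- order(quota - base, decreasing = TRUE)
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  test <- character(0)
  for (b in seq_along(tab)) {
    ids <- sample_ids[batches == names(tab)[b]]
    k <- min(base[b], length(ids))
    if (k > 0) {
      test <- c(test, with_seed(derive_seed(seed, paste0("split", b)),
                                sample(ids, k)))
    }
  }
  list(train = setdiff(sample_ids, test), test = test)
}

#' Run the full ALSFRS-R slope prediction procedure
#'
#' Applies, in order: TSS subsetting, the correlation-outlier filter, the
#' slope IQR filter, the batch filter, a batch-stratified 90/10 split, and
#' [stability_selection()]; finally refits the majority-vote region set by
#' OLS.
#'
#' @param vst_mat Region-by-sample VST matrix.
#' @param regions,genes Region set and gene table for TSS subsetting.
#' @param metadata Sample table (`alsfrs_r_slope`, `diff_batch`,
#'   `case_status`).
#' @param n_runs Stability runs (default 1000).
#' @param master_seed Master seed.
#' @param test_fraction Held-out fraction (default 0.1).
#' @param n_folds,min_per_batch,iqr_multiplier,majority_threshold,majority_denominator
#'   Procedure parameters (defaults 10, 4, 1.5, 0.5, "all").
#' @param lambda_rule Penalty rule, `"min"` or `"1se"`.
#' @param tss_halfwidth TSS window in bp (default 2000).
#' @return List: `filter_report`, `split`, `stability`, `majority_model`
#'   (OLS refit of the majority set, or `NULL` when empty).
#' @export
run_progression <- function(vst_mat, regions, genes, metadata,
                            n_runs = 1000, master_seed = 1,
                            test_fraction = 0.1, n_folds = 10,
                            min_per_batch = 4, iqr_multiplier = 1.5,
                            majority_threshold = 0.5,
                            majority_denominator = "all",
                            lambda_rule = "1se",
                            tss_halfwidth = 2000) {
  tss_mat <- subset_tss_regions(vst_mat, regions, genes, tss_halfwidth)
  eligible <- metadata$sample_id[metadata$case_status == "ALS" &
                                   !is.na(metadata$alsfrs_r_slope)]
  mat <- tss_mat[, eligible, drop = FALSE]
  excl_corr <- correlation_outlier_filter(mat)
  keep1 <- setdiff(eligible, excl_corr)
  slopes <- stats::setNames(
    metadata$alsfrs_r_slope[match(keep1, metadata$sample_id)], keep1)
  excl_iqr <- iqr_outlier_filter(slopes, iqr_multiplier)
  keep2 <- setdiff(keep1, excl_iqr)
  md2 <- metadata[match(keep2, metadata$sample_id), , drop = FALSE]
  excl_batch <- batch_filter(md2, min_per_batch)
  retained <- setdiff(keep2, excl_batch)
  report <- list(excluded_by_correlation = excl_corr,
                 excluded_by_slope_iqr = excl_iqr,
                 excluded_by_batch = excl_batch,
                 retained = retained)
  md3 <- metadata[match(retained, metadata$sample_id), , drop = FALSE]
  split <- stratified_split(retained, md3$diff_batch, test_fraction,
                            derive_seed(master_seed, "traintest"))
  X <- t(tss_mat[, retained, drop = FALSE])
  y <- stats::setNames(
    metadata$alsfrs_r_slope[match(retained, metadata$sample_id)], retained)
  stab <- stability_selection(
    X[split$train, , drop = FALSE], y[split$train],
    X[split$test, , drop = FALSE], y[split$test],
    n_runs = n_runs, master_seed = master_seed, n_folds = n_folds,
    majority_threshold = majority_threshold,
    majority_denominator = majority_denominator,
    lambda_rule = lambda_rule
  )
  maj <- stab$majority_set
  majority_model <- if (length(maj)) {
    refit_ols_and_evaluate(X[split$train, maj, drop = FALSE], y[split$train],
                           X[split$test, maj, drop = FALSE], y[split$test])
  } else NULL
  list(filter_report = report, split = split, stability = stab,
       majority_model = majority_model)
}
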