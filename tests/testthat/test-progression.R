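test_that("TSS subsetting keeps exactly the regions within the halfwidth", {
  genes <- data.frame(gene_id = "g", chrom = "chr1", tss = 100000L,
                      strand = "+", stringsAsFactors = FALSE)
  rs <- region_set("chr1", c(101749, 102251, 97750), c(102249, 102751, 98250),
                   c("at1999", "at2501", "at2000"))
  mat <- matrix(0, 3, 4, dimnames = list(c("at1999", "at2501", "at2000"),
                                         paste0("s", 1:4)))
  kept <- rownames(subset_tss_regions(mat, rs, genes, halfwidth = 2000))
  expect_true("at1999" %in% kept)   # 1,999 bp away
  expect_true("at2000" %in% kept)   # boundary included
  expect_false("at2501" %in% kept)  # 2,501 bp away
  genes2 <- data.frame(gene_id = "g", chrom = "chr9", tss = 1L, strand = "+")
  expect_error(subset_tss_regions(mat, rs, genes2), "no region")
})

test_that("the IQR filter reproduces the worked five-value example", {
  slopes <- setNames(c(-5.0, -0.4, -0.3, -0.2, -0.1), paste0("s", 1:5))
  expect_equal(iqr_outlier_filter(slopes), "s1")
  tight <- setNames(seq(-0.5, -0.1, by = 0.1), paste0("t", 1:5))
  expect_equal(iqr_outlier_filter(tight), character(0))
  expect_error(iqr_outlier_filter(c(a = 1, b = 2, c = 3)), "at least 4")
})

test_that("the batch filter removes under-represented batches only", {
  md <- data.frame(sample_id = sprintf("s%02d", 1:17),
                   diff_batch = rep(c("A", "B", "C"), times = c(10, 4, 3)))
  expect_setequal(batch_filter(md), md$sample_id[md$diff_batch == "C"])
  expect_equal(batch_filter(md[md$diff_batch != "C", ]), character(0))
  expect_equal(batch_filter(md, min_per_batch = 1), character(0))
})

test_that("the correlation filter excludes planted decorrelated samples only", {
  set.seed(61)
  m <- 400
  base <- rnorm(m, 8, 2)
  good <- sapply(1:50, function(i) base + rnorm(m, 0, 0.7))
  bad <- sapply(1:5, function(i) rnorm(m, 8, 2))
  mat <- cbind(good, bad)
  colnames(mat) <- c(sprintf("good%02d", 1:50), sprintf("bad%02d", 1:5))
  rownames(mat) <- sprintf("r%03d", 1:m)
  expect_setequal(correlation_outlier_filter(mat), sprintf("bad%02d", 1:5))
  # homogeneous cohort: nothing excluded
  expect_equal(correlation_outlier_filter(mat[, 1:50]), character(0))
  # two equal halves with distinct profiles: size guard blocks exclusion
  base2 <- rnorm(m, 8, 2)
  half2 <- sapply(1:50, function(i) base2 + rnorm(m, 0, 0.7))
  colnames(half2) <- sprintf("h2_%02d", 1:50)
  expect_equal(correlation_outlier_filter(cbind(good, half2)), character(0))
  expect_error(correlation_outlier_filter(mat[, 1:5]), "at least 10")
})

test_that("the lasso satisfies its KKT, OLS and orthonormal oracles", {
  set.seed(62)
  n <- 90; p <- 25
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("x", 1:p)))
  y <- drop(X[, 1:3] %*% c(2, -1.5, 1) + rnorm(n))
  lmax <- lasso_lambda_max(X, y)
  expect_equal(unname(lasso_fit(X, y, lmax * (1 + 1e-9))$coefficients),
               rep(0, p))
  f0 <- lasso_fit(X, y, 0)
  ols <- unname(coef(lm(y ~ X)))
  expect_lt(max(abs(c(f0$intercept, f0$coefficients) - ols)), 1e-6)
  # exactly orthonormal design (Helmert contrasts are mean-zero and
  # mutually orthogonal; rescale to population sd 1): closed-form solution
  H <- stats::contr.helmert(n)[, 1:p]
  Q <- sweep(H, 2, sqrt(colMeans(H^2)), "/")
  colnames(Q) <- paste0("q", 1:p)
  yo <- drop(Q[, 1] * 2 - Q[, 2] + rnorm(n))
  lam <- 0.25
  fo <- lasso_fit(Q, yo, lam)
  rho <- drop(crossprod(Q, yo - mean(yo))) / n
  closed <- sign(rho) * pmax(abs(rho) - lam, 0)
  expect_lt(max(abs(unname(fo$coefficients) - unname(closed))), 1e-6)
  expect_error(lasso_fit(X, y, -1), ">= 0")
  Xz <- cbind(X, zero = 0)
  expect_warning(lasso_fit(Xz, y, 0.1), "zero-variance")
})

test_that("the lasso agrees with glmnet at matched penalties", {
  skip_if_not_installed("glmnet")
  set.seed(63)
  n <- 120; p <- 40
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("x", 1:p)))
  y <- drop(X[, 1:5] %*% seq(0.4, 1.2, length.out = 5) + rnorm(n))
  for (lam in c(0.05, 0.2, 0.5)) {
    g <- glmnet::glmnet(X, y, lambda = lam, standardize = TRUE, thresh = 1e-14)
    f <- lasso_fit(X, y, lam)
    expect_lt(max(abs(as.numeric(coef(g))[-1] - f$coefficients)), 1e-6)
  }
})

test_that("cross-validated penalty selection is deterministic and sane", {
  set.seed(64)
  n <- 150; p <- 30
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("x", 1:p)))
  y <- drop(X[, 1:3] %*% c(1.5, -1.2, 1) + rnorm(n, 0, 0.5))
  cv1 <- cv_select_lambda(X, y, fold_seed = 99)
  cv2 <- cv_select_lambda(X, y, fold_seed = 99)
  expect_identical(cv1$lambda, cv2$lambda)
  # a strong 3-predictor signal is captured at the chosen penalty
  hits <- vapply(1:10, function(sd0) {
    cv <- cv_select_lambda(X, y, fold_seed = sd0)
    supp <- which(lasso_fit(X, y, cv$lambda)$coefficients != 0)
    all(1:3 %in% supp)
  }, logical(1))
  expect_gte(mean(hits), 0.9)
  # pure-noise response: the selected model stays (near-)empty
  empty <- vapply(1:10, function(sd0) {
    set.seed(1000 + sd0); yn <- rnorm(n)
    cv <- cv_select_lambda(X, yn, fold_seed = sd0, lambda_rule = "1se")
    sum(lasso_fit(X, yn, cv$lambda)$coefficients != 0) <= 2
  }, logical(1))
  expect_gte(mean(empty), 0.8)
})

test_that("OLS refit metrics follow the train-mean-anchored convention", {
  # crafted so test predictions are (1,2,3,5) against truth (1,2,3,4)
  Xtr <- matrix(c(1, 2, 3), 3, 1, dimnames = list(NULL, "r"))
  ytr <- c(1, 2, 3)
  Xte <- matrix(c(1, 2, 3, 5), 4, 1, dimnames = list(NULL, "r"))
  yte <- c(1, 2, 3, 4)
  m <- refit_ols_and_evaluate(Xtr, ytr, Xte, yte)
  expect_equal(m$train_rmse, 0)
  expect_equal(m$train_r2, 1)
  expect_equal(m$test_rmse, 0.5)
  expect_equal(m$test_r2, 1 - 1 / 6)  # total variation anchored at mean(ytr) = 2
  expect_error(refit_ols_and_evaluate(Xtr[, 0, drop = FALSE], ytr, Xte, yte),
               "empty")
})

test_that("stability selection is deterministic and rejects noise", {
  set.seed(65)
  n <- 60; p <- 50
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("x", 1:p)))
  y <- rnorm(n)
  s1 <- stability_selection(X, y, X[1:10, ], y[1:10], n_runs = 8, master_seed = 5)
  s2 <- stability_selection(X, y, X[1:10, ], y[1:10], n_runs = 8, master_seed = 5)
  expect_identical(s1$selection_frequency, s2$selection_frequency)
  expect_identical(s1$majority_set, s2$majority_set)
  expect_length(s1$majority_set, 0)  # noise-only response
})

test_that("the full progression pipeline mirrors the staged filter cascade", {
  co <- memo("prog_cohort", function() {
    simulate_cohort(progression_benchmark_config(seed = 2))
  })
  nn <- memo("prog_norm", function() normalize_counts(co$counts))
  out <- memo("prog_run", function() {
    run_progression(nn$vst$values, co$regions, co$genes, co$metadata,
                    n_runs = 25, master_seed = 2)
  })
  rep <- out$filter_report
  expect_setequal(rep$excluded_by_correlation, co$truth$corr_outliers)
  expect_setequal(rep$excluded_by_slope_iqr, co$truth$slope_outliers)
  expect_length(rep$excluded_by_batch, 68)
  expect_length(rep$retained, 156)
  expect_length(out$split$train, 140)
  expect_length(out$split$test, 16)
  # filter report accounts for every eligible sample exactly once
  eligible <- co$metadata$sample_id[co$metadata$case_status == "ALS" &
                                      !is.na(co$metadata$alsfrs_r_slope)]
  expect_setequal(c(rep$excluded_by_correlation, rep$excluded_by_slope_iqr,
                    rep$excluded_by_batch, rep$retained), eligible)
  # majority set is dominated by planted drivers
  drv <- co$truth$progression$driver_region_ids
  expect_gte(mean(out$stability$majority_set %in% drv), 0.8)
})
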