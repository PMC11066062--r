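test_that("top variable regions are ranked by variance with id tie-breaks", {
  m <- matrix(rnorm(50 * 10), 50, 10,
              dimnames = list(sprintf("r%02d", 1:50), paste0("s", 1:10)))
  m["r07", ] <- m["r07", ] * 50
  expect_equal(top_variable_regions(m, 1), "r07")
  expect_setequal(top_variable_regions(m, 50), rownames(m))
  tie <- matrix(rep(c(1, -1), 5), 3, 10, byrow = TRUE,
                dimnames = list(c("b", "a", "c"), paste0("s", 1:10)))
  expect_equal(top_variable_regions(tie, 2), c("a", "b"))
  expect_error(top_variable_regions(m, 0), "positive")
  expect_error(top_variable_regions(m, 51), "exceeds")
})

test_that("PCA captures planted low-rank structure", {
  set.seed(81)
  n <- 40; m <- 200
  f <- rnorm(n)
  mat <- outer(rnorm(m), f) + matrix(rnorm(m * n, 0, 0.2), m, n)
  dimnames(mat) <- list(sprintf("r%03d", 1:m), sprintf("s%02d", 1:n))
  pc <- pca_samples(mat)
  expect_gte(pc$variance_explained[1], 0.9)
  expect_true(all(diff(pc$variance_explained) <= 1e-12))
  # adding a per-region constant does not move the scores
  pc2 <- pca_samples(mat + rnorm(m))
  expect_equal(abs(pc$scores[, 1]), abs(pc2$scores[, 1]), tolerance = 1e-6)
  expect_error(pca_samples(matrix(1, 5, 3,
                                  dimnames = list(1:5, 1:3))), "constant")
})

test_that("sex and PBMC structure separates samples in PC space", {
  co <- small_cohort()
  nn <- small_normalized()
  ids <- top_variable_regions(nn$vst$values, 100)
  pc <- pca_samples(nn$vst$values, ids, n_components = 2)
  sex <- co$metadata$sex
  # one of the top two PCs splits the sexes nearly perfectly
  sep <- vapply(1:2, function(k) {
    thr <- median(pc$scores[, k])
    max(mean((pc$scores[, k] > thr) == (sex == "Female")),
        mean((pc$scores[, k] > thr) == (sex == "Male")))
  }, numeric(1))
  expect_gte(max(sep), 0.9)
})

test_that("PBMC label imputation recovers hidden labels", {
  co <- small_cohort()
  nn <- small_normalized()
  md <- co$metadata
  hidden <- which(is.na(md$pbmc_type))
  expect_gt(length(hidden), 0)
  imp <- impute_pbmc_labels(nn$vst$values, md)
  expect_false(any(is.na(imp$pbmc_type)))
  truth <- ifelse(co$truth$pbmc_true[hidden], "T-cell", "non-T-cell")
  expect_gte(mean(imp$pbmc_type[hidden] == truth), 0.9)
  # nothing to do when labels are complete
  md2 <- md; md2$pbmc_type <- ifelse(co$truth$pbmc_true, "T-cell", "non-T-cell")
  imp2 <- impute_pbmc_labels(nn$vst$values, md2)
  expect_equal(imp2$pbmc_type, md2$pbmc_type)
  expect_error(impute_pbmc_labels(nn$vst$values, md, k = nrow(md) + 1),
               "labeled samples")
})

test_that("chrX reads-not-in-peaks arithmetic is exact and scale-consistent", {
  md <- data.frame(sample_id = c("a", "b"), sex = c("Female", "Male"),
                   total_reads = c(10000, 10000),
                   chrx_reads = c(1000, 400),
                   chrx_reads_in_peaks = c(400, 400))
  rn <- chrx_rnip(md)
  expect_equal(rn$per_sample$chrx_rnip_normalized, c(0.06, 0))
  md2 <- md
  md2[, c("total_reads", "chrx_reads", "chrx_reads_in_peaks")] <-
    2 * md2[, c("total_reads", "chrx_reads", "chrx_reads_in_peaks")]
  expect_equal(chrx_rnip(md2)$per_sample$chrx_rnip_normalized,
               rn$per_sample$chrx_rnip_normalized)
  bad <- md; bad$chrx_reads_in_peaks[1] <- 2000
  expect_error(chrx_rnip(bad), "exceeds")
})

test_that("females carry the planted two-fold chrX background excess", {
  co <- small_cohort()
  rn <- chrx_rnip(co$metadata)
  ratio <- rn$medians[["Female"]] / rn$medians[["Male"]]
  expect_equal(ratio, 2, tolerance = 0.1)
  expect_lt(rn$mw_p_value, 0.01)
})

test_that("correlation clustering flags a planted outlier block", {
  set.seed(82)
  m <- 300
  base <- rnorm(m, 6, 2)
  good <- sapply(1:30, function(i) base + rnorm(m, 0, 0.5))
  bad <- sapply(1:3, function(i) rnorm(m, 6, 2))
  mat <- cbind(good, bad)
  colnames(mat) <- c(sprintf("g%02d", 1:30), sprintf("o%02d", 1:3))
  rownames(mat) <- sprintf("r%03d", 1:m)
  cl <- inter_sample_correlation_cluster(mat)
  expect_setequal(cl$flagged, sprintf("o%02d", 1:3))
  expect_true(all(diff(cl$tree$height) >= -1e-12))  # complete-link monotone
  # three near-identical samples: one tight cluster, nothing flagged
  tri <- sapply(1:3, function(i) base)
  colnames(tri) <- paste0("t", 1:3); rownames(tri) <- rownames(mat)
  cl3 <- inter_sample_correlation_cluster(tri + matrix(rnorm(3 * m, 0, 1e-6), m))
  expect_equal(cl3$flagged, character(0))
  expect_error(inter_sample_correlation_cluster(mat[, 1:2]), "at least 3")
})
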