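test_that("median-of-ratios size factors are exact on proportional columns", {
  k1 <- matrix(c(10L, 40L, 100L, 7L), 4, 1)
  k <- cbind(k1, 2L * k1)
  dimnames(k) <- list(paste0("r", 1:4), c("a", "b"))
  s <- size_factors_median_of_ratios(k)
  expect_equal(unname(s), c(1 / sqrt(2), sqrt(2)))
  k_id <- cbind(k1, k1, k1)
  dimnames(k_id) <- list(paste0("r", 1:4), c("a", "b", "c"))
  expect_equal(unname(size_factors_median_of_ratios(k_id)), rep(1, 3))
})

test_that("size factors require a fully observed region", {
  k <- matrix(c(0L, 5L, 3L, 0L), 2, 2,
              dimnames = list(c("r1", "r2"), c("a", "b")))
  expect_error(size_factors_median_of_ratios(k), "pseudocount")
})

test_that("per-region dispersion MLE is consistent at moderate n", {
  set.seed(21)
  n <- 200
  k <- matrix(rnbinom(40 * n, mu = 500, size = 10), 40, n,
              dimnames = list(paste0("r", 1:40), paste0("s", 1:n)))
  dm <- estimate_dispersions(k, setNames(rep(1, n), colnames(k)))
  expect_true(all(abs(dm$alpha_hat - 0.1) / 0.1 < 0.35))
  expect_lt(abs(median(dm$alpha_hat) - 0.1) / 0.1, 0.2)
})

test_that("Poisson counts give a near-zero dispersion trend", {
  set.seed(22)
  n <- 120; m <- 400
  mu0 <- 2^runif(m, 3, 9)
  k <- matrix(rpois(m * n, rep(mu0, n)), m, n,
              dimnames = list(paste0("r", 1:m), paste0("s", 1:n)))
  dm <- estimate_dispersions(k, setNames(rep(1, n), colnames(k)))
  expect_lte(dm$alpha0, 0.01)
})

test_that("the dispersion trend is recovered from trend-generated data", {
  fx <- nb_trend_matrix(n = 200, m = 1500)
  dm <- estimate_dispersions(fx$counts, fx$s)
  expect_lt(abs(dm$alpha0 - fx$alpha0) / fx$alpha0, 0.25)
  expect_lt(abs(dm$a1 - fx$a1) / fx$a1, 0.25)
})

test_that("the VST is monotone, log2-like at large counts, and invertible", {
  fx <- nb_trend_matrix(n = 60, m = 400, seed = 9)
  nn <- normalize_counts(fx$counts)
  v <- nn$vst
  # monotone on the grid
  expect_true(all(diff(v$grid_y) >= 0))
  # per-sample monotone in counts
  j <- 1
  ord <- order(fx$counts[, j])
  expect_true(all(diff(v$values[ord, j]) >= -1e-9))
  # above the calibration range the transform is log2-like: unit local
  # slope against log2(q) and a modest absolute offset
  hi <- v$grid_q > quantile(fx$counts, 0.75)
  q <- v$grid_q[hi]; y <- v$grid_y[hi]
  slope_local <- diff(y) / diff(log2(q))
  expect_true(all(slope_local > 0.6 & slope_local <= 1 + 1e-8))
  expect_lt(max(abs(y - log2(q))), 3)
  # numerical round-trip on the calibration grid
  g <- v$grid_q[v$grid_q > 0 & v$grid_q < max(v$grid_q)]
  expect_lt(max(abs(vst_inverse(v, approx(v$grid_q, v$grid_y, g)$y) - g)), 1e-6)
  expect_error(vst(-fx$counts, fx$s, nn$dispersions), "non-negative")
})

test_that("the VST flattens variance across the mean range", {
  fx <- nb_trend_matrix(n = 150, m = 2000, scatter_sd = 0, seed = 31)
  s <- size_factors_median_of_ratios(fx$counts)
  dm <- estimate_dispersions(fx$counts, s)
  v <- vst(fx$counts, s, dm)
  sds <- sqrt(atacohort:::row_vars(v$values))
  qs <- cut(rowMeans(fx$counts), quantile(rowMeans(fx$counts), 0:4 / 4),
            include.lowest = TRUE)
  bin_sd <- tapply(sds, qs, median)
  expect_lt(max(bin_sd) / min(bin_sd), 1.5)
})

test_that("rescaling one sample's counts moves only its size factor", {
  fx <- nb_trend_matrix(n = 20, m = 300, seed = 12)
  k <- fx$counts
  k2 <- k; k2[, 1] <- 4L * k2[, 1]
  s1 <- size_factors_median_of_ratios(k)
  s2 <- size_factors_median_of_ratios(k2)
  n <- ncol(k)
  # the scaled sample's factor grows by 4^(1 - 1/n) and the others shrink
  # by 4^(-1/n): the geometric-mean reference absorbs 4^(1/n) of the scale
  expect_equal(s2[[1]] / s1[[1]], 4^(1 - 1 / n), tolerance = 1e-6)
  expect_equal(s2[[2]] / s1[[2]], 4^(-1 / n), tolerance = 1e-6)
  # transformed values shift by (at most) the tiny global constant the
  # reference absorbs; sample-to-sample structure is untouched
  dm <- estimate_dispersions(k, s1)
  v1 <- vst(k, s1, dm)
  v2 <- vst(k2, s2, dm)
  delta <- v2$values[, 1] - v1$values[, 1]
  expect_lt(sd(delta), 0.02)
  expect_lt(abs(mean(delta)), 0.15)
})

test_that("size factors and dispersion calls agree with the DESeq2 oracle", {
  skip_if_not_installed("DESeq2")
  fx <- nb_trend_matrix(n = 40, m = 500, seed = 14)
  s_pkg <- size_factors_median_of_ratios(fx$counts)
  s_ref <- DESeq2::estimateSizeFactorsForMatrix(fx$counts)
  expect_equal(unname(s_pkg), unname(s_ref), tolerance = 1e-10)
})
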