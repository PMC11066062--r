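#' Median-of-ratios size factors
#'
#' For every region `i` whose counts are strictly positive in all samples,
#' let `GM_i` be the geometric mean of its counts across samples. The size
#' factor of sample `j` is the median over those regions of
#' `K_ij / GM_i` (the geometric median-of-ratios estimator).
#'
#' @param counts Region-by-sample integer matrix.
#' @return Named positive numeric vector, one size factor per sample.
#' @export
size_factors_median_of_ratios <- function(counts) {
  validate_counts(counts)
  pos <- rowSums(counts == 0) == 0
  if (!any(pos)) {
    abort_validation(paste0(
      "no region has strictly positive counts in every sample; ",
      "filter low-coverage regions or add a pseudocount before ",
      "estimating size factors"))
  }
  logk <- log(counts[pos, , drop = FALSE])
  log_gm <- rowMeans(logk)
  s <- apply(exp(logk - log_gm), 2, stats::median)
  stats::setNames(s, colnames(counts))
}

# NB log-likelihood in alpha for one region given fixed means mu_j,
# with a Cox-Reid adjustment for n_params fitted mean parameters
nb_alpha_loglik <- function(alpha, k, mu, n_params = 1L) {
  size <- 1 / alpha
  ll <- sum(stats::dnbinom(k, mu = mu, size = size, log = TRUE))
  w <- mu / (1 + alpha * mu)
  ll - 0.5 * n_params * log(sum(w))
}

#' Per-region negative-binomial dispersion estimates and parametric trend
#'
#' Each region's dispersion is estimated by one-dimensional bounded
#' maximum likelihood (`alpha` in `[1e-8, 10]`, profiled on the log scale)
#' given fitted means `mu_hat_i * s_j`, where `mu_hat_i` is the mean
#' normalized count; a Cox-Reid term adjusts for the fitted mean. The
#' parametric trend `alpha(mu) = a1/mu + alpha0` is then fit by iterated
#' least squares of `alpha_hat` on `1/mu_hat`, at each iteration excluding
#' regions whose estimate exceeds twice the current trend, until the
#' trimmed set stabilizes (at most 10 iterations).
#'
#' @param counts Region-by-sample integer matrix.
#' @param size_factors Output of [size_factors_median_of_ratios()].
#' @param min_mu Regions with mean normalized count below this are excluded
#'   from the trend fit (their per-region estimates are still returned).
#' @return A `dispersion_model` list: `mu_hat`, `alpha_hat`, `alpha0`, `a1`.
#' @export
estimate_dispersions <- function(counts, size_factors, min_mu = 1) {
  validate_counts(counts)
  stopifnot(length(size_factors) == ncol(counts), all(size_factors > 0))
  m <- nrow(counts)
  mu_hat <- rowMeans(sweep(counts, 2, size_factors, "/"))
  alpha_hat <- rep(NA_real_, m)
  lo <- log(1e-8); hi <- log(10)
  for (i in seq_len(m)) {
    if (mu_hat[i] <= 0) next
    k <- counts[i, ]
    mu <- mu_hat[i] * size_factors
    opt <- stats::optimize(function(la) -nb_alpha_loglik(exp(la), k, mu),
                           interval = c(lo, hi), tol = 1e-6)
    alpha_hat[i] <- exp(opt$minimum)
  }
  use <- which(!is.na(alpha_hat) & mu_hat >= min_mu)
  trend <- fit_dispersion_trend(alpha_hat[use], mu_hat[use])
  structure(
    list(mu_hat = stats::setNames(mu_hat, rownames(counts)),
         alpha_hat = stats::setNames(alpha_hat, rownames(counts)),
         alpha0 = trend$alpha0, a1 = trend$a1),
    class = "dispersion_model"
  )
}

# iterated (re)weighted least squares of alpha_hat on 1/mu_hat: weights
# 1/trend^2 account for the roughly multiplicative scatter of dispersion
# estimates around the trend (the gamma-GLM convention); regions above
# 2x the current trend are trimmed each round
fit_dispersion_trend <- function(alpha_hat, mu_hat, max_iter = 10) {
  fit_once <- function(idx, w) {
    x <- 1 / mu_hat[idx]
    cf <- stats::coef(stats::lm(alpha_hat[idx] ~ x, weights = w[idx]))
    a0 <- cf[[1]]; a1 <- cf[[2]]
    # non-negativity: refit with the offending term removed
    if (a1 < 0) { a1 <- 0; a0 <- stats::weighted.mean(alpha_hat[idx], w[idx]) }
    if (a0 < 0) {
      a0 <- 0
      a1 <- sum(w[idx] * alpha_hat[idx] * x) / sum(w[idx] * x^2)
    }
    list(alpha0 = max(a0, 0), a1 = max(a1, 0))
  }
  all_idx <- seq_along(alpha_hat)
  w <- rep(1, length(alpha_hat))
  keep <- all_idx
  tr <- fit_once(keep, w)
  for (it in seq_len(max_iter)) {
    pred <- pmax(tr$a1 / mu_hat + tr$alpha0, 1e-8)
    w <- 1 / pred^2
    keep_new <- which(alpha_hat <= 2 * pred)
    if (!length(keep_new)) {
      warning("all regions trimmed during dispersion-trend fitting; ",
              "falling back to the untrimmed fit")
      return(fit_once(all_idx, w))
    }
    tr_new <- fit_once(keep_new, w)
    done <- identical(keep_new, keep)
    keep <- keep_new
    tr <- tr_new
    if (done) break
  }
  tr
}

#' Evaluate the dispersion trend at given means
#'
#' @param model A `dispersion_model`.
#' @param mu Mean normalized counts.
#' @return `a1/mu + alpha0`.
#' @export
dispersion_trend <- function(model, mu) {
  model$a1 / pmax(mu, 1e-8) + model$alpha0
}

#' Variance-stabilizing transformation
#'
#' Applies `y = g(K/s)` with `g(q) = integral_0^q dmu / sqrt(mu +
#' alpha(mu) * mu^2)` under the fitted dispersion trend, evaluated by
#' adaptive numerical quadrature on a log-spaced grid and interpolated
#' monotonically. The transform is affinely calibrated so it matches
#' `log2(q)` at the 25th and 75th percentiles of the positive normalized
#' counts, making large-count values read like log2 normalized counts.
#'
#' @param counts Region-by-sample integer matrix.
#' @param size_factors Size factors.
#' @param dispersion_model Output of [estimate_dispersions()].
#' @param n_grid Number of quadrature grid points.
#' @return A `vst_result` list: `values` (transformed matrix), `grid_q`,
#'   `grid_y` (calibrated transform on the grid), `scale`, `offset`,
#'   `alpha0`, `a1`.
#' @export
vst <- function(counts, size_factors, dispersion_model, n_grid = 200) {
  validate_counts(counts)
  q <- sweep(counts, 2, size_factors, "/")
  if (any(q < 0)) abort_validation("negative normalized counts")
  a0 <- dispersion_model$alpha0; a1 <- dispersion_model$a1
  integrand <- function(mu) 1 / sqrt((1 + a1) * mu + a0 * mu^2)
  qmax <- max(q) * 1.05 + 1
  grid <- c(0, 10^seq(log10(1e-3), log10(qmax), length.out = n_grid))
  seg <- vapply(seq_len(length(grid) - 1), function(i) {
    stats::integrate(integrand, grid[i], grid[i + 1],
                     rel.tol = 1e-9, abs.tol = 1e-12)$value
  }, numeric(1))
  g <- c(0, cumsum(seg))
  # affine calibration: for overdispersed trends the integrand gives
  # g(q) ~ ln(q)/sqrt(alpha0) at large q, so the asymptotic scale
  # sqrt(alpha0)/ln(2) makes the transform exactly log2-like at large
  # counts; the offset anchors it to log2(q) at the 75th percentile of
  # positive normalized counts. Near the Poisson limit (alpha0 ~ 0) there
  # is no log asymptote and the quartiles set the scale instead. Either
  # way the calibration is affine, so downstream correlations and
  # selections are unaffected by the choice.
  qq <- stats::quantile(q[q > 0], c(0.25, 0.75), names = FALSE)
  if (qq[1] == qq[2]) qq <- range(q[q > 0]) + c(0, 1e-6)
  g_at <- stats::approx(grid, g, xout = qq)$y
  if (a0 > 1e-6) {
    sc <- sqrt(a0) / log(2)
  } else {
    sc <- (log2(qq[2]) - log2(qq[1])) / (g_at[2] - g_at[1])
  }
  off <- log2(qq[2]) - sc * g_at[2]
  fun <- stats::splinefun(grid, sc * g + off, method = "monoH.FC")
  vals <- matrix(fun(q), nrow = nrow(q), dimnames = dimnames(q))
  structure(
    list(values = vals, grid_q = grid, grid_y = sc * g + off,
         scale = sc, offset = off, alpha0 = a0, a1 = a1),
    class = "vst_result"
  )
}

#' Invert a variance-stabilizing transform on its calibration grid
#'
#' @param vst_result A [vst()] result.
#' @param y Transformed values.
#' @return Normalized counts `q` such that `vst(q) = y`.
#' @export
vst_inverse <- function(vst_result, y) {
  stats::approx(vst_result$grid_y, vst_result$grid_q, xout = y, rule = 2)$y
}

#' One-call normalization of a counts matrix
#'
#' Convenience wrapper: size factors, dispersion model, then [vst()].
#'
#' @param counts Region-by-sample integer matrix.
#' @return A list: `size_factors`, `dispersions`, `vst` (with `$values`).
#' @export
normalize_counts <- function(counts) {
  s <- size_factors_median_of_ratios(counts)
  d <- estimate_dispersions(counts, s)
  v <- vst(counts, s, d)
  list(size_factors = s, dispersions = d, vst = v)
}
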