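# shared fixtures, built once per test run and memoised

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (!exists(key, envir = .fixture_env)) {
    assign(key, builder(), envir = .fixture_env)
  }
  get(key, envir = .fixture_env)
}

# small cohort exercising every planted effect class
small_cohort <- function() {
  memo("small_cohort", function() {
    cfg <- cohort_config(n_cases = 60, n_controls = 10, n_regions = 800,
                         n_genes = 300, seed = 101)
    simulate_cohort(cfg)
  })
}

small_normalized <- function() {
  memo("small_normalized", function() normalize_counts(small_cohort()$counts))
}

# NB matrix drawn straight from a dispersion trend, no planted effects
nb_trend_matrix <- function(n = 200, m = 1500, alpha0 = 0.05, a1 = 3,
                            scatter_sd = 0.3, seed = 77) {
  set.seed(seed)
  mu0 <- 2^rnorm(m, 5, 1.5)
  s <- runif(n, 0.5, 2)
  alpha <- (a1 / mu0 + alpha0) * exp(rnorm(m, 0, scatter_sd))
  k <- matrix(rnbinom(m * n, mu = as.vector(outer(mu0, s)),
                      size = rep(1 / alpha, n)), m, n)
  rownames(k) <- sprintf("r%05d", seq_len(m))
  colnames(k) <- sprintf("s%03d", seq_len(n))
  list(counts = k, s = setNames(s, colnames(k)), mu0 = mu0, alpha = alpha,
       alpha0 = alpha0, a1 = a1)
}

# three-region toy region set
toy_regions <- function() {
  region_set(c("chr1", "chr1", "chr2"), c(100L, 500L, 40L),
             c(300L, 900L, 90L), c("a", "b", "c"))
}
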