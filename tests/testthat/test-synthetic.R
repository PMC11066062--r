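test_that("metadata group counts echo the configuration exactly", {
  cfg <- cohort_config(n_cases = 140, n_controls = 20, n_regions = 200,
                       n_genes = 80, seed = 3)
  md <- simulate_metadata(cfg)
  expect_equal(sum(md$case_status == "ALS"), 140)
  expect_equal(sum(md$case_status == "HC"), 20)
  expect_equal(sum(md$sex == "Female"), 80)
  expect_equal(sum(md$c9_status == "POS"), cfg$c9_pos)
  cfg2 <- cohort_config(n_cases = 180, n_controls = 20, n_regions = 200,
                        n_genes = 80, t_cell_fraction = 0.5,
                        pbmc_missing_fraction = 0, seed = 3)
  md2 <- simulate_metadata(cfg2)
  expect_equal(sum(md2$pbmc_type == "T-cell"), 100)
})

test_that("the cohort is deterministic under (seed, config)", {
  cfg <- cohort_config(n_cases = 30, n_controls = 6, n_regions = 600,
                       n_genes = 240, seed = 17)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$counts, b$counts)
  expect_identical(a$metadata, b$metadata)
  expect_identical(a$expression, b$expression)
  cfg2 <- cohort_config(n_cases = 30, n_controls = 6, n_regions = 600,
                        n_genes = 240, seed = 18)
  c <- simulate_cohort(cfg2)
  expect_false(identical(a$counts, c$counts))
  # planted truth structure (which classes exist, their sizes) is seed-stable
  expect_equal(lengths(a$truth$classes), lengths(c$truth$classes))
})

test_that("counts follow the planted negative-binomial mean-variance trend", {
  co <- small_cohort()
  truth <- co$truth
  norm <- sweep(co$counts, 2, truth$size_factors, "/")
  planted <- setdiff(rownames(co$counts), truth$effects$region_id)
  planted <- setdiff(planted, truth$progression$driver_region_ids)
  mu <- rowMeans(norm[planted, ])
  v_obs <- apply(norm[planted, ], 1, var)
  alpha <- truth$dispersions[planted]
  # normalized-count variance is approx mu/harmonic-mean(s) + alpha mu^2;
  # compare in aggregate over effect-free regions
  s <- truth$size_factors
  v_pred <- mu * mean(1 / s) + alpha * mu^2
  ratio <- median(v_obs / v_pred)
  expect_gt(ratio, 0.8)
  expect_lt(ratio, 1.25)
})

test_that("per-sample depth factors drive column sums", {
  co <- small_cohort()
  s <- co$truth$size_factors
  cs <- colSums(co$counts)
  expect_gt(cor(cs, s), 0.98)
  hi <- which.max(s); lo <- which.min(s)
  expect_equal(cs[[hi]] / cs[[lo]], s[[hi]] / s[[lo]], tolerance = 0.15)
})

test_that("planted group effects appear in normalized group means", {
  co <- small_cohort()
  truth <- co$truth
  md <- co$metadata
  norm <- sweep(co$counts, 2, truth$size_factors, "/")
  c9 <- truth$effects[truth$effects$class == "c9_promoter", ]
  pos <- md$c9_status == "POS"
  obs <- log2(rowMeans(norm[c9$region_id, pos, drop = FALSE]) /
                rowMeans(norm[c9$region_id, !pos, drop = FALSE]))
  expect_lt(abs(mean(obs) - (-0.6)), 0.2)  # 10-vs-60 group sizes
  # chrY regions near-silent in females
  chry <- truth$effects$region_id[truth$effects$class == "chry"]
  f <- md$sex == "Female"
  expect_lt(mean(norm[chry, f]), 0.05 * mean(norm[chry, !f]))
})

test_that("read-total bookkeeping is internally consistent", {
  md <- small_cohort()$metadata
  expect_true(all(md$chrx_reads_in_peaks <= md$chrx_reads))
  expect_true(all(md$chrx_reads <= md$total_reads))
  expect_true(all(md$frip >= 0 & md$frip <= 1))
})

test_that("planted expression links have the configured strength and signs", {
  cfg <- cohort_config(n_cases = 80, n_controls = 10, n_regions = 600,
                       n_genes = 250, seed = 5,
                       coexpr = list(n_links = 20, n_dual = 3, noise_sd = 0.1))
  co <- simulate_cohort(cfg)
  links <- co$truth$links
  expect_gt(nrow(links), 15)
  a_norm <- log2(sweep(co$counts, 2, co$truth$size_factors, "/") + 1)
  cors <- mapply(function(g, r, sl) {
    sign(sl) * cor(co$expression[g, ], a_norm[r, ])
  }, links$gene_id, links$region_id, links$slope)
  expect_true(all(cors >= 0.9))  # attenuation: slope 1, noise sd 0.1
  expect_true(all(abs(links$distance) <= 250000))
  # dual-sign peaks recorded with one positive and one negative gene
  both <- vapply(split(sign(links$slope), links$region_id),
                 function(z) all(c(-1, 1) %in% z), logical(1))
  expect_gte(sum(both), 1)
  # unlinked genes are null: their best correlation stays moderate
  un <- setdiff(rownames(co$expression), links$gene_id)[1:10]
  maxcor <- vapply(un, function(g)
    max(abs(cor(co$expression[g, ], t(a_norm[sample(nrow(a_norm), 100), ])))),
    numeric(1))
  expect_true(all(maxcor < 0.6))
})

test_that("fixture bundles round-trip through the writer", {
  co <- small_cohort()
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  expect_equal(read_counts(file.path(dir, "counts.tsv")), co$counts)
  md <- as.data.frame(data.table::fread(file.path(dir, "metadata.tsv")))
  expect_equal(md$sample_id, co$metadata$sample_id)
  rs <- read_regions_bed(file.path(dir, "regions.bed"))
  expect_setequal(rs$region_id, co$regions$region_id)
  cfg <- yaml::read_yaml(file.path(dir, "config.yaml"))
  expect_equal(cfg$n_regions, co$config$n_regions)
})
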