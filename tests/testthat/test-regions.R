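test_that("region centers follow the floor-midpoint convention", {
  rs <- region_set("chr1", 100, 300, "r1")
  expect_equal(region_centers(rs), 200L)
  rs2 <- region_set("chr1", 100, 301, "r1")
  expect_equal(region_centers(rs2), 200L)  # floor((100 + 301) / 2)
  expect_true(all(region_centers(toy_regions()) >= toy_regions()$start))
  expect_true(all(region_centers(toy_regions()) < toy_regions()$end))
})

test_that("BED write-then-read round-trips a region set", {
  rs <- toy_regions()
  path <- withr::local_tempfile(fileext = ".bed")
  write_regions_bed(rs, path)
  back <- read_regions_bed(path)
  expect_equal(back[c("chrom", "start", "end", "region_id")],
               rs[c("chrom", "start", "end", "region_id")])
})

test_that("malformed BED input is rejected with the offending line", {
  path <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t300\tok", "chr1\t300\t100\tbad"), path)
  expect_error(read_regions_bed(path), "line 2")
  writeLines("chr1\t100", path)
  expect_error(read_regions_bed(path), "fewer than 3")
  expect_error(region_set("chr1", 300, 100), "end")
})

test_that("consensus retention threshold is ceil(min_fraction * n)", {
  # 20 samples; one interval shared by exactly 2 of them, another by 1
  base <- region_set("chr1", c(5000), c(5400), "bg")
  shared2 <- region_set("chr1", c(1000, 5000), c(1500, 5400), c("p", "bg"))
  shared1 <- region_set("chr1", c(9000, 5000), c(9100, 5400), c("q", "bg"))
  peaks <- c(list(shared2, shared2, shared1), rep(list(base), 17))
  cons <- build_consensus(peaks, min_fraction = 0.10)  # threshold ceil(2) = 2
  expect_true(any(cons$start == 1000 & cons$end == 1500))   # in 2 samples
  expect_false(any(cons$start == 9000))                      # in 1 sample
  expect_true(any(cons$start == 5000))
})

test_that("identical per-sample peak sets yield themselves as consensus", {
  rs <- toy_regions()
  cons <- build_consensus(rep(list(rs), 6), min_fraction = 0.10)
  expect_equal(cons[c("chrom", "start", "end")], rs[c("chrom", "start", "end")])
})

test_that("consensus construction is idempotent and monotone in min_fraction", {
  set.seed(1)
  peaks <- lapply(1:12, function(i) {
    st <- sort(sample(seq(0, 50000, by = 250), 30))
    region_set("chr1", st, st + sample(200:600, 30, replace = TRUE))
  })
  cons <- build_consensus(peaks, 0.25)
  again <- build_consensus(rep(list(cons), 12), 0.25)
  expect_equal(again[c("chrom", "start", "end")], cons[c("chrom", "start", "end")])
  sizes <- vapply(c(0.1, 0.25, 0.5, 0.9), function(f)
    nrow(build_consensus(peaks, f)), numeric(1))
  expect_true(all(diff(sizes) <= 0))
  # union intervals are disjoint
  expect_true(all(cons$start[-1] >= cons$end[-nrow(cons)] |
                    cons$chrom[-1] != cons$chrom[-nrow(cons)]))
  expect_error(build_consensus(list()), "non-empty")
})

test_that("promoter annotation follows the center-to-TSS distance rule", {
  genes <- data.frame(gene_id = "g1", chrom = "chr1", tss = 10000L,
                      strand = "+", stringsAsFactors = FALSE)
  rs <- region_set("chr1", c(8300, 59900), c(8700, 60300), c("near", "far"))
  ann <- annotate_regions(rs, genes, promoter_halfwidth = 2000)
  expect_equal(ann$annotation[ann$region_id == "near"], "promoter_tss")  # 1500 bp
  expect_equal(ann$annotation[ann$region_id == "far"], "intronic_intergenic")
  expect_error(annotate_regions(rs, genes[0, ]), "empty")
})

test_that("center-to-TSS distance is strand-oriented", {
  reg <- list(chrom = "chr5", start = 1099800, end = 1100200)
  gplus <- list(chrom = "chr5", tss = 1000000, strand = "+")
  gminus <- list(chrom = "chr5", tss = 1000000, strand = "-")
  expect_equal(center_tss_distance(reg, gplus), 100000)
  expect_equal(center_tss_distance(reg, gminus), -100000)
  g0 <- list(chrom = "chr5", tss = 1100000, strand = "+")
  expect_equal(center_tss_distance(reg, g0), 0)
  expect_error(center_tss_distance(reg, list(chrom = "chr6", tss = 1, strand = "+")),
               "different chromosomes")
})

test_that("counts matrices round-trip through TSV and MatrixMarket", {
  m <- matrix(rpois(20, 10), 5, 4,
              dimnames = list(paste0("r", 1:5), paste0("s", 1:4)))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_counts(m, tsv)
  expect_equal(read_counts(tsv), m)
  mtx <- withr::local_tempfile(fileext = ".mtx")
  write_counts(m, mtx)
  back <- read_counts(mtx)
  expect_equal(back[rownames(m), colnames(m)], m)
  bad <- m; bad[1, 1] <- -1
  expect_error(write_counts(bad, tsv), "non-negative")
})
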