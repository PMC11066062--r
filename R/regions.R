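#' Genomic regions, consensus peaks, and coordinate arithmetic
#'
#' Regions are plain data frames with columns `chrom`, `start`, `end`,
#' `region_id` (and optionally `annotation`), in the BED convention:
#' 0-based, half-open `[start, end)`. A region's *center* is
#' `floor((start + end) / 2)`, which always lies in `[start, end)`.
#'
#' @name regions
NULL

#' Construct a region set
#'
#' @param chrom Character chromosome names.
#' @param start,end Integer BED coordinates (0-based, half-open).
#' @param region_id Optional region identifiers; generated if missing.
#' @return A `data.frame` with class `"region_set"`, sorted by
#'   `(chrom, start)`.
#' @export
region_set <- function(chrom, start, end, region_id = NULL) {
  start <- as.integer(start); end <- as.integer(end)
  if (any(end <= start)) {
    bad <- which(end <= start)[1]
    abort_validation("region %d has end (%d) <= start (%d)", bad, end[bad], start[bad])
  }
  if (is.null(region_id)) {
    region_id <- sprintf("region_%0*d", nchar(length(chrom)), seq_along(chrom))
  }
  if (anyDuplicated(region_id)) abort_validation("duplicate region_id values")
  df <- data.frame(chrom = as.character(chrom), start = start, end = end,
                   region_id = as.character(region_id),
                   stringsAsFactors = FALSE)
  df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("region_set", "data.frame")
  df
}

#' Region centers
#'
#' @param regions A region set.
#' @return Integer vector, `floor((start + end) / 2)` per region.
#' @export
region_centers <- function(regions) {
  as.integer(floor((as.numeric(regions$start) + as.numeric(regions$end)) / 2))
}

# region set <-> GRanges (GRanges is 1-based closed)
regions_to_granges <- function(regions) {
  GenomicRanges::GRanges(
    seqnames = regions$chrom,
    ranges = IRanges::IRanges(start = regions$start + 1L, end = regions$end),
    region_id = regions$region_id
  )
}

granges_to_regions <- function(gr, region_id = NULL) {
  region_set(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    region_id = region_id
  )
}

#' Read regions from a BED file
#'
#' Accepts 3+ column BED (0-based, half-open); a fourth column, when
#' present, is used as `region_id`.
#'
#' @param path Path to a BED file.
#' @return A region set.
#' @export
read_regions_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) abort_validation("empty BED file: %s", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    abort_validation("malformed BED line %d in %s: fewer than 3 fields",
                     which(nf < 3L)[1], path)
  }
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3L)))
  if (anyNA(start) || anyNA(end)) {
    abort_validation("malformed BED line %d in %s: non-integer coordinates",
                     which(is.na(start) | is.na(end))[1], path)
  }
  if (any(end <= start)) {
    abort_validation("invalid BED line %d in %s: end <= start",
                     which(end <= start)[1], path)
  }
  id <- if (all(nf >= 4L)) vapply(fields, `[[`, "", 4L) else NULL
  region_set(chrom, start, end, id)
}

#' Write regions to a BED file
#'
#' @param regions A region set.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_regions_bed <- function(regions, path) {
  data.table::fwrite(
    data.table::as.data.table(unclass(regions))[, c("chrom", "start", "end", "region_id")],
    path, sep = "\t", col.names = FALSE
  )
  invisible(path)
}

#' Build a consensus peak set from per-sample peak sets
#'
#' Candidate intervals are the maximal unions of overlapping per-sample
#' peaks. A candidate is retained when at least `ceiling(min_fraction * n)`
#' of the `n` samples have at least 1 bp of overlap with it; retained
#' intervals keep their full union span, so consensus peaks are
#' variable-width.
#'
#' @param peak_sets List of region sets, one per sample.
#' @param min_fraction Minimum fraction of samples (default 0.10) in which a
#'   candidate must be open.
#' @return A region set of consensus peaks (ids `consensus_...`).
#' @export
build_consensus <- function(peak_sets, min_fraction = 0.10) {
  if (!is.list(peak_sets) || length(peak_sets) == 0L) {
    abort_validation("peak_sets must be a non-empty list of region sets")
  }
  if (min_fraction <= 0 || min_fraction > 1) {
    abort_validation("min_fraction must be in (0, 1]")
  }
  n <- length(peak_sets)
  grl <- lapply(peak_sets, regions_to_granges)
  all_gr <- suppressWarnings(do.call(c, unname(grl)))
  candidates <- GenomicRanges::reduce(all_gr)
  # number of samples with >= 1 bp overlap per candidate
  support <- rep(0L, length(candidates))
  for (g in grl) {
    support <- support +
      as.integer(GenomicRanges::countOverlaps(candidates, GenomicRanges::reduce(g)) > 0L)
  }
  keep <- support >= ceiling(min_fraction * n)
  kept <- candidates[keep]
  granges_to_regions(
    kept,
    region_id = sprintf("consensus_%0*d", max(1L, nchar(length(kept))), seq_along(kept))
  )
}

#' Read a gene table
#'
#' TSV with header columns `gene_id`, `chrom`, `tss` (0-based bp) and
#' `strand` (`+`/`-`).
#'
#' @param path Path to the TSV.
#' @return A `data.frame` of gene records.
#' @export
read_gene_table <- function(path) {
  g <- as.data.frame(data.table::fread(path, sep = "\t"))
  need <- c("gene_id", "chrom", "tss", "strand")
  if (!all(need %in% names(g))) {
    abort_validation("gene table must have columns %s", paste(need, collapse = ", "))
  }
  validate_genes(g)
  g
}

#' @rdname read_gene_table
#' @param genes Gene table.
#' @export
write_gene_table <- function(genes, path) {
  data.table::fwrite(genes, path, sep = "\t")
  invisible(path)
}

validate_genes <- function(genes) {
  if (is.null(genes) || nrow(genes) == 0L) abort_validation("gene table is empty")
  if (any(genes$tss < 0)) abort_validation("gene tss must be >= 0")
  if (!all(genes$strand %in% c("+", "-"))) abort_validation("gene strand must be '+' or '-'")
  invisible(genes)
}

# per-region distance (bp, unsigned) to the nearest TSS on the same chromosome;
# Inf when the chromosome carries no gene
nearest_tss_distance <- function(regions, genes) {
  centers <- region_centers(regions)
  out <- rep(Inf, nrow(regions))
  for (ch in unique(regions$chrom)) {
    tss <- genes$tss[genes$chrom == ch]
    if (!length(tss)) next
    idx <- which(regions$chrom == ch)
    tss <- sort(tss)
    pos <- findInterval(centers[idx], tss)
    lo <- pmax(pos, 1L); hi <- pmin(pos + 1L, length(tss))
    out[idx] <- pmin(abs(centers[idx] - tss[lo]), abs(centers[idx] - tss[hi]))
  }
  out
}

#' Annotate regions by TSS proximity
#'
#' A simplified distance rule: a region is `promoter_tss` when its center
#' lies within `promoter_halfwidth` bp of any TSS; when gene spans are
#' provided (columns `gene_start`, `gene_end` in the gene table) a
#' non-promoter region whose center falls inside a gene body is
#' `genic_other`; anything else is `intronic_intergenic`.
#'
#' @param regions A region set.
#' @param genes Gene table (`gene_id`, `chrom`, `tss`, `strand`).
#' @param promoter_halfwidth Promoter half-width in bp (default 2000).
#' @return The region set with an `annotation` column.
#' @export
annotate_regions <- function(regions, genes, promoter_halfwidth = 2000) {
  validate_genes(genes)
  d <- nearest_tss_distance(regions, genes)
  ann <- ifelse(d <= promoter_halfwidth, "promoter_tss", "intronic_intergenic")
  if (all(c("gene_start", "gene_end") %in% names(genes))) {
    centers <- region_centers(regions)
    for (i in which(ann == "intronic_intergenic")) {
      g <- genes[genes$chrom == regions$chrom[i], , drop = FALSE]
      if (any(g$gene_start <= centers[i] & centers[i] < g$gene_end)) {
        ann[i] <- "genic_other"
      }
    }
  }
  regions$annotation <- ann
  regions
}

#' Signed center-to-TSS distance
#'
#' Positive values are downstream of the TSS in the gene's direction of
#' transcription: `center - tss` for `+` strand genes, negated for `-`.
#'
#' @param region One-row region set (or list with `chrom`, `start`, `end`).
#' @param gene One-row gene record.
#' @return Signed distance in bp.
#' @export
center_tss_distance <- function(region, gene) {
  if (region$chrom != gene$chrom) {
    abort_validation("region (%s) and gene (%s) are on different chromosomes",
                     region$chrom, gene$chrom)
  }
  center <- floor((region$start + region$end) / 2)
  d <- center - gene$tss
  if (gene$strand == "-") d <- -d
  as.numeric(d)
}

#' Read and write counts matrices
#'
#' TSV layout: first column `region_id`, remaining columns one per sample.
#' MatrixMarket layout (`.mtx`): sidecar files `<stem>.regions.txt` and
#' `<stem>.samples.txt` hold the row and column identifiers.
#'
#' @param path File path (`.tsv`/`.txt` or `.mtx`).
#' @return An integer matrix with region-id rownames and sample-id colnames.
#' @export
read_counts <- function(path) {
  if (grepl("\\.mtx$", path)) {
    m <- as.matrix(Matrix::readMM(path))
    stem <- sub("\\.mtx$", "", path)
    rownames(m) <- readLines(paste0(stem, ".regions.txt"))
    colnames(m) <- readLines(paste0(stem, ".samples.txt"))
  } else {
    dt <- data.table::fread(path, sep = "\t")
    m <- as.matrix(dt[, -1])
    rownames(m) <- dt[[1]]
  }
  validate_counts(m)
  storage.mode(m) <- "integer"
  m
}

#' @rdname read_counts
#' @param counts Counts matrix with dimnames.
#' @export
write_counts <- function(counts, path) {
  validate_counts(counts)
  if (grepl("\\.mtx$", path)) {
    Matrix::writeMM(Matrix::Matrix(counts, sparse = TRUE), path)
    stem <- sub("\\.mtx$", "", path)
    writeLines(rownames(counts), paste0(stem, ".regions.txt"))
    writeLines(colnames(counts), paste0(stem, ".samples.txt"))
  } else {
    dt <- data.table::data.table(region_id = rownames(counts))
    dt <- cbind(dt, data.table::as.data.table(counts))
    data.table::fwrite(dt, path, sep = "\t")
  }
  invisible(path)
}

validate_counts <- function(counts) {
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    abort_validation("counts matrix must carry region_id rownames and sample_id colnames")
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    abort_validation("counts must be non-negative integers")
  }
  invisible(counts)
}
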