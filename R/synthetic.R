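#' Synthetic ATAC-seq cohort configuration
#'
#' Defines a synthetic cohort of iPSC-derived motor neuron lines with the
#' statistical structure the downstream analyses assume: negative-binomial
#' fragment counts with a dispersion-mean trend, per-sample depth factors,
#' and planted covariate effects (sex/chrX/chrY structure, PBMC-type
#' epigenetic memory and TCR-deletion regions, sequencer/FRiP technical
#' effects, ancestry-variant regions, a C9orf72-like promoter decrease, and
#' a multifactorial progression-rate signal linking region accessibility to
#' the ALSFRS-R slope). All planted values are recorded in a ground-truth
#' ledger so recovery can be tested.
#'
#' @param n_cases,n_controls Numbers of ALS cases and healthy controls.
#' @param n_regions,n_genes Numbers of chromatin regions and genes.
#' @param seed Master seed; the cohort is fully deterministic given
#'   `(seed, config)`.
#' @param female_fraction,t_cell_fraction Cohort composition fractions.
#' @param ancestry_fractions Named fractions summing to 1.
#' @param sequencers Sequencer labels; samples split evenly across them.
#' @param c9_pos Number of C9orf72-expansion-positive cases (remaining cases
#'   are verified negative; controls are negative).
#' @param batch_sizes Differentiation-batch sizes (must sum to
#'   `n_cases + n_controls`); `NULL` for `n_batches` near-equal batches.
#' @param n_batches Number of batches when `batch_sizes` is `NULL`.
#' @param pbmc_missing_fraction Fraction of samples whose PBMC label is
#'   hidden (true labels stay in the ground truth) to exercise imputation.
#' @param slope_recorded_fraction Fraction of cases with a recorded
#'   ALSFRS-R slope.
#' @param confound_sex_case In `[0, 1)`: 0 assigns case status independently
#'   of sex; larger values make cases increasingly female-enriched, to
#'   demonstrate covariate confounding.
#' @param tss_region_fraction Target fraction of regions placed at a gene
#'   TSS (capped by `n_genes`).
#' @param chrx_fraction,chry_fraction Fractions of regions on chrX / chrY.
#' @param baseline_log2 Mean and sd of per-region baseline log2 normalized
#'   accessibility.
#' @param nb_alpha0,nb_a1 Dispersion trend `alpha(mu) = a1/mu + alpha0`.
#' @param dispersion_scatter_sd Lognormal scatter (log-scale sd) of
#'   per-region dispersions around the trend.
#' @param depth_factor_range Range of per-sample depth (size) factors.
#' @param effects Planted effect-class sizes and log2 fold changes; see
#'   Details.
#' @param progression Progression-signal settings: `n_drivers` TSS-proximal
#'   driver regions forming a co-regulated module (`factor_loading`: log2
#'   accessibility per unit of the latent per-sample progression factor),
#'   `coef_scale` (slope units per sd of driver accessibility), slope-noise
#'   sd, mean slope, and counts of planted correlation/slope outlier
#'   samples.
#' @param coexpr Peak-gene link settings: number of links, number of
#'   dual-sign peaks, slope magnitude, negative-link fraction, noise sd.
#' @param rnip Per-sex chrX background read rates (fraction of total reads
#'   falling on chrX outside peaks).
#' @param frip_by_sequencer,frip_sd FRiP score mean per sequencer and sd.
#' @param total_reads_mean Mean library size (reads) at depth factor 1.
#'
#' @details Default effect classes: chrY regions nearly closed in females;
#' one XIST-like chrX region at |log2FC| 4 (female-high, escaping
#' X-inactivation); autosomal sex DARs at |log2FC| 1.2; PBMC-memory regions
#' at |log2FC| 0.8; TCR-deletion regions depleted ~50x in T-cell-derived
#' samples; sequencer and FRiP technical regions; ancestry DARs at |log2FC|
#' 0.8; and a C9orf72-like cluster of 5 TSS-proximal regions at log2FC -0.6
#' in expansion carriers (the repeat-expansion signal spans a neighborhood
#' of the TSS rather than a single interval).
#'
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(
    n_cases = 170, n_controls = 30,
    n_regions = 5000, n_genes = 1000, seed = 1,
    female_fraction = 0.5, t_cell_fraction = 0.5,
    ancestry_fractions = c(EUR = 0.9, AFR = 0.1),
    sequencers = c("HiSeq4000", "NovaSeq6000"),
    c9_pos = max(2L, round(0.16 * n_cases)),
    batch_sizes = NULL, n_batches = 10,
    pbmc_missing_fraction = 0.1,
    slope_recorded_fraction = 1,
    confound_sex_case = 0,
    tss_region_fraction = 0.4,
    chrx_fraction = 0.05, chry_fraction = 0.01,
    baseline_log2 = c(mean = 5, sd = 1.5),
    nb_alpha0 = 0.05, nb_a1 = 3,
    dispersion_scatter_sd = 0.3,
    depth_factor_range = c(0.5, 2),
    effects = list(),
    progression = list(),
    coexpr = list(),
    rnip = list(female_rate = 0.04, male_rate = 0.02),
    frip_by_sequencer = c(0.45, 0.60), frip_sd = 0.05,
    total_reads_mean = 2e7) {
  eff_default <- list(
    n_sex_autosomal = 30, sex_autosomal_lfc = 1.2,
    xist_lfc = 4,
    chry_female_depletion = 2^-6,
    n_pbmc_memory = 40, pbmc_memory_lfc = 0.8,
    n_tcr = 20, tcr_depletion = 0.02,
    n_sequencer = 30, sequencer_lfc = 0.6,
    n_frip = 30, frip_coef = 6,
    n_ancestry = 15, ancestry_lfc = 0.8,
    n_c9 = 5, c9_lfc = -0.6
  )
  prog_default <- list(
    n_drivers = 25, factor_loading = 0.4, coef_scale = 0.035,
    noise_sd = 0.2, mean_slope = -0.7,
    n_corr_outliers = 0, n_slope_outliers = 0, slope_outlier_shift = 8
  )
  coexpr_default <- list(
    n_links = 60, n_dual = 5, slope = 1, negative_fraction = 1 / 3,
    noise_sd = 0.5
  )
  cfg <- list(
    n_cases = as.integer(n_cases), n_controls = as.integer(n_controls),
    n_samples = as.integer(n_cases + n_controls),
    n_regions = as.integer(n_regions), n_genes = as.integer(n_genes),
    seed = as.integer(seed),
    female_fraction = female_fraction, t_cell_fraction = t_cell_fraction,
    ancestry_fractions = ancestry_fractions,
    sequencers = sequencers, c9_pos = as.integer(c9_pos),
    batch_sizes = batch_sizes, n_batches = as.integer(n_batches),
    pbmc_missing_fraction = pbmc_missing_fraction,
    slope_recorded_fraction = slope_recorded_fraction,
    confound_sex_case = confound_sex_case,
    tss_region_fraction = tss_region_fraction,
    chrx_fraction = chrx_fraction, chry_fraction = chry_fraction,
    baseline_log2 = baseline_log2,
    nb_alpha0 = nb_alpha0, nb_a1 = nb_a1,
    dispersion_scatter_sd = dispersion_scatter_sd,
    depth_factor_range = depth_factor_range,
    effects = utils::modifyList(eff_default, effects),
    progression = utils::modifyList(prog_default, progression),
    coexpr = utils::modifyList(coexpr_default, coexpr),
    rnip = rnip,
    frip_by_sequencer = frip_by_sequencer, frip_sd = frip_sd,
    total_reads_mean = total_reads_mean
  )
  validate_cohort_config(cfg)
  class(cfg) <- "cohort_config"
  cfg
}

validate_cohort_config <- function(cfg) {
  fr <- c(cfg$female_fraction, cfg$t_cell_fraction, cfg$pbmc_missing_fraction,
          cfg$slope_recorded_fraction, cfg$ancestry_fractions,
          cfg$tss_region_fraction, cfg$chrx_fraction, cfg$chry_fraction)
  if (any(fr < 0 | fr > 1)) abort_validation("config fractions must lie in [0, 1]")
  if (abs(sum(cfg$ancestry_fractions) - 1) > 1e-8) {
    abort_validation("ancestry_fractions must sum to 1")
  }
  if (cfg$n_cases < 0 || cfg$n_controls < 0 || cfg$n_samples < 2) {
    abort_validation("need at least 2 samples")
  }
  if (cfg$c9_pos > cfg$n_cases) abort_validation("c9_pos exceeds n_cases")
  if (!is.null(cfg$batch_sizes) && sum(cfg$batch_sizes) != cfg$n_samples) {
    abort_validation("batch_sizes must sum to n_cases + n_controls")
  }
  if (cfg$nb_alpha0 < 0 || cfg$nb_a1 < 0) {
    abort_validation("dispersion trend parameters must be >= 0")
  }
  invisible(cfg)
}

# exact-count categorical assignment: counts per level, seeded permutation
assign_levels <- function(levels, counts, n, seed) {
  counts <- round(counts)
  counts[length(counts)] <- n - sum(counts[-length(counts)])
  with_seed(seed, sample(rep(levels, times = counts)))
}

# deterministic region/gene layout: coordinates, chromosomes, and the
# disjoint region classes every planted effect draws from
simulate_layout <- function(cfg) {
  n <- cfg$n_regions
  n_y <- max(if (cfg$chry_fraction > 0) 2L else 0L, round(cfg$chry_fraction * n))
  n_x <- max(if (cfg$chrx_fraction > 0) 2L else 0L, round(cfg$chrx_fraction * n))
  n_auto <- n - n_y - n_x
  chrom <- c(rep("chrY", n_y), rep("chrX", n_x),
             paste0("chr", rep(1:22, length.out = n_auto)))
  # regions spaced 10 kb apart along each chromosome, width 500 bp
  start <- integer(n)
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    start[idx] <- 100000L + 10000L * (seq_along(idx) - 1L)
  }
  regions <- region_set(chrom, start, start + 500L,
                        sprintf("region_%05d", seq_len(n)))
  # region_set sorts; recover layout order by id
  regions <- regions[order(regions$region_id), , drop = FALSE]
  rownames(regions) <- NULL

  # TSS-proximal regions: each hosts one gene with TSS at the region center
  n_tss <- min(cfg$n_genes, round(cfg$tss_region_fraction * n))
  eligible <- which(regions$chrom != "chrY")
  tss_regions <- with_seed(derive_seed(cfg$seed, "layout_tss"),
                           sort(sample(eligible, n_tss)))
  centers <- region_centers(regions)
  strand_pool <- with_seed(derive_seed(cfg$seed, "layout_strand"),
                           sample(c("+", "-"), cfg$n_genes, replace = TRUE))
  genes <- data.frame(
    gene_id = sprintf("gene_%05d", seq_len(cfg$n_genes)),
    chrom = c(regions$chrom[tss_regions],
              rep("chr1", cfg$n_genes - n_tss)),
    tss = c(centers[tss_regions],
            # remaining genes parked far beyond any region
            1e8 + 10000 * seq_len(cfg$n_genes - n_tss)),
    strand = strand_pool,
    stringsAsFactors = FALSE
  )

  # disjoint effect-class region pools
  eff <- cfg$effects
  chry_idx <- which(regions$chrom == "chrY")
  chrx_idx <- which(regions$chrom == "chrX")
  auto_idx <- setdiff(seq_len(n), c(chry_idx, chrx_idx))
  auto_tss <- intersect(tss_regions, auto_idx)
  auto_nontss <- setdiff(auto_idx, tss_regions)

  pick <- local({
    pool_tss <- auto_tss
    pool_other <- auto_nontss
    counter <- 0L
    function(k, from_tss = FALSE) {
      counter <<- counter + 1L
      pool <- if (from_tss) pool_tss else pool_other
      if (k > length(pool)) abort_validation(
        "not enough free regions for planted effects (need %d)", k)
      sel <- with_seed(derive_seed(cfg$seed, paste0("pick", counter)),
                       sort(sample(pool, k)))
      if (from_tss) pool_tss <<- setdiff(pool_tss, sel)
      else pool_other <<- setdiff(pool_other, sel)
      sel
    }
  })

  classes <- list(
    chry = chry_idx,
    xist = if (length(chrx_idx)) chrx_idx[1] else integer(0),
    sex_autosomal = pick(eff$n_sex_autosomal),
    pbmc_memory = pick(eff$n_pbmc_memory),
    tcr = pick(eff$n_tcr),
    sequencer = pick(eff$n_sequencer),
    frip = pick(eff$n_frip),
    ancestry = pick(eff$n_ancestry),
    c9 = pick(eff$n_c9, from_tss = TRUE),
    driver = pick(cfg$progression$n_drivers, from_tss = TRUE)
  )
  list(regions = regions, genes = genes, tss_regions = tss_regions,
       classes = classes)
}

#' Simulate cohort sample metadata
#'
#' Group counts match the configuration exactly. The ALSFRS-R slope column
#' is left `NA` here: slopes are linear in measured driver-region
#' accessibility, which only exists after counts are drawn, so
#' [simulate_cohort()] fills them in a second pass.
#'
#' @param cfg A [cohort_config()].
#' @return A `data.frame`, one row per sample.
#' @export
simulate_metadata <- function(cfg) {
  validate_cohort_config(cfg)
  n <- cfg$n_samples
  sample_id <- sprintf("S%04d", seq_len(n))
  sex <- assign_levels(c("Female", "Male"),
                       c(round(cfg$female_fraction * n), 0), n,
                       derive_seed(cfg$seed, "sex"))
  if (cfg$confound_sex_case > 0) {
    # female-enriched cases: a fraction (0.5 + confound/2) of cases is female
    n_f_case <- round(cfg$n_cases * (0.5 + cfg$confound_sex_case / 2))
    n_f_case <- min(n_f_case, sum(sex == "Female"), cfg$n_cases)
    case_status <- rep("HC", n)
    f_idx <- which(sex == "Female"); m_idx <- which(sex == "Male")
    sel_f <- with_seed(derive_seed(cfg$seed, "case_f"),
                       sample(f_idx, n_f_case))
    sel_m <- with_seed(derive_seed(cfg$seed, "case_m"),
                       sample(m_idx, cfg$n_cases - n_f_case))
    case_status[c(sel_f, sel_m)] <- "ALS"
  } else {
    case_status <- assign_levels(c("ALS", "HC"), c(cfg$n_cases, 0), n,
                                 derive_seed(cfg$seed, "case"))
  }
  pbmc_true <- assign_levels(c("T-cell", "non-T-cell"),
                             c(round(cfg$t_cell_fraction * n), 0), n,
                             derive_seed(cfg$seed, "pbmc"))
  ancestry <- assign_levels(names(cfg$ancestry_fractions),
                            cfg$ancestry_fractions * n, n,
                            derive_seed(cfg$seed, "ancestry"))
  sequencer <- assign_levels(cfg$sequencers,
                             rep(n / length(cfg$sequencers), length(cfg$sequencers)),
                             n, derive_seed(cfg$seed, "sequencer"))
  # C9 expansion status among cases; controls verified negative
  c9_status <- rep("NEG", n)
  case_idx <- which(case_status == "ALS")
  pos_idx <- with_seed(derive_seed(cfg$seed, "c9"),
                       sample(case_idx, cfg$c9_pos))
  c9_status[pos_idx] <- "POS"
  # differentiation batches assigned in sequence over a seeded permutation
  sizes <- cfg$batch_sizes
  if (is.null(sizes)) {
    base <- n %/% cfg$n_batches
    sizes <- rep(base, cfg$n_batches)
    extra <- n - sum(sizes)
    if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  }
  batch_labels <- rep(sprintf("batch%02d", seq_along(sizes)), times = sizes)
  diff_batch <- character(n)
  diff_batch[with_seed(derive_seed(cfg$seed, "batch"), sample.int(n))] <- batch_labels
  frip_mean <- cfg$frip_by_sequencer[match(sequencer, cfg$sequencers)]
  frip <- with_seed(derive_seed(cfg$seed, "frip"),
                    pmin(0.95, pmax(0.05, stats::rnorm(n, frip_mean, cfg$frip_sd))))
  pbmc_type <- pbmc_true
  n_miss <- round(cfg$pbmc_missing_fraction * n)
  miss_idx <- with_seed(derive_seed(cfg$seed, "pbmc_miss"), sample.int(n, n_miss))
  pbmc_type[miss_idx] <- NA_character_
  onset <- with_seed(derive_seed(cfg$seed, "onset"), stats::runif(n, 1, 10))
  onset[case_status == "HC"] <- NA_real_
  data.frame(
    sample_id = sample_id, sex = sex, pbmc_type = pbmc_type,
    sequencer = sequencer, frip = frip, diff_batch = diff_batch,
    ancestry = ancestry, case_status = case_status, c9_status = c9_status,
    alsfrs_r_slope = NA_real_, onset_to_collection_years = onset,
    total_reads = NA_real_, chrx_reads = NA_real_,
    chrx_reads_in_peaks = NA_real_,
    stringsAsFactors = FALSE
  )
}

#' Simulate the fragment-count matrix and ground truth
#'
#' Counts are `K_ij ~ NB(mean = s_j * q_ij, dispersion alpha_i)` with
#' `log2 q_ij = b_i + sum of planted effects(covariates of sample j)` and
#' `alpha_i` following the trend `alpha(mu) = a1/mu + alpha0` with lognormal
#' scatter. Planted correlation-outlier samples have their baseline profile
#' permuted across regions, decorrelating them from the cohort.
#'
#' @param cfg A [cohort_config()].
#' @param metadata Output of [simulate_metadata()].
#' @return A list: `counts` (integer matrix), `truth` (ground-truth ledger),
#'   `regions`, `genes`.
#' @export
simulate_counts <- function(cfg, metadata) {
  lay <- simulate_layout(cfg)
  n <- cfg$n_samples; m <- cfg$n_regions
  eff <- cfg$effects
  cls <- lay$classes

  b <- with_seed(derive_seed(cfg$seed, "baseline"),
                 stats::rnorm(m, cfg$baseline_log2[["mean"]], cfg$baseline_log2[["sd"]]))
  # keep planted-effect regions comfortably away from zero counts so their
  # fold changes are identifiable
  special <- unlist(cls[c("sex_autosomal", "pbmc_memory", "sequencer", "frip",
                          "ancestry", "c9", "driver", "xist", "tcr")])
  b[special] <- pmax(b[special], 5)
  # the C9-like cluster sits at a strong promoter: high baseline counts,
  # as for the highly accessible TSS such repeat-expansion signals occupy
  b[cls$c9] <- pmax(b[cls$c9], 8)

  female <- metadata$sex == "Female"
  tcell_true <- assigned_pbmc_truth(cfg, metadata)
  seq2 <- metadata$sequencer == cfg$sequencers[min(2, length(cfg$sequencers))]
  afr <- metadata$ancestry == names(cfg$ancestry_fractions)[min(2, length(cfg$ancestry_fractions))]
  c9pos <- metadata$c9_status == "POS"
  frip_c <- metadata$frip - mean(metadata$frip)

  log2q <- matrix(b, nrow = m, ncol = n)
  add_lfc <- function(idx, lfc_mag, indicator, signs_seed) {
    if (!length(idx)) return(NULL)
    signs <- with_seed(derive_seed(cfg$seed, signs_seed),
                       sample(c(-1, 1), length(idx), replace = TRUE))
    log2q[idx, indicator] <<- log2q[idx, indicator] + signs * lfc_mag
    signs * lfc_mag
  }
  lfc_sex <- add_lfc(cls$sex_autosomal, eff$sex_autosomal_lfc, female, "sgn_sex")
  lfc_mem <- add_lfc(cls$pbmc_memory, eff$pbmc_memory_lfc, tcell_true, "sgn_mem")
  lfc_seq <- add_lfc(cls$sequencer, eff$sequencer_lfc, seq2, "sgn_seq")
  lfc_anc <- add_lfc(cls$ancestry, eff$ancestry_lfc, afr, "sgn_anc")
  if (length(cls$xist)) log2q[cls$xist, female] <- log2q[cls$xist, female] + eff$xist_lfc
  if (length(cls$tcr)) {
    log2q[cls$tcr, tcell_true] <- log2q[cls$tcr, tcell_true] + log2(eff$tcr_depletion)
  }
  if (length(cls$chry)) {
    log2q[cls$chry, female] <- log2q[cls$chry, female] + log2(eff$chry_female_depletion)
  }
  log2q[cls$c9, c9pos] <- log2q[cls$c9, c9pos] + eff$c9_lfc
  # progression drivers: a co-regulated module sharing a latent per-sample
  # progression factor (log2-scale loading, sign per driver)
  prog_factor <- with_seed(derive_seed(cfg$seed, "latent_prog"),
                           stats::rnorm(n))
  if (length(cls$driver)) {
    sgn <- driver_signs(cfg)
    log2q[cls$driver, ] <- log2q[cls$driver, ] +
      (sgn * cfg$progression$factor_loading) %o% prog_factor
  }
  if (length(cls$frip)) {
    log2q[cls$frip, ] <- log2q[cls$frip, ] +
      eff$frip_coef * matrix(frip_c, nrow = length(cls$frip), ncol = n, byrow = TRUE)
  }

  # planted correlation outliers: permute the expected profile per sample
  co_ids <- planted_outlier_ids(cfg, metadata)
  for (j in which(metadata$sample_id %in% co_ids$corr)) {
    perm <- with_seed(derive_seed(cfg$seed, paste0("corrout", j)), sample.int(m))
    log2q[, j] <- log2q[perm, j]
  }

  s <- with_seed(derive_seed(cfg$seed, "depth"),
                 stats::runif(n, cfg$depth_factor_range[1], cfg$depth_factor_range[2]))
  q <- 2^log2q
  qbar <- rowMeans(q)
  scatter <- with_seed(derive_seed(cfg$seed, "disp"),
                       exp(stats::rnorm(m, 0, cfg$dispersion_scatter_sd)))
  alpha <- pmax(1e-8, (cfg$nb_a1 / qbar + cfg$nb_alpha0) * scatter)
  mu <- sweep(q, 2, s, "*")
  counts <- with_seed(
    derive_seed(cfg$seed, "counts"),
    matrix(stats::rnbinom(m * n, mu = as.vector(mu), size = rep(1 / alpha, n)),
           nrow = m, ncol = n)
  )
  rownames(counts) <- lay$regions$region_id
  colnames(counts) <- metadata$sample_id

  effect_ledger <- rbind(
    effect_rows(lay, cls$sex_autosomal, "sex_autosomal", "Female_vs_Male", lfc_sex),
    effect_rows(lay, cls$xist, "xist_escape", "Female_vs_Male", rep(eff$xist_lfc, length(cls$xist))),
    effect_rows(lay, cls$chry, "chry", "Female_vs_Male",
                rep(log2(eff$chry_female_depletion), length(cls$chry))),
    effect_rows(lay, cls$pbmc_memory, "pbmc_memory", "Tcell_vs_nonTcell", lfc_mem),
    effect_rows(lay, cls$tcr, "tcr_deletion", "Tcell_vs_nonTcell",
                rep(log2(eff$tcr_depletion), length(cls$tcr))),
    effect_rows(lay, cls$sequencer, "sequencer", "seq2_vs_seq1", lfc_seq),
    effect_rows(lay, cls$frip, "frip", "per_unit_frip",
                rep(eff$frip_coef, length(cls$frip))),
    effect_rows(lay, cls$ancestry, "ancestry", "AFR_vs_EUR", lfc_anc),
    effect_rows(lay, cls$c9, "c9_promoter", "C9POS_vs_C9NEG",
                rep(eff$c9_lfc, length(cls$c9)))
  )
  truth <- list(
    classes = cls,
    effects = effect_ledger,
    size_factors = stats::setNames(s, metadata$sample_id),
    dispersions = stats::setNames(alpha, lay$regions$region_id),
    baseline_log2 = stats::setNames(b, lay$regions$region_id),
    pbmc_true = stats::setNames(tcell_true, metadata$sample_id),
    corr_outliers = co_ids$corr,
    slope_outliers = co_ids$slope,
    progression_factor = stats::setNames(prog_factor, metadata$sample_id),
    tss_regions = lay$regions$region_id[lay$tss_regions]
  )
  list(counts = counts, truth = truth, regions = lay$regions, genes = lay$genes)
}

effect_rows <- function(lay, idx, class, contrast, lfc) {
  if (!length(idx)) return(NULL)
  data.frame(region_id = lay$regions$region_id[idx], class = class,
             contrast = contrast, log2fc = lfc, stringsAsFactors = FALSE)
}

# true T-cell indicator (independent of injected missingness)
assigned_pbmc_truth <- function(cfg, metadata) {
  truth <- assign_levels(c("T-cell", "non-T-cell"),
                         c(round(cfg$t_cell_fraction * cfg$n_samples), 0),
                         cfg$n_samples, derive_seed(cfg$seed, "pbmc"))
  truth == "T-cell"
}

# which samples are planted as correlation / slope outliers: drawn from the
# largest differentiation batch among slope-recorded cases, so the filter
# ground truths stay disjoint from the small-batch exclusions
planted_outlier_ids <- function(cfg, metadata) {
  pr <- cfg$progression
  n_co <- pr$n_corr_outliers; n_so <- pr$n_slope_outliers
  if (n_co + n_so == 0) return(list(corr = character(0), slope = character(0)))
  rec <- slope_recorded_ids(cfg, metadata)
  cand <- metadata[metadata$sample_id %in% rec, , drop = FALSE]
  tab <- sort(table(cand$diff_batch), decreasing = TRUE)
  big <- names(tab)[1]
  pool <- cand$sample_id[cand$diff_batch == big]
  if (length(pool) < n_co + n_so) {
    abort_validation("largest batch too small to host %d planted outliers", n_co + n_so)
  }
  sel <- with_seed(derive_seed(cfg$seed, "planted_outliers"),
                   sample(pool, n_co + n_so))
  list(corr = sel[seq_len(n_co)],
       slope = if (n_so > 0) sel[n_co + seq_len(n_so)] else character(0))
}

# driver sign per region: the direction in which the latent progression
# factor moves the region, matched to the sign of its slope coefficient
driver_signs <- function(cfg) {
  with_seed(derive_seed(cfg$seed, "driver_sign"),
            sample(c(-1, 1), cfg$progression$n_drivers, replace = TRUE))
}

slope_recorded_ids <- function(cfg, metadata) {
  cases <- metadata$sample_id[metadata$case_status == "ALS"]
  k <- round(cfg$slope_recorded_fraction * length(cases))
  with_seed(derive_seed(cfg$seed, "slope_recorded"), sample(cases, k))
}

#' Simulate a gene-by-sample normalized expression matrix
#'
#' Linked genes follow `expression = slope * z(accessibility) + noise`,
#' where `z(accessibility)` is the linked region's log2 normalized
#' accessibility standardized across samples; unlinked genes are pure
#' Gaussian noise. Some peaks are linked to two genes with opposite signs
#' (dual-sign peaks). The matrix is on the normalized (log-like) scale the
#' co-expression module consumes.
#'
#' @param cfg A [cohort_config()].
#' @param sim Output of [simulate_counts()].
#' @return A list: `expression` (matrix), `links` (data.frame of planted
#'   peak-gene links with slopes and center-to-TSS distances).
#' @export
simulate_expression <- function(cfg, sim) {
  cx <- cfg$coexpr
  genes <- sim$genes; regions <- sim$regions
  n <- ncol(sim$counts)
  centers <- region_centers(regions)
  a_norm <- log2(sweep(sim$counts, 2, sim$truth$size_factors, "/") + 1)

  # candidate (gene, region) pairs within 250 kb used for planting
  window <- 250000
  cand_regions <- function(g) {
    which(regions$chrom == genes$chrom[g] & abs(centers - genes$tss[g]) <= window)
  }
  n_real <- sum(genes$tss < 5e7)  # genes anchored at region TSSs
  links <- with_seed(derive_seed(cfg$seed, "links"), {
    gsel <- sample(seq_len(n_real), min(cx$n_links, n_real))
    out <- lapply(gsel, function(g) {
      rs <- cand_regions(g)
      if (!length(rs)) return(NULL)
      r <- sample(rs, 1)
      sgn <- if (stats::runif(1) < cx$negative_fraction) -1 else 1
      data.frame(gene = g, region = r, slope = sgn * cx$slope)
    })
    do.call(rbind, out)
  })
  # dual-sign peaks: one region linked + to one gene and - to another
  dual <- with_seed(derive_seed(cfg$seed, "dual"), {
    out <- NULL
    pool_g <- setdiff(seq_len(n_real), links$gene)
    for (k in seq_len(cx$n_dual)) {
      if (length(pool_g) < 2) break
      g1 <- sample(pool_g, 1)
      rs <- cand_regions(g1)
      rs <- setdiff(rs, links$region)
      if (!length(rs)) next
      r <- sample(rs, 1)
      # second gene within window of the same region center
      g2 <- setdiff(which(genes$chrom == regions$chrom[r] &
                            abs(genes$tss - centers[r]) <= window), c(g1, links$gene))
      g2 <- intersect(g2, pool_g)
      if (!length(g2)) next
      g2 <- sample(g2, 1)
      out <- rbind(out,
                   data.frame(gene = g1, region = r, slope = cx$slope),
                   data.frame(gene = g2, region = r, slope = -cx$slope))
      pool_g <- setdiff(pool_g, c(g1, g2))
    }
    out
  })
  links <- rbind(links, dual)
  links <- links[!duplicated(links[c("gene", "region")]), , drop = FALSE]

  expr <- with_seed(derive_seed(cfg$seed, "expr_noise"),
                    matrix(stats::rnorm(cfg$n_genes * n, 0, 1),
                           nrow = cfg$n_genes, ncol = n))
  noise <- with_seed(derive_seed(cfg$seed, "link_noise"),
                     matrix(stats::rnorm(nrow(links) * n, 0, cx$noise_sd),
                            nrow = nrow(links)))
  for (k in seq_len(nrow(links))) {
    a <- a_norm[links$region[k], ]
    z <- (a - mean(a)) / stats::sd(a)
    expr[links$gene[k], ] <- links$slope[k] * z + noise[k, ]
  }
  rownames(expr) <- genes$gene_id
  colnames(expr) <- colnames(sim$counts)
  links_out <- data.frame(
    gene_id = genes$gene_id[links$gene],
    region_id = regions$region_id[links$region],
    slope = links$slope,
    distance = centers[links$region] - genes$tss[links$gene],
    stringsAsFactors = FALSE
  )
  list(expression = expr, links = links_out)
}

#' Simulate a complete synthetic cohort
#'
#' Runs the two-pass generation: metadata, counts (with planted effects and
#' ground truth), ALSFRS-R slopes linear in measured driver accessibility,
#' read-total bookkeeping for the chrX reads-not-in-peaks statistic, and the
#' expression matrix with planted peak-gene links.
#'
#' @param cfg A [cohort_config()].
#' @return A `synthetic_cohort` list with elements `config`, `metadata`,
#'   `regions`, `genes`, `counts`, `expression`, `truth`.
#' @export
simulate_cohort <- function(cfg) {
  md <- simulate_metadata(cfg)
  sim <- simulate_counts(cfg, md)
  truth <- sim$truth
  pr <- cfg$progression

  # second pass: ALSFRS-R slope linear in measured driver accessibility
  drv <- truth$classes$driver
  a <- log2(sweep(sim$counts[drv, , drop = FALSE], 2, truth$size_factors, "/") + 1)
  az <- t(scale(t(a)))
  beta <- driver_signs(cfg) *
    with_seed(derive_seed(cfg$seed, "driver_beta"),
              stats::runif(length(drv), 0.8, 1.2)) * pr$coef_scale
  score <- as.numeric(crossprod(az, beta))
  eps <- with_seed(derive_seed(cfg$seed, "slope_noise"),
                   stats::rnorm(cfg$n_samples, 0, pr$noise_sd))
  raw <- score + eps
  # light winsorization keeps the planted slope outliers the only samples
  # outside the 1.5-IQR fences
  lim <- 2.4 * stats::sd(raw)
  raw <- pmin(pmax(raw, -lim), lim)
  slope <- pr$mean_slope + raw
  rec <- slope_recorded_ids(cfg, md)
  md$alsfrs_r_slope <- ifelse(md$sample_id %in% rec, slope, NA_real_)
  so <- truth$slope_outliers
  if (length(so)) {
    sgn <- with_seed(derive_seed(cfg$seed, "so_sign"),
                     sample(c(-1, 1), length(so), replace = TRUE))
    md$alsfrs_r_slope[match(so, md$sample_id)] <-
      pr$mean_slope + sgn * pr$slope_outlier_shift
  }
  normal <- md$sample_id %in% rec &
    !(md$sample_id %in% c(so, truth$corr_outliers))
  truth$progression <- list(
    driver_region_ids = rownames(sim$counts)[drv],
    beta = stats::setNames(beta, rownames(sim$counts)[drv]),
    noise_sd = pr$noise_sd, mean_slope = pr$mean_slope,
    r2_true = 1 - stats::var(md$alsfrs_r_slope[normal] -
                               (pr$mean_slope + score[normal])) /
      stats::var(md$alsfrs_r_slope[normal])
  )

  # read totals: chrX in-peak reads from the counts, chrX background at the
  # per-sex planted rate
  s <- truth$size_factors
  total <- round(cfg$total_reads_mean * s / mean(s))
  chrx_rows <- sim$regions$chrom == "chrX"
  in_peaks <- colSums(sim$counts[chrx_rows, , drop = FALSE])
  rate <- ifelse(md$sex == "Female", cfg$rnip$female_rate, cfg$rnip$male_rate)
  bg <- with_seed(derive_seed(cfg$seed, "rnip"),
                  round(rate * total * exp(stats::rnorm(cfg$n_samples, 0, 0.05))))
  md$total_reads <- total
  md$chrx_reads_in_peaks <- in_peaks
  md$chrx_reads <- in_peaks + bg
  stopifnot(all(md$chrx_reads <= md$total_reads))

  ex <- simulate_expression(cfg, sim)
  truth$links <- ex$links
  structure(
    list(config = cfg, metadata = md, regions = sim$regions,
         genes = sim$genes, counts = sim$counts,
         expression = ex$expression, truth = truth),
    class = "synthetic_cohort"
  )
}

#' Study-scale progression benchmark configuration
#'
#' A cohort of 242 slope-recorded ALS cases mirroring the predictor's
#' filter cascade: 12 planted decorrelated samples, 6 planted slope
#' outliers, and 68 samples in differentiation batches of fewer than 4,
#' leaving 156 retained samples that split 140/16. Twenty-five driver
#' regions are planted among roughly 2,000 TSS-proximal regions.
#'
#' @param seed Master seed.
#' @return A [cohort_config()].
#' @export
progression_benchmark_config <- function(seed = 1) {
  batch_sizes <- c(26L, rep(10L, 14), 8L, rep(3L, 22), 2L)
  stopifnot(sum(batch_sizes) == 242L)
  cohort_config(
    n_cases = 242, n_controls = 0,
    n_regions = 3000, n_genes = 2100, seed = seed,
    tss_region_fraction = 0.67,
    batch_sizes = batch_sizes,
    pbmc_missing_fraction = 0,
    progression = list(n_corr_outliers = 12, n_slope_outliers = 6),
    coexpr = list(n_links = 20, n_dual = 2)
  )
}

#' Write a synthetic cohort fixture bundle to a directory
#'
#' Emits `regions.bed`, `genes.tsv`, `counts.tsv`, `expression.tsv`,
#' `metadata.tsv`, ground-truth TSVs and a YAML snapshot of the
#' configuration.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_regions_bed(cohort$regions, file.path(dir, "regions.bed"))
  write_gene_table(cohort$genes, file.path(dir, "genes.tsv"))
  write_counts(cohort$counts, file.path(dir, "counts.tsv"))
  expr <- cohort$expression
  dt <- cbind(data.table::data.table(gene_id = rownames(expr)),
              data.table::as.data.table(expr))
  data.table::fwrite(dt, file.path(dir, "expression.tsv"), sep = "\t")
  data.table::fwrite(cohort$metadata, file.path(dir, "metadata.tsv"), sep = "\t")
  data.table::fwrite(cohort$truth$effects, file.path(dir, "truth_effects.tsv"), sep = "\t")
  data.table::fwrite(cohort$truth$links, file.path(dir, "truth_links.tsv"), sep = "\t")
  drv <- cohort$truth$progression
  data.table::fwrite(
    data.frame(region_id = drv$driver_region_ids, beta = unname(drv$beta)),
    file.path(dir, "truth_drivers.tsv"), sep = "\t"
  )
  cfg <- cohort$config
  class(cfg) <- NULL
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  invisible(dir)
}
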