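#' Simulation configuration
#'
#' Parameters of the paired genotype + ROI-time-series generator. Defaults
#' emulate a two-group imaging-genetics cohort: 37 patients (label -1) and 35
#' controls (+1), 90 atlas regions, 36 genes each spanning 40-50 chip SNPs,
#' 140-timepoint region series, common minor allele frequencies (0.1-0.5),
#' low per-call missingness as on modern genotyping chips, and unit-variance
#' region noise. `planted_couplings` lists (region index, gene index, effect
#' size) triples: in the patient group only, that region's series is a
#' noisy affine image of the subject's encoded gene sequence, which is the
#' discriminative signal the fusion features are designed to pick up.
#'
#' @param n_ad,n_nc subjects per group (>= 2 each).
#' @param n_regions number of atlas regions (default 90).
#' @param n_genes number of simulated genes.
#' @param snps_per_gene integer range `c(min, max)` of SNPs per gene.
#' @param n_timepoints region time-series length.
#' @param planted_couplings list of `c(region, gene, effect)` triples with
#'   effect in `[0, 1]`.
#' @param maf_range true minor-allele-frequency range, within (0, 0.5].
#' @param missing_rate per-call missingness fraction in `[0, 1)`.
#' @param hwe_violation_genes gene indices whose SNPs get excess
#'   homozygosity (inbreeding coefficient 0.5), violating Hardy-Weinberg.
#' @param noise_sd standard deviation of region-series noise.
#' @param seed master RNG seed for the generator.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_ad = 37, n_nc = 35, n_regions = 90, n_genes = 36,
                       snps_per_gene = c(40, 50), n_timepoints = 140,
                       planted_couplings = list(), maf_range = c(0.1, 0.5),
                       missing_rate = 0.001, hwe_violation_genes = integer(),
                       noise_sd = 1, seed = 1L) {
  stopifnot(n_ad >= 2, n_nc >= 2, n_regions >= 1, n_genes >= 1,
            length(snps_per_gene) == 2, snps_per_gene[1] >= 1,
            snps_per_gene[1] <= snps_per_gene[2],
            n_timepoints >= 1,
            length(maf_range) == 2, maf_range[1] > 0,
            maf_range[1] <= maf_range[2], maf_range[2] <= 0.5,
            missing_rate >= 0, missing_rate < 1, noise_sd > 0)
  planted_couplings <- lapply(planted_couplings, function(p) {
    p <- as.numeric(p)
    if (length(p) != 3) stop("each planted coupling is (region, gene, effect)")
    if (p[1] < 1 || p[1] > n_regions) stop("planted region index out of bounds")
    if (p[2] < 1 || p[2] > n_genes) stop("planted gene index out of bounds")
    if (p[3] < 0 || p[3] > 1) stop("effect size must be in [0, 1]")
    list(region = as.integer(p[1]), gene = as.integer(p[2]), effect = p[3])
  })
  if (length(hwe_violation_genes) > 0) {
    stopifnot(all(hwe_violation_genes >= 1), all(hwe_violation_genes <= n_genes))
  }
  structure(list(n_ad = as.integer(n_ad), n_nc = as.integer(n_nc),
                 n_regions = as.integer(n_regions),
                 n_genes = as.integer(n_genes),
                 snps_per_gene = as.integer(snps_per_gene),
                 n_timepoints = as.integer(n_timepoints),
                 planted_couplings = planted_couplings,
                 maf_range = as.numeric(maf_range),
                 missing_rate = missing_rate,
                 hwe_violation_genes = as.integer(hwe_violation_genes),
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "sim_config")
}

sim_gene_ids <- function(n) sprintf("gene_%02d", seq_len(n))

sim_subject_ids <- function(config) {
  c(sprintf("AD_%03d", seq_len(config$n_ad)),
    sprintf("NC_%03d", seq_len(config$n_nc)))
}

#' Generate a synthetic genotype table
#'
#' Each SNP gets two distinct nucleotide alleles and a true minor allele
#' frequency drawn uniformly from `maf_range`. Genotypes follow
#' Hardy-Weinberg proportions except for SNPs of `hwe_violation_genes`,
#' which get excess homozygosity with inbreeding coefficient F = 0.5
#' (P(het) shrinks by half, the deficit moving to the homozygotes). Missing
#' calls are injected uniformly at `missing_rate`.
#'
#' @param config a [sim_config()].
#' @return List with `table` (a [genotype_table()]) and `truth` (config echo,
#'   per-SNP true MAF, planted couplings, per-subject labels, and the derived
#'   seed for the ROI stage).
#' @export
generate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  seed_geno <- sample.int(.Machine$integer.max, 1)
  seed_roi <- sample.int(.Machine$integer.max, 1)
  set.seed(seed_geno)

  gene_ids <- sim_gene_ids(config$n_genes)
  counts <- sample(seq(config$snps_per_gene[1], config$snps_per_gene[2]),
                   config$n_genes, replace = TRUE)
  if (any(counts == 0)) stop("a gene would have zero SNPs")
  n_snp <- sum(counts)
  gene_of <- rep(seq_len(config$n_genes), counts)
  snps <- data.frame(
    snp_id = sprintf("snp_%06d", seq_len(n_snp)),
    chrom = (gene_of - 1L) %% 22L + 1L,
    pos = unlist(lapply(seq_len(config$n_genes),
                        function(g) g * 10^6 + 1000L * seq_len(counts[g]))),
    gene_id = gene_ids[gene_of],
    stringsAsFactors = FALSE)
  pair <- vapply(seq_len(n_snp), function(i) sample(c("A", "C", "G", "T"), 2),
                 character(2))
  snps$allele_a <- pair[1, ]   # major allele
  snps$allele_b <- pair[2, ]   # minor allele
  true_maf <- stats::runif(n_snp, config$maf_range[1], config$maf_range[2])

  n <- config$n_ad + config$n_nc
  labels <- c(rep(-1, config$n_ad), rep(1, config$n_nc))
  subject_ids <- sim_subject_ids(config)

  viol <- gene_of %in% config$hwe_violation_genes
  p <- true_maf
  f_in <- ifelse(viol, 0.5, 0)
  p_bb <- p^2 + f_in * p * (1 - p)
  p_ab <- 2 * p * (1 - p) * (1 - f_in)
  # draw minor-allele dosage per call; column-wise per SNP
  u <- matrix(stats::runif(n * n_snp), n, n_snp)
  thr1 <- matrix(p_bb, n, n_snp, byrow = TRUE)
  thr2 <- matrix(p_bb + p_ab, n, n_snp, byrow = TRUE)
  dosage <- (u < thr1) + (u < thr2)   # 2 = hom minor, 1 = het, 0 = hom major
  amat <- matrix(snps$allele_a, n, n_snp, byrow = TRUE)
  bmat <- matrix(snps$allele_b, n, n_snp, byrow = TRUE)
  a1 <- ifelse(dosage == 2, bmat, amat)
  a2 <- ifelse(dosage >= 1, bmat, amat)
  if (config$missing_rate > 0) {
    miss <- matrix(stats::runif(n * n_snp) < config$missing_rate, n, n_snp)
    a1[miss] <- NA_character_
    a2[miss] <- NA_character_
  }
  table <- genotype_table(subject_ids, snps, a1, a2)
  truth <- structure(list(config = config, true_maf = stats::setNames(true_maf, snps$snp_id),
                          planted_couplings = config$planted_couplings,
                          labels = stats::setNames(labels, subject_ids),
                          seed_roi = seed_roi),
                     class = "sim_truth")
  list(table = table, truth = truth)
}

#' Generate ROI time series with planted region-gene couplings
#'
#' Baseline series are i.i.d. Gaussian noise with `noise_sd`. For each
#' planted coupling (r, g, e), each patient's (label -1) region-r series has
#' its first L points replaced by `e * standardize(code) + (1 - e) * noise`,
#' where `code` is that subject's digitally encoded gene-g sequence as the
#' downstream pipeline will compute it (default QC thresholds, major-allele
#' policy, common segment length L). Controls and uncoupled regions stay pure
#' noise, so the group difference in the fusion feature is the only signal.
#'
#' @param config a [sim_config()].
#' @param table the genotype table from [generate_genotypes()].
#' @param truth its companion truth object.
#' @return A [roi_series()]; attribute `encoded` carries the internally
#'   computed `encoded_genes` used for planting.
#' @export
generate_roi_series <- function(config, table, truth) {
  stopifnot(inherits(config, "sim_config"), inherits(table, "genotype_table"))
  qc <- apply_qc(table, qc_thresholds())
  groups <- group_by_gene(qc$table, min_snps = 30)
  if (length(groups) == 0) stop("no gene survived QC; cannot plant couplings")
  encoded <- encode_genes(segment_to_length(groups, qc$table,
                                            policy = "major_allele"))
  L <- encoded$L
  if (config$n_timepoints < L) {
    stop(sprintf("n_timepoints (%d) is shorter than the gene segment length L = %d",
                 config$n_timepoints, L))
  }
  set.seed(truth$seed_roi)
  n <- length(table$subject_ids)
  series <- array(stats::rnorm(n * config$n_regions * config$n_timepoints,
                               sd = config$noise_sd),
                  dim = c(n, config$n_regions, config$n_timepoints))
  gene_ids <- sim_gene_ids(config$n_genes)
  kept_subj <- match(encoded$subject_ids, table$subject_ids)
  ad_rows <- which(truth$labels[encoded$subject_ids] == -1)
  # couplings sharing a region superpose: the region's planted segment is the
  # sum of the effect-weighted standardized codes, with the noise term
  # weighted by (1 - max effect); a single coupling reduces to
  # e * z + (1 - e) * noise exactly
  by_region <- split(config$planted_couplings,
                     vapply(config$planted_couplings, `[[`, integer(1), "region"))
  for (pcs in by_region) {
    r <- pcs[[1]]$region
    e_max <- max(vapply(pcs, `[[`, numeric(1), "effect"))
    for (s in ad_rows) {
      signal <- numeric(L)
      for (pc in pcs) {
        gid <- gene_ids[pc$gene]
        if (!gid %in% names(encoded$codes)) {
          stop("planted gene ", gid, " did not survive QC/grouping; ",
               "increase its SNP count or relax the configuration")
        }
        code <- as.numeric(encoded$codes[[gid]][s, ])
        sdc <- stats::sd(code)
        if (sdc == 0) {
          warning("constant encoded sequence for ", gid,
                  "; coupling left unplanted for one subject")
          next
        }
        signal <- signal + pc$effect * (code - mean(code)) / sdc
      }
      series[kept_subj[s], r, seq_len(L)] <-
        signal + (1 - e_max) * stats::rnorm(L, sd = config$noise_sd)
    }
  }
  region_names <- if (config$n_regions == 90) aal90_regions() else
    sprintf("Region_%03d", seq_len(config$n_regions))
  out <- roi_series(table$subject_ids, region_names, series)
  attr(out, "encoded") <- encoded
  out
}

#' Generate a complete paired dataset
#'
#' @param config a [sim_config()].
#' @return List of class `sim_dataset` with `genotypes`, `roi`, `truth`.
#' @export
simulate_dataset <- function(config) {
  g <- generate_genotypes(config)
  roi <- generate_roi_series(config, g$table, g$truth)
  structure(list(genotypes = g$table, roi = roi, truth = g$truth),
            class = "sim_dataset")
}
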