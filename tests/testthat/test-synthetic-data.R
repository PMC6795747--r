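test_that("configuration invariants are enforced", {
  expect_error(sim_config(n_ad = 1), "n_ad")
  expect_error(sim_config(planted_couplings = list(c(99, 1, 0.5)),
                          n_regions = 10), "out of bounds")
  expect_error(sim_config(planted_couplings = list(c(1, 1, 1.5))), "effect")
  expect_error(sim_config(maf_range = c(0.3, 0.2)))
  expect_error(sim_config(snps_per_gene = c(0, 5)))
})

test_that("no injected missingness gives call rate one everywhere", {
  sim <- generate_genotypes(sim_config(n_ad = 5, n_nc = 5, n_genes = 3,
                                       snps_per_gene = c(5, 8),
                                       missing_rate = 0, seed = 2))
  expect_true(all(sample_call_rate(sim$table) == 1))
  expect_true(all(snp_call_rate(sim$table) == 1))
})

test_that("realized allele frequency converges to the configured MAF", {
  # one SNP, many subjects: binomial bound 0.25 +/- 0.02 by direct counting
  cfg <- sim_config(n_ad = 5000, n_nc = 5000, n_regions = 1, n_genes = 1,
                    snps_per_gene = c(1, 1), maf_range = c(0.25, 0.25),
                    missing_rate = 0, seed = 9)
  sim <- generate_genotypes(cfg)
  b <- sim$table$snps$allele_b[1]
  realized <- (sum(sim$table$a1 == b) + sum(sim$table$a2 == b)) / 20000
  expect_lt(abs(realized - 0.25), 0.02)
})

test_that("generation is deterministic under a fixed seed", {
  cfg <- sim_config(n_ad = 6, n_nc = 6, n_regions = 5, n_genes = 3,
                    snps_per_gene = c(32, 34),
                    planted_couplings = list(c(2, 1, 0.7)), seed = 123)
  d1 <- simulate_dataset(cfg)
  d2 <- simulate_dataset(cfg)
  expect_identical(d1$genotypes, d2$genotypes)
  expect_identical(d1$roi$series, d2$roi$series)
  expect_identical(d1$truth$true_maf, d2$truth$true_maf)
})

test_that("labels cover every subject with values in {-1, +1}", {
  sim <- generate_genotypes(sim_config(n_ad = 7, n_nc = 4, n_genes = 2,
                                       snps_per_gene = c(3, 5), seed = 1))
  expect_length(sim$truth$labels, 11)
  expect_setequal(unique(sim$truth$labels), c(-1, 1))
  expect_equal(names(sim$truth$labels), sim$table$subject_ids)
})

test_that("HWE-violating genes show excess homozygosity detectable at 1e-4", {
  cfg <- sim_config(n_ad = 36, n_nc = 36, n_genes = 2,
                    snps_per_gene = c(31, 31), maf_range = c(0.3, 0.5),
                    missing_rate = 0, hwe_violation_genes = 2L, seed = 21)
  sim <- generate_genotypes(cfg)
  gc <- genotype_counts(sim$table)
  pv <- vapply(seq_len(nrow(gc)),
               function(i) hwe_exact_test(gc[i, 1], gc[i, 2], gc[i, 3]),
               numeric(1))
  viol <- sim$table$snps$gene_id == "gene_02"
  # at n = 72 the exact test catches the majority of F = 0.5 violators
  # (power depends on the MAF, so per-SNP detection is not certain);
  # conforming SNPs are essentially never flagged
  expect_gt(mean(pv[viol] < 1e-4), 0.5)
  expect_lt(mean(pv[!viol] < 1e-4), 0.05)
  expect_gt(mean(pv[viol] < 1e-4), mean(pv[!viol] < 1e-4))
})

test_that("HWE p-values on conforming SNPs are approximately uniform", {
  # 1000 SNPs x 500 subjects; the exact test is discrete and slightly
  # conservative, so the KS distance to uniform stays small but nonzero
  cfg <- sim_config(n_ad = 250, n_nc = 250, n_regions = 1, n_genes = 10,
                    snps_per_gene = c(100, 100), missing_rate = 0, seed = 1)
  sim <- generate_genotypes(cfg)
  gc <- genotype_counts(sim$table)
  pv <- vapply(seq_len(nrow(gc)),
               function(i) hwe_exact_test(gc[i, 1], gc[i, 2], gc[i, 3]),
               numeric(1))
  ks <- suppressWarnings(stats::ks.test(pv, "punif"))
  expect_lt(unname(ks$statistic), 0.1)
})

test_that("a full-effect coupling makes the fusion feature exactly 1 for patients", {
  out <- small_fusion(seed = 4, couplings = list(c(3, 2, 1)))
  id <- paste(out$dataset$roi$region_names[3], "gene_02", sep = "|")
  r_ad <- out$fm$values[out$labels == -1, id]
  expect_equal(unname(r_ad), rep(1, sum(out$labels == -1)), tolerance = 1e-12)
  # controls stay at noise level
  expect_lt(max(abs(out$fm$values[out$labels == 1, id])), 0.9)
})

test_that("zero effect leaves the coupled pair at the null correlation level", {
  out <- small_fusion(seed = 6, couplings = list(c(1, 1, 0)), n_ad = 30,
                      n_nc = 10)
  id <- paste(out$dataset$roi$region_names[1], "gene_01", sep = "|")
  r <- out$fm$values[out$labels == -1, id]
  # null sampling distribution: |r| < 3/sqrt(L) for ~99% of subjects
  expect_gt(mean(abs(r) < 3 / sqrt(out$fm$L)), 0.9)
})

test_that("without planted couplings no feature reaches Bonferroni significance", {
  hits <- vapply(1:40, function(s) {
    out <- small_fusion(seed = s)
    tt <- ttest_feature_filter(out$fm$values, out$labels, alpha = 0.05,
                               adjust = "bonferroni")
    sum(tt$selected)
  }, numeric(1))
  expect_gte(mean(hits == 0), 0.9)
})

test_that("the patient-group fusion feature is monotone in effect size", {
  means <- vapply(c(0, 0.25, 0.5, 0.75, 1), function(e) {
    out <- small_fusion(seed = 17, couplings = list(c(2, 1, e)))
    id <- paste(out$dataset$roi$region_names[2], "gene_01", sep = "|")
    mean(out$fm$values[out$labels == -1, id])
  }, numeric(1))
  expect_true(all(diff(means) >= 0))
})

test_that("fixtures round-trip through the readers", {
  cfg <- sim_config(n_ad = 4, n_nc = 4, n_regions = 6, n_genes = 3,
                    snps_per_gene = c(40, 45), n_timepoints = 40,
                    planted_couplings = list(c(1, 2, 0.8)),
                    missing_rate = 0.02, seed = 31)
  ds <- simulate_dataset(cfg)
  dir <- withr::local_tempdir()
  paths <- write_fixture(ds, dir)
  fx <- read_fixture(dir)
  expect_identical(fx$genotypes$subject_ids, ds$genotypes$subject_ids)
  expect_identical(fx$genotypes$a1, ds$genotypes$a1)
  expect_identical(fx$genotypes$a2, ds$genotypes$a2)
  expect_identical(fx$genotypes$snps$snp_id, ds$genotypes$snps$snp_id)
  expect_identical(fx$genotypes$snps$gene_id, ds$genotypes$snps$gene_id)
  expect_equal(fx$labels, ds$truth$labels)
  # floats survive at the fixed serialization precision
  expect_equal(fx$roi$series, ds$roi$series, tolerance = 1e-8)
  expect_identical(fx$roi$region_names, ds$roi$region_names)
  # labels TSV has one row per subject; truth echoes the planted couplings
  expect_equal(nrow(read.delim(paths[["labels"]])), 8)
  truth <- jsonlite::read_json(paths[["truth"]])
  expect_length(truth$planted_couplings, 1)
  expect_equal(truth$planted_couplings[[1]]$region, 1)
  expect_equal(truth$planted_couplings[[1]]$gene, 2)
  expect_equal(truth$planted_couplings[[1]]$effect, 0.8)
})
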