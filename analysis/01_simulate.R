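#!/usr/bin/env Rscript

# Step 1: generate the synthetic study cohort.
#
# Emulates a two-group imaging-genetics study (37 patients, 35 controls):
# chip genotypes grouped into 36 genes of 40-50 SNPs, 90-region fMRI time
# series of 140 timepoints, and three planted region-gene couplings
# concentrated on region 29 (Insula_L) and gene_07, which are the ground
# truth every later step tries to recover. Writes the dataset as
# pipeline-readable text files under results/data/.

suppressPackageStartupMessages(library(mrfusion))

seed <- 20260930L
out_dir <- "results/data"

cfg <- sim_config(
  n_ad = 37, n_nc = 35, n_regions = 90, n_genes = 36,
  snps_per_gene = c(40, 50), n_timepoints = 140,
  planted_couplings = list(c(29L, 7L, 0.9),
                           c(29L, 20L, 0.85),
                           c(53L, 7L, 0.9)),
  maf_range = c(0.1, 0.5), missing_rate = 0.001, noise_sd = 1,
  seed = seed)

dataset <- simulate_dataset(cfg)
paths <- write_fixture(dataset, out_dir)

cat("Simulated", length(dataset$genotypes$subject_ids), "subjects,",
    nrow(dataset$genotypes$snps), "SNPs in", cfg$n_genes, "genes;",
    dim(dataset$roi$series)[2], "regions x", dim(dataset$roi$series)[3],
    "timepoints.\n")
cat("Planted couplings:",
    paste(vapply(cfg$planted_couplings, function(p) {
      sprintf("%s|gene_%02d (effect %.2f)",
              dataset$roi$region_names[p$region], p$gene, p$effect)
    }, character(1)), collapse = ", "), "\n")
cat("Files written under", out_dir, "\n")
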