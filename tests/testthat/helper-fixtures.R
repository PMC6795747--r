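# Shared fixtures and independent oracles, built in code.

# A genotype table from an explicit call matrix. `calls` is a character
# matrix of "AA", "AG", "--" (missing) entries; alleles are taken per column
# from the stated pair.
make_table <- function(calls, allele_a, allele_b, gene_id = NA_character_,
                       pos = NULL) {
  n <- nrow(calls)
  p <- ncol(calls)
  if (is.null(pos)) pos <- seq_len(p) * 1000L
  a1 <- matrix(substr(calls, 1, 1), n, p)
  a2 <- matrix(substr(calls, 2, 2), n, p)
  a1[a1 == "-"] <- NA_character_
  a2[a2 == "-"] <- NA_character_
  snps <- data.frame(snp_id = sprintf("s%03d", seq_len(p)),
                     chrom = 1L, pos = pos,
                     gene_id = rep_len(gene_id, p),
                     allele_a = rep_len(allele_a, p),
                     allele_b = rep_len(allele_b, p),
                     stringsAsFactors = FALSE)
  genotype_table(sprintf("sub%03d", seq_len(n)), snps, a1, a2)
}

# A genotype table with given genotype counts at one SNP (alleles A/G).
counts_table <- function(n_hom_a, n_het, n_hom_b) {
  calls <- matrix(c(rep("AA", n_hom_a), rep("AG", n_het), rep("GG", n_hom_b)),
                  ncol = 1)
  make_table(calls, "A", "G")
}

# Independent HWE oracle: full enumeration of the conditional distribution
# of the heterozygote count given the allele counts, probabilities from
# direct products over choose(), no shared code with hwe_exact_test().
hwe_enum_oracle <- function(n_hom_a, n_het, n_hom_b) {
  n <- n_hom_a + n_het + n_hom_b
  na <- 2 * n_hom_a + n_het
  nb <- 2 * n_hom_b + n_het
  if (na == 0 || nb == 0) return(1)
  hets <- Filter(function(h) (na - h) %% 2 == 0 && h <= min(na, nb) &&
                   (na - h) / 2 + (nb - h) / 2 + h == n,
                 0:min(na, nb))
  probs <- vapply(hets, function(h) {
    # multinomial count of genotype configurations over permutations of
    # alleles: C(n; haa, h, hbb) * 2^h / C(2n, na)
    haa <- (na - h) / 2
    hbb <- (nb - h) / 2
    exp(lchoose(n, haa) + lchoose(n - haa, h) + h * log(2) -
          lchoose(2 * n, na))
  }, numeric(1))
  probs <- probs / sum(probs)
  p_obs <- probs[match(n_het, hets)]
  sum(probs[probs <= p_obs + 1e-12])
}

# Independent hypergeometric upper-tail oracle by support enumeration.
hyper_enum_oracle <- function(N, K, n, x) {
  support <- max(0, K + n - N):min(K, n)
  probs <- choose(K, support) * choose(N - K, n - support) / choose(N, n)
  sum(probs[support >= x])
}

# Exhaustive depth-1 classifier oracle: best single threshold on any one
# feature by training accuracy (ties: -1 on the ambiguous side).
stump_oracle_accuracy <- function(x, y) {
  best <- mean(y == if (sum(y == -1) >= sum(y == 1)) -1 else 1)
  for (j in seq_len(ncol(x))) {
    vals <- sort(unique(x[, j]))
    if (length(vals) < 2) next
    for (t in (vals[-1] + vals[-length(vals)]) / 2) {
      left <- x[, j] <= t
      for (ll in c(-1, 1)) for (rl in c(-1, 1)) {
        pred <- ifelse(left, ll, rl)
        best <- max(best, mean(pred == y))
      }
    }
  }
  best
}

# Small simulated dataset pushed through QC, encoding and fusion.
small_fusion <- function(seed = 1, couplings = list(), n_ad = 10, n_nc = 10,
                         n_regions = 8, n_genes = 5) {
  cfg <- sim_config(n_ad = n_ad, n_nc = n_nc, n_regions = n_regions,
                    n_genes = n_genes, snps_per_gene = c(36, 40),
                    n_timepoints = 60, planted_couplings = couplings,
                    seed = seed)
  ds <- simulate_dataset(cfg)
  qc <- apply_qc(ds$genotypes)
  enc <- encode_genes(segment_to_length(group_by_gene(qc$table), qc$table))
  lab <- ds$truth$labels[qc$table$subject_ids]
  roi <- roi_series(qc$table$subject_ids, ds$roi$region_names,
                    ds$roi$series[match(qc$table$subject_ids,
                                        ds$roi$subject_ids), , ,
                                  drop = FALSE])
  fm <- suppressWarnings(build_fusion_matrix(roi, enc, lab))
  list(dataset = ds, fm = fm, labels = lab)
}
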